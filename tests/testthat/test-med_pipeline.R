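test_that("preprocessing strips dose, form and punctuation tokens", {
  expect_identical(preprocess_name("Metoprolol Succ ER"), "metoprolol")
  expect_identical(preprocess_name("Metoprolol Tart"), "metoprolol")
  expect_identical(preprocess_name("ibuprofen 200 mg"), "ibuprofen")
  expect_identical(preprocess_name("ibuprofen 200mg"), "ibuprofen")
  expect_identical(preprocess_name("aspirin"), "aspirin")
  expect_identical(preprocess_name("Albuteral  Inhaler"), "albuteral")
  expect_identical(preprocess_name("Vit  B12"), "vit b12")  # b12 is not a dose
  # when every token drops, the case-folded original is returned
  expect_identical(preprocess_name("200 mg"), "200 mg")
  expect_error(preprocess_name("   "), "empty")
  # the stoplist is configurable
  expect_identical(preprocess_name("aspirin forte", form_stoplist = "forte"),
                   "aspirin")
})

test_that("supplement screening uses the ratio clause only", {
  b <- fixture_bundle()
  expect_true(classify_supplement("vitamin c", b$supplements))
  expect_true(classify_supplement("vit b12", b$supplements))
  expect_true(classify_supplement("vitemin b12", b$supplements))
  expect_false(classify_supplement("metoprolol", b$supplements))
  # distance alone must NOT qualify: "irom" is 1 edit from "iron" but
  # ratio 7/8 = 0.875 > 0.85 passes; "irn" has ratio 6/7 ≈ 0.857 > 0.85;
  # "zincx" ratio 8/9 ≈ 0.889. Use a pair where only distance would pass:
  # "ironxx" vs "iron": distance 2, ratio 8/10 = 0.8 -> not a supplement.
  expect_false(classify_supplement("ironxx", b$supplements))
})

test_that("medication normalization corrects misspellings via the lexicon", {
  b <- fixture_bundle()
  hit <- normalize_medication("fexafenedine", b$drugs)
  expect_identical(hit$canonical_name, "fexofenadine")
  expect_identical(hit$distance, 2L)
  hit <- normalize_medication("quinipril", b$drugs)
  expect_identical(hit$canonical_name, "quinapril")
  # a brand synonym resolves to its canonical name
  hit <- normalize_medication("advil", b$drugs)
  expect_identical(hit$canonical_name, "ibuprofen")
  expect_null(normalize_medication("xqzzt", b$drugs))
})

test_that("the medication branch reproduces the worked examples end to end", {
  b <- fixture_bundle()
  g <- golden_medications()
  res <- process_medications(as_records(med = g$medication_raw), b)
  expect_identical(res$status, g$expected_status)
  mapped <- res$status == "mapped"
  got_label <- vapply(res$atc_codes[mapped], function(s) {
    sub("^[^:]*:", "", strsplit(s, "|", fixed = TRUE)[[1L]][1L])
  }, "", USE.NAMES = FALSE)
  expect_identical(got_label, g$expected_class[mapped])
  # excluded supplements never carry classes or canonical names
  expect_true(all(is.na(res$canonical_name[res$status == "supplement_excluded"])))
  expect_true(all(is.na(res$atc_codes[res$status == "supplement_excluded"])))
})

test_that("statuses partition every batch and order is preserved", {
  b <- fixture_bundle()
  recs <- as_records(med = c("Fexafenedine", "vitamin c", "garblewarble",
                             "Quinipril", "fish oil", ""))
  res <- process_medications(recs, b)
  expect_identical(nrow(res), nrow(recs))
  expect_identical(res$medication_raw, recs$medication_raw)
  tab <- table(factor(res$status, levels = c("supplement_excluded", "mapped",
                                             "manual_queue")))
  expect_identical(sum(tab), nrow(recs))
  expect_identical(unname(tab[["manual_queue"]]), 2L)  # garbage + empty entry
  errs <- attr(res, "errors")
  expect_identical(errs$row, 6L)

  expect_identical(nrow(process_medications(as_records()[0, ], b)), 0L)
})

test_that("no supplement name is ever emitted as a mapped drug", {
  b <- fixture_bundle()
  recs <- as_records(med = c(b$supplements, b$drugs$canonical_name))
  res <- process_medications(recs, b)
  mapped_names <- res$canonical_name[res$status == "mapped"]
  expect_false(any(mapped_names %in% b$supplements))
  expect_identical(sum(res$status == "supplement_excluded"),
                   length(b$supplements))
})

test_that("raising the ratio threshold never increases mapped count", {
  b <- generate_lexicon(12, 6, min_separation = 4, seed = 3)
  cc <- generate_corpus(b, 80, 0.7, 0.2, 0.1, corruption_spec(2, seed = 3))
  mapped_counts <- vapply(c(0.70, 0.80, 0.85, 0.90, 0.95), function(th) {
    res <- process_medications(cc$records, b, match_policy(th, 2L, "any"))
    sum(res$status == "mapped")
  }, 1L)
  expect_true(all(diff(mapped_counts) <= 0L))
})

test_that("re-running the pipeline on its own canonical output is a fixed point", {
  b <- fixture_bundle()
  res <- process_medications(as_records(med = golden_medications()$medication_raw), b)
  canon <- res$canonical_name[res$status == "mapped"]
  res2 <- process_medications(as_records(med = canon), b)
  expect_true(all(res2$status == "mapped"))
  expect_identical(res2$canonical_name, canon)
  expect_true(all(res2$match_distance == 0L))
})
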