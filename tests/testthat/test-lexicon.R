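write_drugs <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("canonical_name\tsynonyms\tconcept_id\tatc_codes", rows), path)
  path
}

test_that("the packaged lexicon loads with folded, validated content", {
  b <- fixture_bundle()
  expect_s3_class(b, "lexicon_bundle")
  expect_true(all(c("fexofenadine", "hydrochlorothiazide", "metoprolol",
                    "quinapril") %in% b$drugs$canonical_name))
  expect_true("vit b12" %in% b$supplements)
  expect_identical(b$stem_map$category[b$stem_map$stem == "ulc colit"],
                   "gastrointestinal disease")
  expect_true(all(b$drugs$canonical_name == tolower(b$drugs$canonical_name)))
  # canonical names never listed among their own synonyms
  for (i in seq_len(nrow(b$drugs))) {
    expect_false(b$drugs$canonical_name[i] %in% b$drugs$synonyms[[i]])
  }
})

test_that("malformed lexicon files are rejected with line context", {
  empty <- write_drugs(character(0))
  expect_error(read_drug_lexicon(empty), "empty")

  bad_atc <- write_drugs("aspirin\t\tRX1\tZZ99X9:junk")
  expect_error(read_drug_lexicon(bad_atc), "ZZ99X9")

  dup <- write_drugs(c("aspirin\t\tRX1\tN02B:x", "Aspirin\t\tRX2\tB01A:y"))
  expect_error(read_drug_lexicon(dup), "duplicate canonical_name")

  expect_error(read_drug_lexicon(tempfile()), "not found")
})

test_that("cross-file invariants are enforced at load time", {
  dir <- tempfile()
  dir.create(dir)
  file.copy(list.files(fixture_dir(), full.names = TRUE), dir)
  # inject a supplement that collides with a drug canonical name
  cat("aspirin\n", file = file.path(dir, "supplements.tsv"), append = TRUE)
  expect_error(load_bundle(dir), "both drug and supplement")
})

test_that("a synonym shared by two drug entries is rejected", {
  dir <- tempfile()
  dir.create(dir)
  file.copy(list.files(fixture_dir(), full.names = TRUE), dir)
  drugs <- write_drugs(c("aspirin\tshared\tRX1\tN02B:x",
                         "ibuprofen\tshared\tRX2\tM01A:y"),
                       file.path(dir, "drugs.tsv"))
  expect_error(load_bundle(dir), "more than one drug entry")
})

test_that("save_bundle / load_bundle round-trips in both formats", {
  b <- fixture_bundle()
  for (fmt in c("tsv", "json")) {
    dir <- tempfile()
    save_bundle(b, dir, format = fmt)
    b2 <- load_bundle(dir, format = fmt)
    expect_equal(b2$drugs$canonical_name, b$drugs$canonical_name)
    expect_equal(b2$drugs$concept_id, b$drugs$concept_id)
    expect_equal(b2$drugs$synonyms, b$drugs$synonyms)
    expect_equal(b2$drugs$atc, b$drugs$atc)
    expect_equal(b2$supplements, b$supplements)
    expect_equal(as.data.frame(b2$stem_map), as.data.frame(b$stem_map))
    expect_equal(b2$wordlist, b$wordlist)
  }
})

test_that("ATC syntax validation and level arithmetic", {
  expect_identical(is_valid_atc(c("C", "C07", "C07A", "ZZ99X9", "c07a", "C07AB")),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(unname(atc_level(c("C", "C07", "C07A"))), c(1L, 2L, 3L))
  expect_identical(atc_truncate("C07A", 1), "C")
  expect_identical(atc_truncate("C07A", 2), "C07")
  expect_identical(atc_truncate(c("N02B", "B01A"), 3), c("N02B", "B01A"))
  # truncating to level k then j < k equals truncating directly to j
  codes <- c("A01A", "B01A", "C07A", "N02B", "R06A", "H03", "J")
  for (k in 3:1) for (j in seq_len(k)) {
    expect_identical(atc_truncate(atc_truncate(codes, k), j),
                     atc_truncate(codes, j))
  }
})

test_that("the offline adapter resolves concepts and truncates classes", {
  b <- fixture_bundle()
  ad <- offline_adapter(b)
  cid <- resolve_concept("fexofenadine", ad)
  expect_identical(cid, b$drugs$concept_id[b$drugs$canonical_name == "fexofenadine"])
  expect_null(resolve_concept("notadrug", ad))

  asp <- resolve_concept("aspirin", ad)
  lvl3 <- atc_classes(asp, level = 3, adapter = ad)
  expect_setequal(lvl3$code, c("N02B", "B01A", "A01A"))
  lvl1 <- atc_classes(asp, level = 1, adapter = ad)
  expect_setequal(lvl1$code, c("N", "B", "A"))
  expect_true(all(is.na(lvl1$label)))  # labels do not survive truncation
  expect_error(atc_classes("nope", level = 3, adapter = ad), "unknown concept")
})
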