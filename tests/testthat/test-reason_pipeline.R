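test_that("word-level spell correction against the dictionary", {
  wl <- fixture_bundle()$wordlist
  expect_identical(spell_correct_word("arthritis", wl), "arthritis")
  expect_identical(spell_correct_word("vitemin", wl), "vitamin")
  expect_identical(spell_correct_word("qqqq", wl), "qqqq")
  expect_identical(spell_correct_word(c("presure", "hygh"), wl),
                   c("pressure", "high"))
})

test_that("stem strings map to categories under the AND rule", {
  sm <- fixture_bundle()$stem_map
  hit <- map_reason("ulc colit", sm)
  expect_identical(hit$category, "gastrointestinal disease")
  expect_identical(hit$distance, 0L)
  hit <- map_reason("arthr", sm)
  expect_identical(hit$category, "arthritis")
  expect_null(map_reason("zzz qqq", sm))
  # near-miss passes only when BOTH distance and ratio clauses hold
  hit <- map_reason("ulc colits", sm)  # distance 1, ratio 18/19
  expect_identical(hit$category, "gastrointestinal disease")
  expect_null(map_reason("ulc colxxx", sm))  # distance 3 fails the AND rule
})

test_that("manual overrides win, validate, and are idempotent", {
  b <- fixture_bundle()
  recs <- as_records(reason = c("b/p", "diabetes"))
  res <- process_reasons(recs, b)
  expect_identical(res$status[1], "manual_queue")

  ov <- data.frame(reason_raw = "b/p", category = "hypertension")
  res2 <- apply_overrides(res, ov)
  expect_identical(res2$status[1], "overridden")
  expect_identical(res2$category[1], "hypertension")
  expect_identical(res2$status[2], "auto")  # untouched row unchanged
  expect_identical(apply_overrides(res2, ov), res2)  # idempotent

  # an override beats a conflicting automatic mapping
  ov2 <- data.frame(reason_raw = "diabetes", category = "endocrine disorders")
  res3 <- apply_overrides(res, ov2)
  expect_identical(res3$status[2], "overridden")
  expect_identical(res3$category[2], "endocrine disorders")

  expect_identical(apply_overrides(res, ov[0, ]), res)  # empty table: identity
  expect_error(apply_overrides(res, data.frame(reason_raw = "x", category = "")),
               "empty category")
})

test_that("the reason branch reproduces the worked examples end to end", {
  b <- fixture_bundle()
  g <- golden_reasons()
  res <- process_reasons(as_records(reason = g$reason_raw), b)
  expect_true(all(res$status == "auto"))
  expect_identical(res$category, g$expected_class)
  # a misspelled multi-word reason still reaches its category
  res2 <- process_reasons(as_records(reason = "hygh blood presure"), b)
  expect_identical(res2$status, "auto")
  expect_identical(res2$category, "hypertension")
  expect_identical(res2$corrected, "high blood pressure")
})

test_that("statuses partition the input and empty reasons are collected", {
  b <- fixture_bundle()
  recs <- as_records(reason = c("arthritis", "zzz qqq", "", "diabetes"))
  res <- process_reasons(recs, b,
                         overrides = c("zzz qqq" = "unmapped example"))
  expect_identical(nrow(res), nrow(recs))
  expect_identical(sum(res$status == "auto") +
                     sum(res$status == "manual_queue") +
                     sum(res$status == "overridden"), nrow(recs))
  expect_identical(res$status,
                   c("auto", "overridden", "manual_queue", "auto"))
  expect_true(all(is.na(res$category[res$status == "manual_queue"])))
  expect_identical(attr(res, "errors")$row, 3L)
  expect_identical(nrow(process_reasons(as_records()[0, ], b)), 0L)
})

test_that("lowering the ratio threshold never decreases auto-mapped count", {
  b <- fixture_bundle()
  reasons <- c("arthritis", "gastritus", "diabetus", "asthmatic", "zzz",
               "ulcerative colitus", "depresion", "hygh blood presure")
  counts <- vapply(c(0.95, 0.90, 0.85, 0.75, 0.60), function(th) {
    res <- process_reasons(as_records(reason = reasons), b,
                           match_policy(th, 2L, "all"))
    sum(res$status == "auto")
  }, 1L)
  expect_true(all(diff(counts) >= 0L))
})
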