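fixture_dir <- function() {
  system.file("extdata", "lexicon", package = "medmapr", mustWork = TRUE)
}

# loaded once per test run
.fixture_env <- new.env(parent = emptyenv())
fixture_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- load_bundle(fixture_dir())
  }
  .fixture_env$bundle
}

# misspelled / brand-form medication entries and the classes they must reach
golden_medications <- function() {
  tibble::tibble(
    medication_raw = c("Fexafenedine", "fexfenadine", "Hydrochlorothazide",
                       "Hydrochlorthiazide", "Metoprolol Succ ER",
                       "Metoprolol Tart", "Quinipril", "Vit B12",
                       "vitemin B12"),
    expected_status = c(rep("mapped", 7L), rep("supplement_excluded", 2L)),
    expected_class = c("antihistamines", "antihistamines", "diuretics",
                       "diuretics", "beta-adrenergic blocking agents",
                       "beta-adrenergic blocking agents",
                       "angiotensin converting enzyme inhibitors", NA, NA)
  )
}

# unambiguous original reasons and their printed classes
golden_reasons <- function() {
  tibble::tibble(
    reason_raw = c("arthritis", "musculoskeletal", "gastritis",
                   "ulcerative colitis", "asthmatic", "diarrhea",
                   "depression", "diabetes"),
    expected_class = c("arthritis", "joint/musculoskeletal problem",
                       "gastrointestinal disease", "gastrointestinal disease",
                       "asthma", "autonomic symptoms",
                       "depression and related disorders", "diabetes")
  )
}

as_records <- function(med = character(0), reason = character(0)) {
  n <- max(length(med), length(reason))
  tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(n)),
    medication_raw = rep_len(if (length(med)) med else "aspirin", n),
    reason_raw = rep_len(if (length(reason)) reason else "arthritis", n)
  )
}
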