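# Seeded synthetic data: stands in for restricted study records. Generates
# lexicons with a guaranteed minimum pairwise edit distance, corrupts names
# with a controlled number of random edits, assembles record corpora with
# ground truth, and scores pipeline output against that truth.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a random misspelling model
#'
#' @param n_edits Number of random single-character edits to apply.
#' @param operations Subset of `c("insert", "delete", "substitute")`.
#' @param seed Integer seed; corruption is deterministic per seed.
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(n_edits = 1L,
                            operations = c("insert", "delete", "substitute"),
                            seed = 1L) {
  operations <- match.arg(operations, several.ok = TRUE)
  stopifnot(length(n_edits) == 1L, n_edits >= 0,
            n_edits == as.integer(n_edits), length(seed) == 1L)
  if (n_edits > 0L && length(operations) == 0L) {
    stop("operations must be non-empty when n_edits > 0", call. = FALSE)
  }
  structure(
    list(n_edits = as.integer(n_edits), operations = operations,
         seed = as.integer(seed)),
    class = "corruption_spec"
  )
}

# one random edit using the ambient RNG stream
.edit_once <- function(name, operations) {
  chars <- strsplit(name, "")[[1L]]
  op <- operations[sample.int(length(operations), 1L)]
  if (op == "delete" && length(chars) <= 1L) op <- "substitute"
  if (op == "insert") {
    pos <- sample.int(length(chars) + 1L, 1L)
    chars <- append(chars, sample(letters, 1L), after = pos - 1L)
  } else if (op == "delete") {
    chars <- chars[-sample.int(length(chars), 1L)]
  } else {
    pos <- sample.int(length(chars), 1L)
    chars[pos] <- sample(setdiff(letters, chars[pos]), 1L)
  }
  paste(chars, collapse = "")
}

.corrupt_ambient <- function(name, n_edits, operations) {
  for (k in seq_len(n_edits)) name <- .edit_once(name, operations)
  name
}

#' Corrupt a name with random edits
#'
#' Applies exactly `n_edits` random insertions, deletions or substitutions;
#' the result is guaranteed to lie within edit distance `n_edits` of the
#' input (edits can partially cancel, so the realized distance may be
#' smaller). Deterministic for a fixed spec.
#'
#' @param name Non-empty string.
#' @param spec A [corruption_spec()].
#' @return The corrupted string.
#' @examples
#' corrupt("metoprolol", corruption_spec(n_edits = 1, seed = 42))
#' @export
corrupt <- function(name, spec = corruption_spec()) {
  stopifnot(inherits(spec, "corruption_spec"),
            is.character(name), length(name) == 1L, nzchar(name))
  if (spec$n_edits == 0L) return(name)
  .with_seed(spec$seed, .corrupt_ambient(name, spec$n_edits, spec$operations))
}

.syllable_name <- function(n_syllables) {
  cons <- setdiff(letters, c("a", "e", "i", "o", "u"))
  paste(vapply(seq_len(n_syllables), function(k) {
    paste0(sample(cons, 1L), sample(c("a", "e", "i", "o", "u"), 1L))
  }, ""), collapse = "")
}

# pronounceable names, pairwise Levenshtein distance >= min_separation
.generate_separated_names <- function(n, min_separation, max_tries = 400L * n) {
  names_out <- character(0)
  tries <- 0L
  while (length(names_out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not generate ", n, " names with minimum separation ",
           min_separation, " after ", max_tries, " attempts", call. = FALSE)
    }
    cand <- .syllable_name(sample(3:6, 1L))  # 6 to 12 characters
    if (length(names_out) == 0L ||
        min(levenshtein_distance(names_out, cand)) >= min_separation) {
      names_out <- c(names_out, cand)
    }
  }
  names_out
}

#' Generate a synthetic lexicon bundle
#'
#' Synthesizes pronounceable drug and supplement names (alternating
#' consonant/vowel syllables, 6-12 characters) such that every pair of
#' distinct names across both lexicons is at least `min_separation` edits
#' apart, attaches synthetic concept ids and 1-2 synthetic level-3 ATC codes
#' per drug, and builds a small reason vocabulary (words, their stems and
#' one category per stem). Deterministic per seed.
#'
#' @param n_drugs,n_supplements Number of names to generate (each >= 1).
#' @param min_separation Minimum pairwise Levenshtein distance (>= 1).
#' @param seed Integer seed.
#' @param n_reason_terms Number of synthetic reason words (default 8).
#' @return A validated `lexicon_bundle`.
#' @examples
#' b <- generate_lexicon(5, 3, min_separation = 5, seed = 7)
#' b
#' @export
generate_lexicon <- function(n_drugs, n_supplements, min_separation = 5L,
                             seed = 1L, n_reason_terms = 8L) {
  stopifnot(n_drugs >= 1L, n_supplements >= 1L, min_separation >= 1L)
  .with_seed(seed, {
    nm <- .generate_separated_names(n_drugs + n_supplements, min_separation)
    drug_names <- nm[seq_len(n_drugs)]
    supp_names <- nm[n_drugs + seq_len(n_supplements)]
    atc <- lapply(seq_len(n_drugs), function(i) {
      k <- sample(1:2, 1L)
      codes <- unique(vapply(seq_len(k), function(j) {
        paste0(sample(LETTERS, 1L), sprintf("%02d", sample(0:99, 1L)),
               sample(LETTERS, 1L))
      }, ""))
      data.frame(code = codes,
                 label = paste("synthetic class", tolower(codes)),
                 stringsAsFactors = FALSE)
    })
    words <- character(0)
    stems <- character(0)
    tries <- 0L
    while (length(words) < n_reason_terms && tries < 400L * n_reason_terms) {
      tries <- tries + 1L
      w <- .syllable_name(sample(3:5, 1L))
      s <- lancaster_stem(w)
      if (!(w %in% words) && !(s %in% stems)) {
        words <- c(words, w)
        stems <- c(stems, s)
      }
    }
    bundle <- structure(
      list(
        drugs = tibble::tibble(
          canonical_name = drug_names,
          synonyms = replicate(n_drugs, character(0), simplify = FALSE),
          concept_id = sprintf("SYN%04d", seq_len(n_drugs)),
          atc = atc
        ),
        supplements = supp_names,
        stem_map = tibble::tibble(
          stem = stems,
          category = sprintf("synthetic category %02d", seq_along(stems))
        ),
        wordlist = words
      ),
      class = "lexicon_bundle"
    )
    validate_bundle(bundle)
  })
}

#' Generate a synthetic record corpus with ground truth
#'
#' Allocates record counts deterministically from the fractions
#' (`diff(round(cumsum(fracs) * n))`, so fractions that are exact multiples
#' of `1/n` give exact counts), samples names of each kind, corrupts drug
#' and supplement names with `corruption$n_edits` random edits each, and
#' emits garbage entries as random strings that are far from every lexicon
#' name (edit distance > 3 *and* ratio <= 0.85, i.e. unmappable by
#' construction). Each record is paired with a reason word drawn from the
#' bundle's vocabulary whose stem is a key of the stem map.
#'
#' @param bundle A validated `lexicon_bundle`.
#' @param n_records Number of records.
#' @param drug_frac,supplement_frac,garbage_frac Composition fractions,
#'   summing to 1.
#' @param corruption A [corruption_spec()]; its seed drives the whole
#'   corpus.
#' @return A list with `records` (tibble: `subject_id`, `medication_raw`,
#'   `reason_raw`) and `truth` (tibble: `raw`, `true_kind`,
#'   `true_canonical`, `true_category`), aligned row by row.
#' @examples
#' b <- generate_lexicon(5, 3, min_separation = 5, seed = 7)
#' cc <- generate_corpus(b, 20, 0.6, 0.3, 0.1, corruption_spec(1, seed = 7))
#' table(cc$truth$true_kind)
#' @export
generate_corpus <- function(bundle, n_records, drug_frac = 0.6,
                            supplement_frac = 0.3, garbage_frac = 0.1,
                            corruption = corruption_spec()) {
  stopifnot(inherits(bundle, "lexicon_bundle"),
            inherits(corruption, "corruption_spec"), n_records >= 1L)
  fracs <- c(drug_frac, supplement_frac, garbage_frac)
  if (abs(sum(fracs) - 1) > 1e-8) {
    stop("composition fractions must sum to 1", call. = FALSE)
  }
  counts <- diff(c(0L, round(cumsum(fracs) * n_records)))
  .with_seed(corruption$seed, {
    lexicon_names <- c(bundle$drugs$canonical_name,
                       unlist(bundle$drugs$synonyms, use.names = FALSE),
                       bundle$supplements)
    word_stem <- lancaster_stem(bundle$wordlist)
    usable <- bundle$wordlist[word_stem %in% bundle$stem_map$stem]
    if (length(usable) == 0L) {
      stop("bundle wordlist has no word whose stem is a stem-map key",
           call. = FALSE)
    }
    usable_cat <- bundle$stem_map$category[
      match(lancaster_stem(usable), bundle$stem_map$stem)]

    kinds <- rep(c("drug", "supplement", "garbage"), counts)
    kinds <- kinds[sample.int(length(kinds))]   # interleave kinds
    n <- length(kinds)
    med_raw <- character(n)
    true_canonical <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (kinds[i] == "drug") {
        nm <- bundle$drugs$canonical_name[sample.int(nrow(bundle$drugs), 1L)]
        true_canonical[i] <- nm
        med_raw[i] <- .corrupt_ambient(nm, corruption$n_edits,
                                       corruption$operations)
      } else if (kinds[i] == "supplement") {
        nm <- bundle$supplements[sample.int(length(bundle$supplements), 1L)]
        med_raw[i] <- .corrupt_ambient(nm, corruption$n_edits,
                                       corruption$operations)
      } else {
        repeat {
          g <- paste(sample(letters, sample(6:14, 1L), replace = TRUE),
                     collapse = "")
          d <- levenshtein_distance(lexicon_names, g)
          r <- levenshtein_ratio(lexicon_names, g)
          if (min(d) > 3L && max(r) <= 0.85) break
        }
        med_raw[i] <- g
      }
    }
    ri <- sample.int(length(usable), n, replace = TRUE)
    list(
      records = tibble::tibble(
        subject_id = sprintf("S%04d", seq_len(n)),
        medication_raw = med_raw,
        reason_raw = usable[ri]
      ),
      truth = tibble::tibble(
        raw = med_raw,
        true_kind = kinds,
        true_canonical = true_canonical,
        true_category = usable_cat[ri]
      )
    )
  })
}

#' Score pipeline output against synthetic ground truth
#'
#' Canonical-name recovery is scored over the medication branch:
#' precision = correctly recovered canonicals / records the pipeline mapped
#' (1 when nothing was mapped: no false positives), recall = correctly
#' recovered / true drug records. `supplement_confusions` counts true drugs
#' excluded as supplements plus true supplements mapped as drugs.
#' `auto_mapped_fraction` follows the distinct-terms convention: distinct
#' non-supplement-excluded medication terms that were auto-mapped, divided
#' by all distinct non-supplement-excluded medication terms.
#'
#' @param med_results Tibble from [process_medications()].
#' @param reason_results Optional tibble from [process_reasons()] (checked
#'   for alignment; reason categories are scored against `true_category`
#'   when present).
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return An object of class `eval_metrics`: list with `precision`,
#'   `recall`, `auto_mapped_fraction`, `supplement_confusions` (and
#'   `reason_accuracy` when reason results were supplied).
#' @export
evaluate_pipeline <- function(med_results, reason_results = NULL, truth) {
  stopifnot(is.data.frame(med_results), is.data.frame(truth))
  if (nrow(med_results) != nrow(truth)) {
    stop("med_results and truth have different numbers of records", call. = FALSE)
  }
  if (!is.null(reason_results) && nrow(reason_results) != nrow(truth)) {
    stop("reason_results and truth have different numbers of records",
         call. = FALSE)
  }
  is_drug <- truth$true_kind == "drug"
  mapped <- med_results$status == "mapped"
  correct <- mapped & is_drug &
    !is.na(med_results$canonical_name) &
    med_results$canonical_name == truth$true_canonical
  precision <- if (sum(mapped) == 0L) 1.0 else sum(correct) / sum(mapped)
  recall <- if (sum(is_drug) == 0L) 1.0 else sum(correct) / sum(is_drug)
  confusions <- sum(is_drug & med_results$status == "supplement_excluded") +
    sum(truth$true_kind == "supplement" & mapped)
  non_supp <- med_results$status != "supplement_excluded"
  terms <- unique(fold(med_results$medication_raw[non_supp]))
  auto_terms <- unique(fold(med_results$medication_raw[mapped]))
  auto_fraction <- if (length(terms) == 0L) 1.0 else
    length(intersect(auto_terms, terms)) / length(terms)
  out <- list(
    precision = precision,
    recall = recall,
    auto_mapped_fraction = auto_fraction,
    supplement_confusions = as.integer(confusions)
  )
  if (!is.null(reason_results)) {
    ok <- !is.na(reason_results$category) &
      reason_results$category == truth$true_category
    out$reason_accuracy <- mean(ok)
  }
  structure(out, class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "<eval_metrics> precision %.3f, recall %.3f, auto-mapped %.3f, supplement confusions %d\n",
    x$precision, x$recall, x$auto_mapped_fraction, x$supplement_confusions
  ))
  invisible(x)
}
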