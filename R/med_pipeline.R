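# Medication branch: preprocess -> supplement check -> fuzzy normalization
# against the drug lexicon -> ATC mapping; residual records go to the manual
# queue. Supplements are screened out before drug matching.

#' Default dosage-form stoplist for medication preprocessing
#'
#' Tokens carrying formulation or strength information rather than drug
#' identity ("er", "succ", "tab", ...). Configurable in
#' [preprocess_name()] and [process_medications()].
#' @return Character vector.
#' @export
default_form_stoplist <- function() {
  c("er", "xr", "sr", "cr", "la", "succ", "tart", "tab", "tabs", "cap",
    "caps", "generic", "extra", "strength", "inhaler", "nebulizer")
}

.units <- c("mg", "mcg", "ml", "g")

#' Preprocess a raw medication string
#'
#' Case-folds, removes punctuation, collapses whitespace, and drops tokens
#' that are pure numbers, numbers with a dose unit (mg, mcg, ml, g), bare
#' dose units, or members of the dosage-form stoplist. If every token is
#' dropped, the case-folded original is returned instead of an empty string.
#'
#' @param raw Character vector of raw medication entries.
#' @param form_stoplist Tokens to drop; see [default_form_stoplist()].
#' @return Character vector of preprocessed names.
#' @examples
#' preprocess_name("Metoprolol Succ ER")  # "metoprolol"
#' preprocess_name("ibuprofen 200 mg")    # "ibuprofen"
#' @export
preprocess_name <- function(raw, form_stoplist = default_form_stoplist()) {
  stopifnot(is.character(raw))
  if (any(is.na(raw) | !nzchar(trimws(raw)))) {
    stop("empty or missing medication entry", call. = FALSE)
  }
  vapply(raw, function(s) {
    folded <- fold(s)
    cleaned <- gsub("\\s+", " ", trimws(gsub("[^[:alnum:][:space:]]", " ", folded)))
    toks <- strsplit(cleaned, " ", fixed = TRUE)[[1L]]
    drop <- grepl("^[0-9]+([.][0-9]+)?$", toks) |
      grepl(paste0("^[0-9]+([.][0-9]+)?(", paste(.units, collapse = "|"), ")$"), toks) |
      toks %in% .units |
      toks %in% form_stoplist
    kept <- toks[!drop]
    if (length(kept) == 0L) folded else paste(kept, collapse = " ")
  }, "", USE.NAMES = FALSE)
}

#' Is a preprocessed entry a supplement?
#'
#' Screens the entry against the supplement lexicon using the ratio clause
#' only: the entry counts as a supplement when its best match among the
#' supplement names has a Levenshtein ratio strictly above the policy's
#' ratio threshold. A `TRUE` result removes the record from drug matching.
#'
#' @param preprocessed Character vector from [preprocess_name()].
#' @param supplements Character vector of supplement names.
#' @param policy A [match_policy()]; only its `ratio_threshold` is used.
#' @return Logical vector.
#' @examples
#' classify_supplement("vitamin c", c("vitamin c", "fish oil"))  # TRUE
#' @export
classify_supplement <- function(preprocessed, supplements,
                                policy = match_policy()) {
  stopifnot(is.character(preprocessed))
  if (length(supplements) == 0L) return(rep(FALSE, length(preprocessed)))
  # ratio clause only: distance_threshold 0 disables the distance clause
  ratio_only <- match_policy(policy$ratio_threshold, 0L, "any")
  vapply(preprocessed, function(x) {
    !is.null(best_match(x, supplements, ratio_only))
  }, NA, USE.NAMES = FALSE)
}

#' Normalize a preprocessed medication to a canonical drug
#'
#' Fuzzy-matches the entry against all canonical names and synonyms in the
#' drug lexicon; a synonym hit resolves to its entry's canonical name.
#'
#' @param preprocessed Single preprocessed string (not supplement-excluded).
#' @param drugs Drug lexicon table from [read_drug_lexicon()].
#' @param policy A [match_policy()]; the default drug rule accepts on ratio
#'   OR distance.
#' @return A list with `canonical_name`, `concept_id`, `distance`, `ratio`,
#'   or `NULL` when nothing passes the policy.
#' @export
normalize_medication <- function(preprocessed, drugs, policy = match_policy()) {
  stopifnot(is.character(preprocessed), length(preprocessed) == 1L)
  n_syn <- vapply(drugs$synonyms, length, 1L)
  search <- c(drugs$canonical_name, unlist(drugs$synonyms, use.names = FALSE))
  owner <- c(seq_len(nrow(drugs)), rep(seq_len(nrow(drugs)), n_syn))
  hit <- best_match(preprocessed, search, policy)
  if (is.null(hit)) return(NULL)
  # the same string never belongs to two entries (bundle invariant)
  i <- owner[match(hit$candidate, search)]
  list(
    canonical_name = drugs$canonical_name[i],
    concept_id = drugs$concept_id[i],
    distance = hit$distance,
    ratio = hit$ratio
  )
}

#' Run the medication branch over a batch of records
#'
#' Each record receives exactly one status: `supplement_excluded`, `mapped`
#' (with canonical name, concept id and ATC classes), or `manual_queue`.
#' The supplement check precedes drug matching. Input order is preserved.
#' Records whose medication text is empty are collected as errors (attribute
#' `"errors"` on the result) and queued for manual review rather than
#' aborting the batch.
#'
#' @param records A data frame with columns `subject_id`, `medication_raw`
#'   (a `reason_raw` column may be present and is ignored here).
#' @param bundle A validated `lexicon_bundle`.
#' @param policy A [match_policy()] for drug matching (default: ratio OR
#'   distance).
#' @param adapter An `ontology_adapter`; defaults to the offline adapter on
#'   `bundle`.
#' @param atc_level ATC truncation level 1-3 (default 3, the therapeutic
#'   class).
#' @param form_stoplist Passed to [preprocess_name()].
#' @return A tibble with one row per record: `subject_id`, `medication_raw`,
#'   `preprocessed`, `status`, `canonical_name`, `concept_id`, `atc_codes`
#'   (pipe-separated `code:label`), `match_distance`, `match_ratio`.
#' @examples
#' bundle <- load_bundle(system.file("extdata", "lexicon", package = "medmapr"))
#' recs <- tibble::tibble(subject_id = "s1", medication_raw = "Quinipril")
#' process_medications(recs, bundle)
#' @export
process_medications <- function(records, bundle, policy = match_policy(),
                                adapter = offline_adapter(bundle),
                                atc_level = 3L,
                                form_stoplist = default_form_stoplist()) {
  stopifnot(is.data.frame(records), inherits(bundle, "lexicon_bundle"),
            all(c("subject_id", "medication_raw") %in% names(records)),
            length(atc_level) == 1L, atc_level %in% 1:3)
  n <- nrow(records)
  out <- tibble::tibble(
    subject_id = as.character(records$subject_id),
    medication_raw = as.character(records$medication_raw),
    preprocessed = NA_character_,
    status = character(n),
    canonical_name = NA_character_,
    concept_id = NA_character_,
    atc_codes = NA_character_,
    match_distance = NA_integer_,
    match_ratio = NA_real_
  )
  errors <- data.frame(row = integer(0), message = character(0))
  for (i in seq_len(n)) {
    raw <- out$medication_raw[i]
    if (is.na(raw) || !nzchar(trimws(raw))) {
      out$status[i] <- "manual_queue"
      errors <- rbind(errors, data.frame(row = i, message = "empty medication entry"))
      next
    }
    pre <- preprocess_name(raw, form_stoplist)
    out$preprocessed[i] <- pre
    # screen the folded raw entry as well as the preprocessed form:
    # token dropping can remove digits that are part of a supplement
    # name proper (e.g. "omega 3"), not a dose
    if (any(classify_supplement(c(pre, fold(raw)), bundle$supplements,
                                policy))) {
      out$status[i] <- "supplement_excluded"
      next
    }
    hit <- normalize_medication(pre, bundle$drugs, policy)
    if (is.null(hit)) {
      out$status[i] <- "manual_queue"
      next
    }
    classes <- atc_classes(hit$concept_id, level = atc_level, adapter = adapter)
    out$status[i] <- "mapped"
    out$canonical_name[i] <- hit$canonical_name
    out$concept_id[i] <- hit$concept_id
    out$atc_codes[i] <- paste(
      ifelse(is.na(classes$label), classes$code,
             paste0(classes$code, ":", classes$label)),
      collapse = "|"
    )
    out$match_distance[i] <- hit$distance
    out$match_ratio[i] <- hit$ratio
  }
  attr(out, "errors") <- errors
  out
}
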