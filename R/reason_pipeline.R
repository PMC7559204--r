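# Reason branch: per-word spell correction against a general dictionary ->
# Lancaster stemming -> fuzzy lookup of the whole stem string in the
# stem-to-category map (distance AND ratio rule) -> manual queue and
# raw-text overrides from human curation.

#' Spell-correct a single word against a dictionary
#'
#' A word already in the dictionary is returned unchanged. Otherwise the
#' dictionary word with the highest Levenshtein ratio replaces it, provided
#' that ratio strictly exceeds the policy's ratio threshold (ties broken as
#' in [best_match()]); if no word qualifies, the input is returned as is.
#'
#' @param word Character vector of single, case-folded tokens.
#' @param wordlist Character vector dictionary.
#' @param policy A [match_policy()]; only `ratio_threshold` is used here.
#' @return Character vector of corrected words.
#' @examples
#' spell_correct_word("vitemin", c("vitamin", "mineral"))  # "vitamin"
#' @export
spell_correct_word <- function(word, wordlist, policy = match_policy()) {
  stopifnot(is.character(word), is.character(wordlist), length(wordlist) > 0L)
  ratio_only <- match_policy(policy$ratio_threshold, 0L, "any")
  vapply(word, function(w) {
    if (w %in% wordlist) return(w)
    hit <- best_match(w, wordlist, ratio_only)
    if (is.null(hit)) w else hit$candidate
  }, "", USE.NAMES = FALSE)
}

#' Map a stem string to a reason category
#'
#' An exact key hit returns its category with distance 0. Otherwise the best
#' fuzzy match over the dictionary keys is used under the reason rule
#' (by default distance AND ratio must both pass). Multi-word stem strings
#' are compared as whole space-joined strings.
#'
#' @param stem_string A stem string from [stem_text()].
#' @param stem_map Tibble with columns `stem`, `category`.
#' @param policy A [match_policy()]; default is the ALL-combinator reason
#'   rule.
#' @return A list with `category`, `distance`, `ratio`, or `NULL` when no
#'   key passes.
#' @examples
#' sm <- tibble::tibble(stem = "ulc colit", category = "gastrointestinal disease")
#' map_reason("ulc colit", sm)
#' @export
map_reason <- function(stem_string, stem_map,
                       policy = match_policy(combinator = "all")) {
  stopifnot(is.character(stem_string), length(stem_string) == 1L,
            is.data.frame(stem_map), nrow(stem_map) > 0L)
  i <- match(stem_string, stem_map$stem)
  if (!is.na(i)) {
    return(list(category = stem_map$category[i], distance = 0L, ratio = 1.0))
  }
  hit <- best_match(stem_string, stem_map$stem, policy)
  if (is.null(hit)) return(NULL)
  list(
    category = stem_map$category[match(hit$candidate, stem_map$stem)],
    distance = hit$distance,
    ratio = hit$ratio
  )
}

#' Apply manual raw-text overrides to reason results
#'
#' Human curation wins: any result whose raw reason text (case-folded) has
#' an override receives that category with status `overridden`, whatever its
#' prior status; all other rows are unchanged. The operation is idempotent.
#'
#' @param results Tibble from [process_reasons()].
#' @param overrides A data frame with columns `reason_raw`, `category`, or a
#'   named character vector (names = raw text). May be empty.
#' @return The updated tibble.
#' @export
apply_overrides <- function(results, overrides) {
  stopifnot(is.data.frame(results))
  if (is.null(overrides)) return(results)
  if (is.character(overrides)) {
    overrides <- data.frame(reason_raw = names(overrides),
                            category = unname(overrides),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("reason_raw", "category") %in% names(overrides)))
  if (nrow(overrides) == 0L) return(results)
  key <- fold(overrides$reason_raw)
  cat_ <- fold(overrides$category)
  if (any(!nzchar(cat_))) {
    stop("override with empty category for: ",
         key[!nzchar(cat_)][1L], call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("duplicate override key: ", key[duplicated(key)][1L], call. = FALSE)
  }
  i <- match(fold(results$reason_raw), key)
  hit <- !is.na(i)
  results$category[hit] <- cat_[i[hit]]
  results$status[hit] <- "overridden"
  results$match_distance[hit] <- NA_integer_
  results$match_ratio[hit] <- NA_real_
  results
}

#' Read a manual override table
#' @param path TSV file with columns `reason_raw`, `category`.
#' @return A data frame.
#' @export
read_overrides <- function(path) {
  if (!file.exists(path)) stop("override file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  if (!all(c("reason_raw", "category") %in% names(raw))) {
    stop("override table must have columns reason_raw, category", call. = FALSE)
  }
  raw
}

#' Run the reason branch over a batch of records
#'
#' Per record: case-fold and tokenize the raw reason, spell-correct each
#' word against the general dictionary, stem the corrected text, look the
#' whole stem string up in the stem-to-category map, then apply any manual
#' overrides. Statuses (`auto`, `manual_queue`, `overridden`) partition the
#' input. Records with empty reason text are collected as errors (attribute
#' `"errors"`) and queued for manual review.
#'
#' @param records Data frame with columns `subject_id`, `reason_raw`.
#' @param bundle A validated `lexicon_bundle` (uses `wordlist`, `stem_map`).
#' @param policy Reason-matching [match_policy()] (default ALL: distance AND
#'   ratio).
#' @param rules A `stem_rules` table; default [lancaster_rules()].
#' @param overrides Optional override table (see [apply_overrides()]).
#' @return A tibble with columns `subject_id`, `reason_raw`, `corrected`,
#'   `stem_string`, `status`, `category`, `match_distance`, `match_ratio`.
#' @examples
#' bundle <- load_bundle(system.file("extdata", "lexicon", package = "medmapr"))
#' recs <- tibble::tibble(subject_id = "s1", reason_raw = "ulcerative colitis")
#' process_reasons(recs, bundle)
#' @export
process_reasons <- function(records, bundle,
                            policy = match_policy(combinator = "all"),
                            rules = lancaster_rules(), overrides = NULL) {
  stopifnot(is.data.frame(records), inherits(bundle, "lexicon_bundle"),
            all(c("subject_id", "reason_raw") %in% names(records)))
  n <- nrow(records)
  out <- tibble::tibble(
    subject_id = as.character(records$subject_id),
    reason_raw = as.character(records$reason_raw),
    corrected = NA_character_,
    stem_string = NA_character_,
    status = character(n),
    category = NA_character_,
    match_distance = NA_integer_,
    match_ratio = NA_real_
  )
  errors <- data.frame(row = integer(0), message = character(0))
  for (i in seq_len(n)) {
    raw <- out$reason_raw[i]
    if (is.na(raw) || !nzchar(trimws(raw))) {
      out$status[i] <- "manual_queue"
      errors <- rbind(errors, data.frame(row = i, message = "empty reason entry"))
      next
    }
    folded <- fold(gsub("[^[:alnum:][:space:]]", " ", fold(raw)))
    toks <- strsplit(folded, " ", fixed = TRUE)[[1L]]
    corrected <- paste(spell_correct_word(toks, bundle$wordlist, policy),
                       collapse = " ")
    out$corrected[i] <- corrected
    out$stem_string[i] <- stem_text(corrected, rules)
    hit <- map_reason(out$stem_string[i], bundle$stem_map, policy)
    if (is.null(hit)) {
      out$status[i] <- "manual_queue"
    } else {
      out$status[i] <- "auto"
      out$category[i] <- hit$category
      out$match_distance[i] <- hit$distance
      out$match_ratio[i] <- hit$ratio
    }
  }
  out <- apply_overrides(out, overrides)
  attr(out, "errors") <- errors
  out
}
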