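# Knowledge sources: drug lexicon with ATC codes, supplement lexicon,
# stem-to-category map, general word list. File-backed (TSV or JSON); all
# text is case-folded and whitespace-collapsed on load.

fold <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Validate ATC codes at levels 1 to 3
#'
#' Level 1 is the anatomical main group (one letter), level 2 the therapeutic
#' main group (letter + two digits), level 3 the therapeutic/pharmacologic
#' subgroup (letter + two digits + letter).
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector.
#' @examples
#' is_valid_atc(c("C07A", "C07", "C", "ZZ99X9"))  # TRUE TRUE TRUE FALSE
#' @export
is_valid_atc <- function(code) {
  grepl("^[A-Z]([0-9]{2}([A-Z])?)?$", code)
}

#' ATC level of a code
#' @param code Character vector of valid level 1-3 codes.
#' @return Integer vector: 1, 2 or 3.
#' @export
atc_level <- function(code) {
  stopifnot(all(is_valid_atc(code)))
  c(`1` = 1L, `3` = 2L, `4` = 3L)[as.character(nchar(code))]
}

#' Truncate ATC codes to a level
#'
#' Truncating to level `k` then to `j < k` equals truncating directly to
#' `j`. Codes already at or below the requested level are unchanged.
#'
#' @param code Character vector of valid codes.
#' @param level Target level, 1, 2 or 3.
#' @return Character vector of truncated codes.
#' @export
atc_truncate <- function(code, level) {
  stopifnot(all(is_valid_atc(code)), length(level) == 1L, level %in% 1:3)
  width <- c(1L, 3L, 4L)[level]
  ifelse(nchar(code) > width, substr(code, 1L, width), code)
}

# parse "CODE:label|CODE:label" into a data frame
.parse_atc_field <- function(field) {
  if (is.na(field) || !nzchar(field)) {
    return(data.frame(code = character(0), label = character(0)))
  }
  parts <- strsplit(field, "|", fixed = TRUE)[[1L]]
  code <- sub(":.*$", "", parts)
  label <- ifelse(grepl(":", parts), sub("^[^:]*:", "", parts), NA_character_)
  data.frame(code = toupper(trimws(code)), label = fold(label),
             stringsAsFactors = FALSE)
}

.parse_syn_field <- function(field) {
  if (is.na(field) || !nzchar(field)) return(character(0))
  s <- fold(strsplit(field, "|", fixed = TRUE)[[1L]])
  unique(s[nzchar(s)])
}

#' Read a drug lexicon table
#'
#' Expects columns `canonical_name`, `synonyms` (pipe-separated),
#' `concept_id`, `atc_codes` (pipe-separated `code:label` pairs). Names and
#' synonyms are case-folded; a canonical name listed among its own synonyms
#' is dropped from the synonyms. Duplicate canonical names and malformed ATC
#' codes are load-time errors naming the offending line.
#'
#' @param path Path to a TSV file (header row required).
#' @return A tibble with list-columns `synonyms` and `atc` (each `atc` a
#'   data frame of `code`, `label`).
#' @export
read_drug_lexicon <- function(path) {
  if (!file.exists(path)) stop("drug lexicon file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  needed <- c("canonical_name", "synonyms", "concept_id", "atc_codes")
  if (!all(needed %in% names(raw))) {
    stop("drug lexicon must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("drug lexicon is empty: ", path, call. = FALSE)
  canonical <- fold(raw$canonical_name)
  if (any(!nzchar(canonical))) {
    stop("empty canonical_name at line ", which(!nzchar(canonical))[1L] + 1L,
         " of ", path, call. = FALSE)
  }
  if (anyDuplicated(canonical)) {
    stop("duplicate canonical_name '", canonical[duplicated(canonical)][1L],
         "' at line ", which(duplicated(canonical))[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  atc <- vector("list", nrow(raw))
  syn <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    a <- .parse_atc_field(raw$atc_codes[i])
    if (any(!is_valid_atc(a$code))) {
      stop("invalid ATC code '", a$code[!is_valid_atc(a$code)][1L],
           "' at line ", i + 1L, " of ", path, call. = FALSE)
    }
    atc[[i]] <- a
    syn[[i]] <- setdiff(.parse_syn_field(raw$synonyms[i]), canonical[i])
  }
  tibble::tibble(
    canonical_name = canonical,
    synonyms = syn,
    concept_id = trimws(raw$concept_id),
    atc = atc
  )
}

#' Read a supplement lexicon (one name per line)
#' @param path Path to a text file; blank lines and `#` comments ignored.
#' @return Character vector of unique, case-folded supplement names.
#' @export
read_supplement_lexicon <- function(path) {
  if (!file.exists(path)) stop("supplement lexicon file not found: ", path, call. = FALSE)
  x <- readLines(path, encoding = "UTF-8")
  x <- fold(x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")])
  unique(x)
}

#' Read a stem-to-category map
#'
#' Expects columns `stem` and `category`. Keys are whole space-joined stem
#' strings (e.g. `"ulc colit"`), matched as complete strings, not word by
#' word.
#'
#' @param path Path to a TSV file (header row required).
#' @return A tibble with columns `stem`, `category`.
#' @export
read_stem_map <- function(path) {
  if (!file.exists(path)) stop("stem map file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  if (!all(c("stem", "category") %in% names(raw))) {
    stop("stem map must have columns stem, category", call. = FALSE)
  }
  stem <- fold(raw$stem)
  category <- fold(raw$category)
  if (any(!nzchar(category))) {
    stop("empty category at line ", which(!nzchar(category))[1L] + 1L, " of ",
         path, call. = FALSE)
  }
  if (anyDuplicated(stem)) {
    stop("duplicate stem key '", stem[duplicated(stem)][1L], "' in ", path,
         call. = FALSE)
  }
  tibble::tibble(stem = stem, category = category)
}

#' Read a general word list (one word per line)
#' @param path Path to a text file.
#' @return Character vector of unique, case-folded words.
#' @export
read_wordlist <- function(path) {
  if (!file.exists(path)) stop("word list file not found: ", path, call. = FALSE)
  x <- readLines(path, encoding = "UTF-8")
  x <- fold(x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")])
  if (length(x) == 0L) stop("word list is empty: ", path, call. = FALSE)
  unique(x)
}

#' Load a complete lexicon bundle from a directory
#'
#' Reads `drugs`, `supplements`, `stem_map` and `wordlist` files and
#' validates cross-file invariants: no name may appear both as a drug
#' canonical name and as a supplement name, and no search name (canonical or
#' synonym) may be claimed by two drug entries.
#'
#' @param dir Directory containing the lexicon files.
#' @param format `"tsv"` (files `drugs.tsv`, `supplements.tsv`,
#'   `stem_map.tsv`, `wordlist.txt`) or `"json"` (a single `lexicon.json`
#'   with the same field names).
#' @return An object of class `lexicon_bundle`: a list with elements
#'   `drugs`, `supplements`, `stem_map`, `wordlist`.
#' @examples
#' bundle <- load_bundle(system.file("extdata", "lexicon", package = "medmapr"))
#' bundle
#' @export
load_bundle <- function(dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    bundle <- list(
      drugs = read_drug_lexicon(file.path(dir, "drugs.tsv")),
      supplements = read_supplement_lexicon(file.path(dir, "supplements.tsv")),
      stem_map = read_stem_map(file.path(dir, "stem_map.tsv")),
      wordlist = read_wordlist(file.path(dir, "wordlist.txt"))
    )
  } else {
    path <- file.path(dir, "lexicon.json")
    if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    drugs <- tibble::tibble(
      canonical_name = fold(vapply(j$drugs, `[[`, "", "canonical_name")),
      synonyms = lapply(j$drugs, function(d) {
        s <- fold(unlist(d$synonyms, use.names = FALSE))
        unique(s[nzchar(s)])
      }),
      concept_id = vapply(j$drugs, `[[`, "", "concept_id"),
      atc = lapply(j$drugs, function(d) {
        codes <- toupper(vapply(d$atc_codes, `[[`, "", "code"))
        if (any(!is_valid_atc(codes))) {
          stop("invalid ATC code '", codes[!is_valid_atc(codes)][1L],
               "' in ", path, call. = FALSE)
        }
        data.frame(code = codes,
                   label = fold(vapply(d$atc_codes, `[[`, "", "label")),
                   stringsAsFactors = FALSE)
      })
    )
    if (nrow(drugs) == 0L) stop("drug lexicon is empty: ", path, call. = FALSE)
    if (anyDuplicated(drugs$canonical_name)) {
      stop("duplicate canonical_name in ", path, call. = FALSE)
    }
    drugs$synonyms <- Map(setdiff, drugs$synonyms, drugs$canonical_name)
    sm <- j$stem_map
    bundle <- list(
      drugs = drugs,
      supplements = unique(fold(unlist(j$supplements, use.names = FALSE))),
      stem_map = tibble::tibble(
        stem = fold(vapply(sm, `[[`, "", "stem")),
        category = fold(vapply(sm, `[[`, "", "category"))
      ),
      wordlist = unique(fold(unlist(j$wordlist, use.names = FALSE)))
    )
    if (anyDuplicated(bundle$stem_map$stem)) {
      stop("duplicate stem key in ", path, call. = FALSE)
    }
  }
  validate_bundle(structure(bundle, class = "lexicon_bundle"))
}

#' Validate a lexicon bundle's cross-file invariants
#' @param bundle A `lexicon_bundle`.
#' @return The bundle, invisibly-checked (errors on violation). Entries with
#'   no ATC codes are permitted but flagged with a warning.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "lexicon_bundle"))
  clash <- intersect(bundle$drugs$canonical_name, bundle$supplements)
  if (length(clash) > 0L) {
    stop("name(s) present in both drug and supplement lexicons: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  search <- c(bundle$drugs$canonical_name,
              unlist(bundle$drugs$synonyms, use.names = FALSE))
  if (anyDuplicated(search)) {
    stop("search name claimed by more than one drug entry: ",
         search[duplicated(search)][1L], call. = FALSE)
  }
  no_atc <- vapply(bundle$drugs$atc, nrow, 1L) == 0L
  if (any(no_atc)) {
    warning("drug entries without ATC codes: ",
            paste(bundle$drugs$canonical_name[no_atc], collapse = ", "),
            call. = FALSE)
  }
  bundle
}

#' Write a lexicon bundle back to disk
#'
#' Inverse of [load_bundle()]: `load_bundle(save_bundle(b, dir))` returns a
#' bundle identical to `b` for both formats.
#'
#' @param bundle A validated `lexicon_bundle`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"`.
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "lexicon_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "tsv") {
    drugs <- data.frame(
      canonical_name = bundle$drugs$canonical_name,
      synonyms = vapply(bundle$drugs$synonyms, paste, "", collapse = "|"),
      concept_id = bundle$drugs$concept_id,
      atc_codes = vapply(bundle$drugs$atc, function(a) {
        paste(paste0(a$code, ":", a$label), collapse = "|")
      }, ""),
      stringsAsFactors = FALSE
    )
    utils::write.table(drugs, file.path(dir, "drugs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    writeLines(bundle$supplements, file.path(dir, "supplements.tsv"))
    utils::write.table(as.data.frame(bundle$stem_map),
                       file.path(dir, "stem_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    writeLines(bundle$wordlist, file.path(dir, "wordlist.txt"))
  } else {
    obj <- list(
      drugs = lapply(seq_len(nrow(bundle$drugs)), function(i) {
        list(
          canonical_name = bundle$drugs$canonical_name[i],
          synonyms = as.list(bundle$drugs$synonyms[[i]]),
          concept_id = bundle$drugs$concept_id[i],
          atc_codes = lapply(seq_len(nrow(bundle$drugs$atc[[i]])), function(k) {
            list(code = bundle$drugs$atc[[i]]$code[k],
                 label = bundle$drugs$atc[[i]]$label[k])
          })
        )
      }),
      supplements = as.list(bundle$supplements),
      stem_map = lapply(seq_len(nrow(bundle$stem_map)), function(i) {
        list(stem = bundle$stem_map$stem[i],
             category = bundle$stem_map$category[i])
      }),
      wordlist = as.list(bundle$wordlist)
    )
    jsonlite::write_json(obj, file.path(dir, "lexicon.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' @export
print.lexicon_bundle <- function(x, ...) {
  cat(sprintf(
    "<lexicon_bundle> %d drugs, %d supplements, %d stem keys, %d dictionary words\n",
    nrow(x$drugs), length(x$supplements), nrow(x$stem_map), length(x$wordlist)
  ))
  invisible(x)
}

# ---- ontology adapter -------------------------------------------------------

#' Offline ontology adapter backed by a loaded lexicon bundle
#'
#' The adapter contract decouples concept resolution and ATC lookup from any
#' specific backend. This offline adapter answers from the drug table of a
#' loaded bundle; a remote adapter implementing the same two functions could
#' answer from a live terminology service instead.
#'
#' @param bundle A validated `lexicon_bundle`.
#' @return An object of class `ontology_adapter` with functions
#'   `resolve(name)` and `atc(concept_id)`.
#' @export
offline_adapter <- function(bundle) {
  stopifnot(inherits(bundle, "lexicon_bundle"))
  drugs <- bundle$drugs
  structure(
    list(
      resolve = function(name) {
        i <- match(fold(name), drugs$canonical_name)
        if (is.na(i)) NULL else drugs$concept_id[i]
      },
      atc = function(concept_id) {
        i <- match(concept_id, drugs$concept_id)
        if (is.na(i)) {
          stop("unknown concept id: ", concept_id, call. = FALSE)
        }
        drugs$atc[[i]]
      }
    ),
    class = "ontology_adapter"
  )
}

#' Resolve a canonical drug name to its concept identifier
#'
#' @param name A canonical drug name (case-folded internally).
#' @param adapter An `ontology_adapter`.
#' @return The concept id string, or `NULL` when the adapter does not know
#'   the name. A backend failure (e.g. an unreachable remote service) is an
#'   error, never a silent `NULL`.
#' @export
resolve_concept <- function(name, adapter) {
  stopifnot(inherits(adapter, "ontology_adapter"),
            is.character(name), length(name) == 1L)
  adapter$resolve(name)
}

#' ATC classes for a concept, truncated to a level
#'
#' Returns all ATC codes recorded for the concept, truncated to the
#' requested level and deduplicated after truncation (one drug can map to
#' multiple ATC codes). A truncated code keeps its label only when
#' truncation left it unchanged.
#'
#' @param concept_id Concept identifier known to the adapter.
#' @param level ATC level 1, 2 or 3 (default 3, the therapeutic class).
#' @param adapter An `ontology_adapter`.
#' @return A data frame with columns `code`, `label`.
#' @export
atc_classes <- function(concept_id, level = 3L, adapter) {
  stopifnot(length(level) == 1L, level %in% 1:3)
  a <- adapter$atc(concept_id)
  if (nrow(a) == 0L) return(a)
  trunc <- atc_truncate(a$code, level)
  label <- ifelse(trunc == a$code, a$label, NA_character_)
  out <- data.frame(code = trunc, label = label, stringsAsFactors = FALSE)
  out[!duplicated(out$code), , drop = FALSE]
}
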