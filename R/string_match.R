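#' Fuzzy-match acceptance policy
#'
#' A match policy bundles the two thresholds and the rule that combines them.
#' The drug-matching rule accepts a candidate when the Levenshtein ratio
#' exceeds `ratio_threshold` *or* the Levenshtein distance is strictly below
#' `distance_threshold` (`combinator = "any"`); the reason-matching rule
#' requires *both* conditions (`combinator = "all"`). Both comparisons are
#' strict: "over 0.85" means `> 0.85`, "less than 2" means `<= 1`.
#'
#' @param ratio_threshold Minimum similarity ratio in `[0, 1]`, exceeded
#'   strictly. Default 0.85.
#' @param distance_threshold Edit-distance bound, strict upper bound
#'   (a nonnegative integer). Default 2, i.e. distances 0 and 1 pass.
#' @param combinator `"any"` (either condition suffices) or `"all"`
#'   (both required).
#' @return An object of class `match_policy`.
#' @examples
#' match_policy()                       # drug rule: ratio OR distance
#' match_policy(combinator = "all")     # reason rule: ratio AND distance
#' @export
match_policy <- function(ratio_threshold = 0.85,
                         distance_threshold = 2L,
                         combinator = c("any", "all")) {
  combinator <- match.arg(combinator)
  stopifnot(
    is.numeric(ratio_threshold), length(ratio_threshold) == 1L,
    ratio_threshold >= 0, ratio_threshold <= 1,
    is.numeric(distance_threshold), length(distance_threshold) == 1L,
    distance_threshold >= 0, distance_threshold == as.integer(distance_threshold)
  )
  structure(
    list(
      ratio_threshold = as.numeric(ratio_threshold),
      distance_threshold = as.integer(distance_threshold),
      combinator = combinator
    ),
    class = "match_policy"
  )
}

#' @export
print.match_policy <- function(x, ...) {
  cat(sprintf(
    "<match_policy> ratio > %g %s distance < %d\n",
    x$ratio_threshold, if (x$combinator == "any") "OR" else "AND",
    x$distance_threshold
  ))
  invisible(x)
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming `a` into `b`. Vectorised over both arguments with the usual
#' recycling; strings are compared character-wise (UTF-8 aware), verbatim —
#' no case folding is applied here.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @examples
#' levenshtein_distance("kitten", "sitting")      # 3
#' levenshtein_distance("metoprolol", "metoprold") # 2
#' @export
levenshtein_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  .lev_distance_cpp(a, b)
}

#' Levenshtein similarity ratio
#'
#' The normalized similarity `((|a| + |b|) - lev(a, b)) / (|a| + |b|)`, a
#' value in `[0, 1]` that is 1 exactly when the strings are equal (two empty
#' strings are defined to have ratio 1). Note this uses the unit-cost
#' distance; it is *not* the substitution-cost-2 ratio of some common fuzzy
#' matching libraries, so e.g. `levenshtein_ratio("ab", "ac")` is 0.75, not
#' 0.5.
#'
#' @inheritParams levenshtein_distance
#' @return Numeric vector of ratios in `[0, 1]`.
#' @examples
#' levenshtein_ratio("metoprolol", "metoprold")  # 17/19
#' @export
levenshtein_ratio <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  if (length(a) == 0L || length(b) == 0L) return(numeric(0))
  d <- .lev_distance_cpp(a, b)
  tot <- nchar(rep_len(a, length(d)), type = "chars") +
    nchar(rep_len(b, length(d)), type = "chars")
  ifelse(tot == 0L, 1.0, (tot - d) / tot)
}

#' Does a (distance, ratio) pair satisfy a match policy?
#'
#' @param distance Nonnegative integer edit distance(s).
#' @param ratio Similarity ratio(s) in `[0, 1]`.
#' @param policy A [match_policy()].
#' @return Logical vector.
#' @examples
#' passes_policy(2, 17/19, match_policy())        # TRUE: ratio clause
#' passes_policy(2, 17/19, match_policy(combinator = "all"))  # FALSE
#' @export
passes_policy <- function(distance, ratio, policy = match_policy()) {
  stopifnot(inherits(policy, "match_policy"),
            all(distance >= 0, na.rm = TRUE),
            all(ratio >= 0 & ratio <= 1, na.rm = TRUE))
  r <- ratio > policy$ratio_threshold
  d <- distance < policy$distance_threshold
  if (policy$combinator == "any") r | d else r & d
}

#' Best accepted fuzzy match among candidates
#'
#' Evaluates every candidate against the query and returns the accepted one
#' with maximal ratio; ties are broken by minimal distance, then by
#' lexicographically smallest candidate (in the C locale), so the result is
#' deterministic and independent of candidate order. Comparison is verbatim:
#' case-fold and collapse whitespace upstream.
#'
#' @param query Single string.
#' @param candidates Non-empty character vector of candidate names.
#' @param policy A [match_policy()].
#' @return A one-row tibble with columns `candidate`, `distance`, `ratio`,
#'   `accepted`, or `NULL` when no candidate passes the policy.
#' @examples
#' best_match("fexafenedine", c("fexofenadine", "quinapril"))
#' @export
best_match <- function(query, candidates, policy = match_policy()) {
  stopifnot(is.character(query), length(query) == 1L, !is.na(query))
  if (!is.character(candidates) || length(candidates) == 0L) {
    stop("`candidates` must be a non-empty character vector", call. = FALSE)
  }
  d <- .lev_distance_cpp(candidates, query)
  tot <- nchar(candidates, type = "chars") + nchar(query, type = "chars")
  r <- ifelse(tot == 0L, 1.0, (tot - d) / tot)
  ok <- passes_policy(d, r, policy)
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  # order: max ratio, then min distance, then lexicographic; radix sorting
  # compares strings in the C locale, so ties break identically everywhere
  o <- idx[order(-r[idx], d[idx], candidates[idx], method = "radix")][1L]
  tibble::tibble(
    candidate = candidates[o],
    distance = as.integer(d[o]),
    ratio = r[o],
    accepted = TRUE
  )
}
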