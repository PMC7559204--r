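# Feature-set summary reporting and TSV/JSON output writers.

#' Summarize a pipeline run
#'
#' Computes the feature-set sizes of a run: record counts before and after
#' supplement removal, distinct raw terms (after case folding and whitespace
#' collapse), category counts over the mapped outputs, and the percentage of
#' distinct terms that still require manual mapping. Percentages follow the
#' distinct-terms convention; the medication denominator excludes
#' supplement-excluded terms.
#'
#' @param med_results Tibble from [process_medications()].
#' @param reason_results Tibble from [process_reasons()].
#' @return An object of class `summary_report`: a list with fields
#'   `n_records`, `n_after_supplement_removal`, `n_distinct_raw_medications`,
#'   `n_medication_categories`, `n_distinct_raw_reasons`,
#'   `n_reason_categories`, `pct_medications_manual`, `pct_reasons_manual`.
#' @export
summarize_run <- function(med_results, reason_results) {
  stopifnot(is.data.frame(med_results), is.data.frame(reason_results))
  med_terms <- fold(med_results$medication_raw)
  non_supp <- med_results$status != "supplement_excluded"
  mapped <- med_results$status == "mapped"
  codes <- unlist(lapply(med_results$atc_codes[mapped], function(s) {
    if (is.na(s)) return(character(0))
    sub(":.*$", "", strsplit(s, "|", fixed = TRUE)[[1L]])
  }), use.names = FALSE)
  reason_terms <- fold(reason_results$reason_raw)
  reason_auto <- reason_results$status %in% c("auto", "overridden")
  n_terms_nonsupp <- length(unique(med_terms[non_supp]))
  med_manual_terms <- setdiff(unique(med_terms[med_results$status == "manual_queue"]),
                              unique(med_terms[mapped]))
  reason_manual_terms <- setdiff(
    unique(reason_terms[reason_results$status == "manual_queue"]),
    unique(reason_terms[reason_auto])
  )
  rep_ <- list(
    n_records = nrow(med_results),
    n_after_supplement_removal = sum(non_supp),
    n_distinct_raw_medications = length(unique(med_terms)),
    n_medication_categories = length(unique(codes)),
    n_distinct_raw_reasons = length(unique(reason_terms)),
    n_reason_categories = length(unique(
      reason_results$category[reason_auto & !is.na(reason_results$category)])),
    pct_medications_manual = if (n_terms_nonsupp == 0L) 0 else
      100 * length(med_manual_terms) / n_terms_nonsupp,
    pct_reasons_manual = if (length(unique(reason_terms)) == 0L) 0 else
      100 * length(reason_manual_terms) / length(unique(reason_terms))
  )
  stopifnot(rep_$n_after_supplement_removal <= rep_$n_records,
            rep_$pct_medications_manual >= 0, rep_$pct_medications_manual <= 100,
            rep_$pct_reasons_manual >= 0, rep_$pct_reasons_manual <= 100)
  structure(rep_, class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  cat(sprintf("  records: %d (%d after supplement removal)\n",
              x$n_records, x$n_after_supplement_removal))
  cat(sprintf("  medications: %d distinct raw -> %d categories (%.1f%% manual)\n",
              x$n_distinct_raw_medications, x$n_medication_categories,
              x$pct_medications_manual))
  cat(sprintf("  reasons: %d distinct raw -> %d categories (%.1f%% manual)\n",
              x$n_distinct_raw_reasons, x$n_reason_categories,
              x$pct_reasons_manual))
  invisible(x)
}

#' Read a records table
#' @param path TSV with columns `subject_id`, `medication_raw`,
#'   `reason_raw` (header required).
#' @return A tibble.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  needed <- c("subject_id", "medication_raw", "reason_raw")
  if (!all(needed %in% names(raw))) {
    stop("records file must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(raw)
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  # list columns are not serializable; drop them
  df <- df[vapply(df, is.atomic, NA)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write pipeline outputs to a directory
#'
#' Emits `medications.tsv`, `reasons.tsv`, `manual_queue.tsv` (the
#' unresolved rows of both branches) and `report.json`. Outputs contain no
#' timestamps, so identical inputs give byte-identical files.
#'
#' @param med_results,reason_results Pipeline result tibbles.
#' @param report A `summary_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(med_results, reason_results, report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(med_results, file.path(out_dir, "medications.tsv"))
  .write_tsv(reason_results, file.path(out_dir, "reasons.tsv"))
  mq_med <- med_results[med_results$status == "manual_queue",
                        c("subject_id", "medication_raw")]
  mq_reason <- reason_results[reason_results$status == "manual_queue",
                              c("subject_id", "reason_raw")]
  mq <- merge(
    data.frame(branch = rep("medication", nrow(mq_med)),
               subject_id = mq_med$subject_id, raw = mq_med$medication_raw),
    data.frame(branch = rep("reason", nrow(mq_reason)),
               subject_id = mq_reason$subject_id, raw = mq_reason$reason_raw),
    all = TRUE, sort = FALSE
  )
  mq <- mq[order(mq$branch, mq$subject_id, mq$raw, method = "radix"), ,
           drop = FALSE]
  .write_tsv(mq, file.path(out_dir, "manual_queue.tsv"))
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
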