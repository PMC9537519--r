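# Concordance arithmetic for CNV-call evaluation against orthogonal truth
# sets (diagnostic testing, WGS, population CNV maps). Percentages are
# rounded half-up to one decimal, the convention used when such rates are
# printed.

.round1 <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10

#' Detection sensitivity
#'
#' Percentage of truth-set CNVs that were detected: `100 * detected / truth`,
#' rounded half-up to one decimal.
#'
#' @param truth_count number of truth-set CNVs (> 0).
#' @param detected_count number of those detected (0..truth_count).
#' @return Percent, one decimal.
#' @examples
#' sensitivity_pct(1138, 678)  # 59.6
#' @export
sensitivity_pct <- function(truth_count, detected_count) {
  stopifnot(truth_count > 0, detected_count >= 0, detected_count <= truth_count)
  .round1(100 * detected_count / truth_count)
}

#' Call support rate
#'
#' Percentage of called CNVs corroborated by the orthogonal truth source:
#' `100 * (called - unsupported) / called`. This is a precision-type
#' quantity, sometimes reported as a detection "specificity" in call
#' evaluations against diagnostic truth sets.
#'
#' @param called_count number of calls (> 0).
#' @param unsupported_count calls without truth support (0..called_count).
#' @return Percent, one decimal.
#' @examples
#' support_rate_pct(183, 28)  # 84.7
#' @export
support_rate_pct <- function(called_count, unsupported_count) {
  stopifnot(called_count > 0, unsupported_count >= 0,
            unsupported_count <= called_count)
  .round1(100 * (called_count - unsupported_count) / called_count)
}

#' Simple proportion as a percent
#'
#' `100 * numerator / denominator`, one decimal, half-up.
#'
#' @param numerator,denominator counts, `denominator > 0`.
#' @return Percent, one decimal.
#' @examples
#' proportion_pct(10, 14)  # 71.4
#' @export
proportion_pct <- function(numerator, denominator) {
  stopifnot(denominator > 0)
  .round1(100 * numerator / denominator)
}

#' Label calls as supported by a truth set
#'
#' A call is supported iff a truth interval of the same CNV type on the
#' same chromosome overlaps it by one or more base pairs (type-aware:
#' a deletion call over a duplication truth interval is unsupported).
#'
#' @param calls a [cnv_calls()] table.
#' @param truth a [cnv_calls()]-like table of truth intervals.
#' @return Logical vector, one element per call.
#' @export
match_calls <- function(calls, truth) {
  supported <- rep(FALSE, nrow(calls))
  for (type in c("deletion", "duplication")) {
    qi <- which(calls$cnv_type == type)
    ti <- which(truth$cnv_type == type)
    if (!length(qi) || !length(ti)) next
    hits <- .overlaps(.calls_granges(calls[qi, , drop = FALSE]),
                      .calls_granges(truth[ti, , drop = FALSE]))
    supported[qi[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  supported
}

#' Concordance report against a truth set
#'
#' Counts detections in both directions: `sensitivity` is the percentage of
#' truth intervals overlapped by a same-type call, `support_rate` the
#' percentage of calls overlapped by a same-type truth interval.
#'
#' @param calls a [cnv_calls()] table.
#' @param truth a [cnv_calls()]-like truth table.
#' @param by_sample if `TRUE`, overlap is additionally required to be within
#'   the same sample.
#' @return list of class `concordance_report` with `n_truth`, `n_detected`,
#'   `n_called`, `n_unsupported`, `sensitivity`, `support_rate`.
#' @export
concordance_report <- function(calls, truth, by_sample = TRUE) {
  if (by_sample) {
    # fold the sample into the sequence name so one interval query does the
    # sample-restricted, type-aware overlap
    key <- function(df) {
      out <- as.data.frame(df)
      out$chrom <- paste(out$sample_id, df$chrom, df$cnv_type, sep = "|")
      out
    }
    grc <- GenomicRanges::GRanges(key(calls)$chrom,
                                  IRanges::IRanges(calls$start, calls$end))
    grt <- GenomicRanges::GRanges(key(truth)$chrom,
                                  IRanges::IRanges(truth$start, truth$end))
    hits_ct <- .overlaps(grc, grt)
    supported <- length(unique(S4Vectors::queryHits(hits_ct)))
    detected <- length(unique(S4Vectors::subjectHits(hits_ct)))
    n_truth <- nrow(truth); n_called <- nrow(calls)
  } else {
    n_truth <- nrow(truth); n_called <- nrow(calls)
    detected <- sum(match_calls(truth, calls))
    supported <- sum(match_calls(calls, truth))
  }
  structure(list(
    n_truth = n_truth, n_detected = detected,
    n_called = n_called, n_unsupported = n_called - supported,
    sensitivity = if (n_truth > 0) sensitivity_pct(n_truth, detected) else NA,
    support_rate = if (n_called > 0) support_rate_pct(n_called, n_called - supported)
                   else NA
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Truth CNVs: %d, detected: %d (sensitivity %.1f%%)\n",
              x$n_truth, x$n_detected, x$sensitivity))
  cat(sprintf("Called CNVs: %d, unsupported: %d (support rate %.1f%%)\n",
              x$n_called, x$n_unsupported, x$support_rate))
  invisible(x)
}
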