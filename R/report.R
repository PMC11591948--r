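# Ranked RBP tables, event classification and cross-condition aggregation.

#' Rank RBPs by enrichment p-value
#'
#' Stable sort by (pvalue ascending, |statistic| descending, RBP name);
#' rank is the 1-based position and the percentile is
#' \code{floor(100 * (1 - rank/S)) / 100} — rank 1 of 244 prints 0.99, the
#' last rank prints 0.00. BH-adjusted p-values are appended.
#'
#' @param results One method's enrichment table (must contain \code{rbp},
#'   \code{pvalue}, \code{statistic} and a single \code{method} value).
#' @return \code{data.frame}: \code{rbp, method, statistic, pvalue, rank,
#'   percentile, bh_adjusted_pvalue}, ordered by rank.
#' @export
rank_rbps <- function(results) {
  if (!nrow(results)) stop_sfe("empty results table")
  if (length(unique(results$method)) != 1L) {
    stop_sfe("rank_rbps() ranks one method at a time")
  }
  if (anyDuplicated(results$rbp)) stop_sfe("duplicate RBP within a method")
  check_pvalues(results$pvalue)
  ord <- order(results$pvalue, -abs(results$statistic), results$rbp)
  S <- nrow(results)
  out <- data.frame(
    rbp = results$rbp[ord],
    method = results$method[ord],
    statistic = results$statistic[ord],
    pvalue = results$pvalue[ord],
    rank = seq_len(S),
    percentile = floor(100 * (1 - seq_len(S) / S)) / 100,
    bh_adjusted_pvalue = bh_adjust(results$pvalue)[ord],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Classify events for volcano-style reporting
#'
#' Partitions events into \code{significant_large} (p below cutoff and
#' |delta PSI| above cutoff), \code{significant_small}, \code{large_only}
#' and \code{neither}. Events without a delta-PSI value are labelled
#' \code{neither} with a warning.
#'
#' @param stats Stats table with \code{delta_psi}.
#' @param p_cut P-value cutoff (default 1e-3, strict \code{<}).
#' @param dpsi_cut |delta PSI| cutoff (default 0.1, strict \code{>}).
#' @return The stats table with an added factor column \code{label}.
#' @export
classify_events <- function(stats, p_cut = 1e-3, dpsi_cut = 0.1) {
  check_pvalues(stats$pvalue)
  miss <- is.na(stats$delta_psi)
  if (any(miss)) {
    warning(sprintf("%d events without delta_psi labelled 'neither'", sum(miss)),
            call. = FALSE)
  }
  sig <- stats$pvalue < p_cut
  large <- !miss & abs(stats$delta_psi) > dpsi_cut
  label <- rep("neither", nrow(stats))
  label[sig & large] <- "significant_large"
  label[sig & !large] <- "significant_small"
  label[!sig & large] <- "large_only"
  label[miss] <- "neither"
  stats$label <- factor(label, levels = c("significant_large", "significant_small",
                                          "large_only", "neither"))
  stats
}

#' Top differentially spliced events
#'
#' The n events with the smallest p-values; ties broken by |delta PSI|
#' descending, then event id. Asking for more events than exist returns
#' all of them.
#'
#' @param stats Stats table.
#' @param n Number of events (default 5).
#' @return \code{data.frame} with \code{event_id, pvalue, delta_psi}.
#' @export
top_events <- function(stats, n = 5L) {
  if (!nrow(stats)) stop_sfe("empty stats table")
  dpsi <- ifelse(is.na(stats$delta_psi), 0, abs(stats$delta_psi))
  ord <- order(stats$pvalue, -dpsi, stats$event_id)
  take <- ord[seq_len(min(n, nrow(stats)))]
  out <- stats[take, c("event_id", "pvalue", "delta_psi")]
  rownames(out) <- NULL
  out
}

#' Aggregate enrichment calls across conditions
#'
#' Builds a binary RBP x condition matrix (1 = BH-adjusted p-value at or
#' below \code{level} in that condition) and lists the RBPs recurrently
#' enriched in at least \code{min_conditions} conditions.
#'
#' @param tables Named list of \code{\link{rank_rbps}} tables, one per
#'   condition; names are the condition labels.
#' @param level Enrichment call cutoff on the BH-adjusted p-value
#'   (default 0.05).
#' @param min_conditions Recurrence threshold, inclusive (default 5).
#' @return List with \code{calls} (binary matrix, RBPs x conditions),
#'   \code{n_conditions} (per-RBP row sums) and \code{recurrent}
#'   (character vector of RBP names).
#' @export
aggregate_conditions <- function(tables, level = 0.05, min_conditions = 5L) {
  if (!length(tables)) stop_sfe("no condition tables supplied")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop_sfe("tables must be a named list (names = condition)")
  }
  if (anyDuplicated(names(tables))) stop_sfe("duplicate condition names")
  rbps <- sort(unique(unlist(lapply(tables, `[[`, "rbp"))))
  calls <- vapply(tables, function(tab) {
    hit <- tab$rbp[tab$bh_adjusted_pvalue <= level]
    as.integer(rbps %in% hit)
  }, integer(length(rbps)))
  calls <- matrix(calls, nrow = length(rbps),
                  dimnames = list(rbps, names(tables)))
  n_cond <- rowSums(calls)
  list(calls = calls, n_conditions = n_cond,
       recurrent = rbps[n_cond >= min_conditions])
}
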