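# Selection of the differentially spliced set K within the universe M.
#
# The universe is the set of events present in BOTH the indicator matrix
# and the stats table: every event counted by the enrichment tests must
# have a binding row and a p-value.

#' Align an indicator matrix with an event-stats table
#'
#' Restricts both to their shared event ids, in matrix row order, so that
#' row i of the matrix and row i of the stats table describe the same
#' event.
#'
#' @param mat Indicator matrix with event rownames.
#' @param stats Stats table from \code{\link{read_event_stats}}.
#' @return A list with elements \code{matrix} and \code{stats}.
#' @export
align_universe <- function(mat, stats) {
  mat <- as_exs(mat)
  shared <- intersect(rownames(mat), stats$event_id)
  if (!length(shared)) stop_sfe("matrix and stats table share no event ids")
  dropped_mat <- nrow(mat) - length(shared)
  dropped_stats <- nrow(stats) - length(shared)
  if (dropped_mat || dropped_stats) {
    message(sprintf("aligned universe: %d events (%d matrix rows and %d stats rows dropped)",
                    length(shared), dropped_mat, dropped_stats))
  }
  keep <- rownames(mat)[rownames(mat) %in% shared]
  list(matrix = mat[keep, , drop = FALSE],
       stats = stats[match(keep, stats$event_id), , drop = FALSE])
}

#' Event-selection rule
#'
#' Three ways to call the "differentially spliced" set: all events with raw
#' p-value strictly under a threshold (default 0.001); the N
#' smallest-p events (default 1000); or all events whose Benjamini-Hochberg
#' adjusted p-value is at most an FDR level.
#'
#' @param kind One of \code{"pvalue_threshold"}, \code{"top_n"},
#'   \code{"fdr_threshold"}.
#' @param value Threshold in (0,1], count >= 1, or FDR level, depending on
#'   \code{kind}; defaults 0.001, 1000 and 0.05.
#' @return A list of class \code{selection_rule}.
#' @export
selection_rule <- function(kind = c("pvalue_threshold", "top_n", "fdr_threshold"),
                           value = NULL) {
  kind <- match.arg(kind)
  if (is.null(value)) {
    value <- switch(kind, pvalue_threshold = 0.001, top_n = 1000L,
                    fdr_threshold = 0.05)
  }
  if (kind == "top_n") {
    if (value < 1 || value != floor(value)) stop_sfe("top_n value must be an integer >= 1")
  } else if (value <= 0 || value > 1) {
    stop_sfe("threshold must lie in (0, 1]")
  }
  structure(list(kind = kind, value = value), class = "selection_rule")
}

#' Select differentially spliced events
#'
#' @param stats Aligned stats table (see \code{\link{align_universe}}).
#' @param rule A \code{\link{selection_rule}}.
#' @return List of class \code{event_selection} with \code{selected_ids}
#'   (ordered by increasing p-value, ties broken by event id), \code{K}
#'   (selected count) and \code{M} (universe size).
#' @details
#' \code{pvalue_threshold} keeps events with \code{pvalue < value}
#' (strict); \code{fdr_threshold} keeps \code{bh_adjust(pvalue) <= value}.
#' \code{top_n} takes exactly N events after a stable sort by (pvalue,
#' event_id), so boundary ties resolve reproducibly.
#' @export
select_events <- function(stats, rule = selection_rule()) {
  check_pvalues(stats$pvalue)
  M <- nrow(stats)
  ord <- order(stats$pvalue, stats$event_id)
  sel <- switch(rule$kind,
    pvalue_threshold = ord[stats$pvalue[ord] < rule$value],
    top_n = {
      if (rule$value > M) stop_sfe(sprintf("top_n = %d exceeds universe size M = %d",
                                           rule$value, M))
      ord[seq_len(rule$value)]
    },
    fdr_threshold = {
      adj <- bh_adjust(stats$pvalue)
      ord[adj[ord] <= rule$value]
    }
  )
  if (!length(sel)) warning("no event satisfies the selection rule", call. = FALSE)
  structure(list(selected_ids = stats$event_id[sel], K = length(sel), M = M),
            class = "event_selection")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; thin
#' validated front-end over \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues Numeric vector in \code{[0,1]}.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  check_pvalues(pvalues)
  p.adjust(pvalues, method = "BH")
}
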