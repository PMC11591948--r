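# Hypergeometric (Fisher) over-representation test per RBP.
#
# With M events in the universe, K of them selected as differentially
# spliced, and m events bound by RBP j, the observed count k of selected
# bound events is compared to a hypergeometric null:
#   P(X >= k), X ~ Hypergeom(M, m, K).
# One-sided enrichment only; depletion is not reported.

#' Contingency summary for one RBP
#'
#' @param mat Aligned indicator matrix.
#' @param selection An \code{\link{select_events}} result computed on the
#'   same universe.
#' @param rbp Column name.
#' @return List \code{(M, K, m, k)}: universe size, selected count, bound
#'   count, selected-and-bound count.
#' @export
contingency <- function(mat, selection, rbp) {
  mat <- as_exs(mat)
  if (!rbp %in% colnames(mat)) unknown_name_error(rbp, colnames(mat), "RBP")
  check_selection(mat, selection)
  col <- mat[, rbp]
  sel <- rownames(mat) %in% selection$selected_ids
  cs <- list(M = selection$M, K = selection$K,
             m = sum(col != 0), k = sum(col[sel] != 0))
  validate_contingency(cs)
  cs
}

#' Hypergeometric upper-tail probability
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeom(M, m, K)} — the probability of
#' observing at least \code{k} selected bound events by chance. Exactly 1
#' when \code{k = 0}.
#'
#' @param cs A contingency summary (list with M, K, m, k), e.g. from
#'   \code{\link{contingency}}.
#' @return P-value in \code{(0, 1]}.
#' @export
hypergeom_tail <- function(cs) {
  validate_contingency(cs)
  if (cs$k == 0) return(1)
  phyper(cs$k - 1, cs$m, cs$M - cs$m, cs$K, lower.tail = FALSE)
}

#' Fisher over-representation across all RBPs
#'
#' @inheritParams contingency
#' @return \code{data.frame} with one row per RBP: \code{rbp, k, m, K, M,
#'   statistic} (= k), \code{pvalue}, \code{method}.
#' @export
fisher_enrichment <- function(mat, selection) {
  mat <- as_exs(mat)
  check_selection(mat, selection)
  if (selection$K == 0) {
    warning("empty selection: all Fisher p-values are 1", call. = FALSE)
  }
  m <- Matrix::colSums(mat != 0)
  sel <- rownames(mat) %in% selection$selected_ids
  k <- if (any(sel)) Matrix::colSums(mat[sel, , drop = FALSE] != 0) else rep(0, ncol(mat))
  pvalue <- ifelse(k == 0, 1,
                   phyper(k - 1, m, selection$M - m, selection$K, lower.tail = FALSE))
  data.frame(rbp = colnames(mat), k = as.integer(k), m = as.integer(m),
             K = selection$K, M = selection$M, statistic = as.integer(k),
             pvalue = pvalue, method = "fisher", row.names = NULL,
             stringsAsFactors = FALSE)
}

validate_contingency <- function(cs) {
  with(cs, {
    if (K > M || m > M || k > min(K, m) || k < 0 || m < 0 || K < 0) {
      stop_sfe(sprintf("invalid contingency summary (M=%d, K=%d, m=%d, k=%d)",
                       M, K, m, k))
    }
  })
  invisible(cs)
}

check_selection <- function(mat, selection) {
  if (!inherits(selection, "event_selection")) {
    stop_sfe("selection must come from select_events()")
  }
  if (selection$M != nrow(mat)) {
    stop_sfe(sprintf("selection universe (M=%d) does not match matrix rows (%d); align first",
                     selection$M, nrow(mat)))
  }
  if (!all(selection$selected_ids %in% rownames(mat))) {
    stop_sfe("selected ids missing from the matrix; align first")
  }
  invisible(selection)
}
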