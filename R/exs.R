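# Construction of the sparse events x RBPs indicator matrix.

#' Configuration for indicator-matrix construction
#'
#' @param window_nt Non-negative integer; each event-defining interval is
#'   extended by this many nucleotides on both sides before overlap testing
#'   (default 400). The extension is clipped at the chromosome origin.
#' @param strand_mode \code{"ignore"} (default) counts overlaps regardless
#'   of strand; \code{"match"} requires site and event strand to agree,
#'   with \code{"."}/\code{"*"} matching anything. CLIP peaks and events
#'   are both stranded, but annotation conventions differ between sources,
#'   so strand-blind overlap is the default.
#' @param keep_empty_rows,keep_empty_cols Keep events / RBPs with no
#'   overlap as all-zero rows / columns (default \code{TRUE} for both, so
#'   matrix dimensions mirror the inputs).
#' @return A list of class \code{exs_build_config}.
#' @export
exs_build_config <- function(window_nt = 400L,
                             strand_mode = c("ignore", "match"),
                             keep_empty_rows = TRUE,
                             keep_empty_cols = TRUE) {
  strand_mode <- match.arg(strand_mode)
  window_nt <- as.numeric(window_nt)
  if (length(window_nt) != 1L || !is.finite(window_nt) || window_nt < 0 ||
      window_nt != floor(window_nt)) {
    stop_sfe("window_nt must be a single non-negative integer")
  }
  structure(list(window_nt = as.integer(window_nt), strand_mode = strand_mode,
                 keep_empty_rows = keep_empty_rows,
                 keep_empty_cols = keep_empty_cols),
            class = "exs_build_config")
}

#' Build the events x RBPs indicator matrix
#'
#' Sets entry \code{(i, j)} to 1 when some binding interval of RBP j
#' intersects some defining interval of event i after each event interval
#' is widened by \code{window_nt} on both sides. Intervals are half-open on
#' disk; a site that starts exactly where the widened event window ends
#' does not overlap.
#'
#' @param sites Named \code{GRangesList} from
#'   \code{\link{read_binding_sites}} (one element per RBP).
#' @param events Event table from \code{\link{read_events}}.
#' @param config An \code{\link{exs_build_config}}.
#' @return A binary \code{dgCMatrix}; rownames are event ids, colnames RBP
#'   names.
#' @export
build_exs <- function(sites, events, config = exs_build_config()) {
  if (length(sites) == 0L) stop_sfe("no binding sites supplied")
  if (is.null(events) || nrow(events) == 0L) stop_sfe("no events supplied")
  rbp_names <- names(sites)
  if (is.null(rbp_names) || any(!nzchar(rbp_names))) {
    stop_sfe("sites must be a named GRangesList (names = RBP)")
  }

  event_gr <- events_to_granges(events, window_nt = config$window_nt)
  site_gr <- BiocGenerics::unlist(sites, use.names = FALSE)
  site_rbp <- rep(seq_along(sites), S4Vectors::elementNROWS(sites))

  warn_if_disjoint_chroms(site_gr, event_gr)

  # seqlevel-mismatch chatter from findOverlaps is redundant with the
  # disjoint-chromosome warning above
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    site_gr, event_gr,
    ignore.strand = (config$strand_mode == "ignore")
  ))
  i <- event_gr$event_idx[S4Vectors::subjectHits(hits)]
  j <- site_rbp[S4Vectors::queryHits(hits)]
  pair <- unique(cbind(i, j))

  mat <- Matrix::sparseMatrix(
    i = pair[, 1], j = pair[, 2], x = 1,
    dims = c(nrow(events), length(sites)),
    dimnames = list(events$event_id, rbp_names)
  )
  if (!config$keep_empty_rows) mat <- mat[Matrix::rowSums(mat) > 0, , drop = FALSE]
  if (!config$keep_empty_cols) mat <- mat[, Matrix::colSums(mat) > 0, drop = FALSE]
  as_exs(mat)
}

# Expand the event table into one GRanges entry per defining interval,
# widened by window_nt and clipped at the origin, carrying the row index.
events_to_granges <- function(events, window_nt = 0L) {
  n_per <- vapply(events$ranges, nrow, 0L)
  start0 <- unlist(lapply(events$ranges, function(m) m[, "start"]), use.names = FALSE)
  end0 <- unlist(lapply(events$ranges, function(m) m[, "end"]), use.names = FALSE)
  if (max(as.numeric(end0)) + as.numeric(window_nt) >= .Machine$integer.max) {
    stop_sfe("window_nt too large: extended coordinates overflow integer range")
  }
  idx <- rep(seq_len(nrow(events)), n_per)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(events$chrom, n_per),
    ranges = IRanges::IRanges(
      start = pmax(1L, start0 + 1L - window_nt),
      end = end0 + window_nt
    ),
    strand = ifelse(rep(events$strand, n_per) == ".", "*", rep(events$strand, n_per))
  )
  gr$event_idx <- idx
  gr
}

warn_if_disjoint_chroms <- function(site_gr, event_gr) {
  sc <- unique(as.character(GenomicRanges::seqnames(site_gr)))
  ec <- unique(as.character(GenomicRanges::seqnames(event_gr)))
  if (!length(intersect(sc, ec))) {
    warning("binding sites and events share no chromosome names; ",
            "check the 'chr' prefix convention (see chr_normalize)",
            call. = FALSE)
  }
}

#' Query the indicator matrix
#'
#' \code{bound_events} returns the ids of events bound by an RBP;
#' \code{binding_rbps} the RBPs binding near an event.
#'
#' @param mat Indicator matrix with dimnames.
#' @param rbp,event_id A single column / row name.
#' @return Character vector of ids (possibly empty).
#' @export
bound_events <- function(mat, rbp) {
  mat <- as_exs(mat)
  if (!rbp %in% colnames(mat)) unknown_name_error(rbp, colnames(mat), "RBP")
  rownames(mat)[mat[, rbp] != 0]
}

#' @rdname bound_events
#' @export
binding_rbps <- function(mat, event_id) {
  mat <- as_exs(mat)
  if (!event_id %in% rownames(mat)) {
    unknown_name_error(event_id, rownames(mat), "event")
  }
  colnames(mat)[mat[event_id, ] != 0]
}
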