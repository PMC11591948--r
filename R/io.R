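# Readers and writers for every on-disk format the tool touches.
#
# All files use BED-style 0-based half-open coordinates. Internally,
# intervals live in GRanges/IRanges objects (1-based closed, the
# Bioconductor convention); conversion happens only at the file boundary,
# so [start, end) on disk becomes start+1..end in memory and back.

VALID_EVENT_TYPES <- c("cassette", "alt5", "alt3", "retained_intron",
                       "mutually_exclusive", "complex", "other")

#' Read RBP binding sites from a BED6-like file
#'
#' Parses a tab-separated BED-like file whose name column carries the RBP
#' name (POSTAR3-style export): \code{chrom start end name [score] [strand]}.
#' The score column, when present, is read and discarded: the downstream
#' indicator matrix is binary, so no affinity weighting is applied. Multiple
#' CLIP experiments for the same RBP are pooled into a single binding set.
#'
#' @param path Path to the tab-separated file (no header).
#' @param merge Logical; union overlapping intervals of the same RBP on the
#'   same chromosome and strand (default \code{TRUE}). For a binary
#'   indicator matrix merging does not change any downstream result.
#' @param chr_normalize One of \code{"none"}, \code{"strip"} (remove a
#'   leading \code{"chr"}) or \code{"add"} (prepend it); lets binding sites
#'   and event tables from different sources agree on naming.
#' @return A named \code{GRangesList}, one element per distinct RBP, sorted
#'   by (chrom, start, end). Strand \code{"."} is stored as \code{"*"}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tFUS\t0\t+", "chr1\t150\t250\tFUS\t0\t+"), bed)
#' sites <- read_binding_sites(bed)
#' length(sites$FUS)  # 1 merged interval [100,250)
#' @export
read_binding_sites <- function(path, merge = TRUE,
                               chr_normalize = c("none", "strip", "add")) {
  chr_normalize <- match.arg(chr_normalize)
  dt <- read_tsv_raw(path, what = "binding sites")
  if (ncol(dt) < 4L) stop_sfe("binding-site file needs at least 4 columns (chrom, start, end, name)")
  chrom <- as.character(dt[[1]])
  start <- dt[[2]]
  end <- dt[[3]]
  name <- as.character(dt[[4]])
  strand <- rep(".", nrow(dt))
  if (ncol(dt) >= 6L) {
    strand <- as.character(dt[[6]])
  } else if (ncol(dt) == 5L) {
    # 5-column files: the extra column is a strand if it looks like one,
    # otherwise a score (strand unknown).
    v <- as.character(dt[[5]])
    if (all(v %in% c("+", "-", "."))) strand <- v
  }
  check_coords(start, end, path)
  start <- as.integer(start)
  end <- as.integer(end)
  if (!all(strand %in% c("+", "-", "."))) {
    bad <- which(!strand %in% c("+", "-", "."))[1]
    stop_sfe(sprintf("%s: line %d: invalid strand '%s'", path, bad, strand[bad]))
  }
  if (any(!nzchar(name))) stop_sfe(sprintf("%s: empty RBP name", path))
  chrom <- normalize_chrom(chrom, chr_normalize)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = sort(unique(chrom))),
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = ifelse(strand == ".", "*", strand)
  )
  n_read <- length(gr)
  grl <- S4Vectors::split(gr, factor(name, levels = sort(unique(name))))
  if (merge) {
    merged <- GenomicRanges::reduce(grl)  # per-RBP, strand-aware union
    n_after <- sum(S4Vectors::elementNROWS(merged))
    message(sprintf("read %d binding records for %d RBPs (%d after merging overlaps)",
                    n_read, length(merged), n_after))
    grl <- merged
  } else {
    message(sprintf("read %d binding records for %d RBPs", n_read, length(grl)))
  }
  GenomicRanges::GRangesList(lapply(grl, function(g) BiocGenerics::sort(g, ignore.strand = TRUE)))
}

#' Read splicing-event definitions
#'
#' Expects a tab-separated file with header columns \code{event_id},
#' \code{gene_id}, \code{event_type}, \code{chrom}, \code{strand},
#' \code{intervals}, where \code{intervals} is a semicolon-separated list of
#' 0-based half-open \code{start-end} pairs, all on \code{chrom}.
#'
#' @param path Path to the event table.
#' @param chr_normalize See \code{\link{read_binding_sites}}.
#' @return A \code{data.frame} with the five scalar columns plus a list
#'   column \code{ranges} of two-column integer matrices (half-open
#'   \code{start}, \code{end} per interval).
#' @export
read_events <- function(path, chr_normalize = c("none", "strip", "add")) {
  chr_normalize <- match.arg(chr_normalize)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  need <- c("event_id", "gene_id", "event_type", "chrom", "strand", "intervals")
  if (!all(need %in% names(dt))) {
    stop_sfe(sprintf("%s: event table must have columns %s", path,
                     paste(need, collapse = ", ")))
  }
  if (nrow(dt) == 0L) stop_sfe(sprintf("%s: empty event table", path))
  if (anyDuplicated(dt$event_id)) {
    dup <- unique(dt$event_id[duplicated(dt$event_id)])
    stop_sfe(sprintf("%s: duplicate event_id: %s", path,
                     paste(head(dup, 3), collapse = ", ")))
  }
  if (!all(dt$event_type %in% VALID_EVENT_TYPES)) {
    stop_sfe(sprintf("%s: invalid event_type (allowed: %s)", path,
                     paste(VALID_EVENT_TYPES, collapse = ", ")))
  }
  if (!all(dt$strand %in% c("+", "-", "."))) stop_sfe(sprintf("%s: invalid strand", path))
  ranges <- lapply(seq_len(nrow(dt)), function(i) {
    parse_interval_field(dt$intervals[i], dt$event_id[i], path)
  })
  out <- dt[need[1:5]]
  out$chrom <- normalize_chrom(out$chrom, chr_normalize)
  out$ranges <- ranges
  out
}

parse_interval_field <- function(field, id, path) {
  if (is.na(field) || !nzchar(field)) {
    stop_sfe(sprintf("%s: event %s has an empty intervals field", path, id))
  }
  pairs <- strsplit(field, ";", fixed = TRUE)[[1]]
  m <- regmatches(pairs, regexec("^([0-9]+)-([0-9]+)$", pairs))
  if (any(lengths(m) != 3L)) {
    stop_sfe(sprintf("%s: event %s: malformed interval '%s'",
                     path, id, pairs[which(lengths(m) != 3L)[1]]))
  }
  start <- as.integer(vapply(m, `[`, "", 2L))
  end <- as.integer(vapply(m, `[`, "", 3L))
  if (any(is.na(start)) || any(is.na(end)) || any(end <= start)) {
    stop_sfe(sprintf("%s: event %s: invalid interval coordinates", path, id))
  }
  cbind(start = start, end = end)
}

#' Read per-event differential-splicing statistics
#'
#' Tab-separated with header \code{event_id}, \code{pvalue},
#' \code{delta_psi}; \code{delta_psi} may be \code{NA} or the column absent.
#' Lines starting with \code{#} are skipped, so tables written by
#' \code{\link{write_results}} round-trip.
#'
#' @param path Path to the stats table.
#' @return \code{data.frame} with columns \code{event_id}, \code{pvalue}
#'   (in \code{[0,1]}) and \code{delta_psi} (in \code{[-1,1]} or \code{NA}).
#' @export
read_event_stats <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          skip = first_noncomment_line(path) - 1L)
  if (!all(c("event_id", "pvalue") %in% names(dt))) {
    stop_sfe(sprintf("%s: stats table must have columns event_id, pvalue", path))
  }
  if (is.null(dt$delta_psi)) dt$delta_psi <- NA_real_
  dt <- dt[c("event_id", "pvalue", "delta_psi")]
  dt$event_id <- as.character(dt$event_id)
  dt$pvalue <- as.numeric(dt$pvalue)
  dt$delta_psi <- as.numeric(dt$delta_psi)
  if (nrow(dt) == 0L) return(dt)
  if (anyDuplicated(dt$event_id)) stop_sfe(sprintf("%s: duplicate event_id", path))
  check_pvalues(dt$pvalue)
  dpsi <- dt$delta_psi[!is.na(dt$delta_psi)]
  if (any(dpsi < -1 | dpsi > 1)) stop_sfe(sprintf("%s: delta_psi outside [-1,1]", path))
  dt
}

#' Write a results table as TSV
#'
#' Writes optional \code{# }-prefixed comment lines (provenance: tool
#' version, config hash, seed) followed by a tab-separated table with
#' header.
#'
#' @param table A \code{data.frame}.
#' @param path Output path.
#' @param comments Character vector of comment lines (without the \code{#}).
#' @return \code{path}, invisibly.
#' @export
write_results <- function(table, path, comments = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(table), collapse = "\t"), con)
  if (nrow(table)) {
    cols <- lapply(table, function(x) {
      if (is.numeric(x)) format(x, digits = 15, trim = TRUE, scientific = NA) else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write / read a labelled sparse indicator matrix
#'
#' The matrix goes to Matrix Market coordinate format at \code{path}; row
#' (event) and column (RBP) identifiers go to the sidecar text files
#' \code{<path>.rows} and \code{<path>.cols}, one per line, in order.
#'
#' @param mat Sparse binary matrix with dimnames.
#' @param path Output path for the \code{.mtx} body.
#' @return \code{write_matrix}: \code{path} invisibly. \code{read_matrix}:
#'   the matrix as a \code{dgCMatrix} with dimnames restored.
#' @export
write_matrix <- function(mat, path) {
  mat <- as_exs(mat)
  Matrix::writeMM(mat, path)
  writeLines(rownames(mat), paste0(path, ".rows"))
  writeLines(colnames(mat), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  m <- Matrix::readMM(path)
  rows <- readLines(paste0(path, ".rows"))
  cols <- readLines(paste0(path, ".cols"))
  if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
    stop_sfe(sprintf("%s: sidecar label count (%d rows, %d cols) does not match matrix dims (%d x %d)",
                     path, length(rows), length(cols), nrow(m), ncol(m)))
  }
  dimnames(m) <- list(rows, cols)
  as_exs(m)
}

# -- internal parsing helpers -----------------------------------------------

read_tsv_raw <- function(path, what) {
  if (!file.exists(path)) stop_sfe(sprintf("file not found: %s", path))
  if (file.size(path) == 0) stop_sfe(sprintf("%s: empty %s file", path, what))
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE,
                      colClasses = "character"),
    error = function(e) stop_sfe(sprintf("%s: cannot parse %s: %s", path, what,
                                         conditionMessage(e)))
  )
  if (nrow(dt) == 0L) stop_sfe(sprintf("%s: empty %s file", path, what))
  dt
}

check_coords <- function(start, end, path) {
  s <- suppressWarnings(as.numeric(start))
  e <- suppressWarnings(as.numeric(end))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad)) {
    stop_sfe(sprintf("%s: line %d: non-integer coordinates", path, bad[1]))
  }
  bad <- which(s < 0 | e <= s)
  if (length(bad)) {
    stop_sfe(sprintf("%s: line %d: invalid interval [%s, %s)", path, bad[1],
                     start[bad[1]], end[bad[1]]))
  }
  invisible(NULL)
}

normalize_chrom <- function(chrom, mode) {
  switch(mode,
         none = chrom,
         strip = sub("^chr", "", chrom),
         add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)))
}

first_noncomment_line <- function(path) {
  lines <- readLines(path, n = 100L)
  i <- which(!startsWith(lines, "#"))
  if (!length(i)) stop_sfe(sprintf("%s: no data lines", path))
  i[1]
}
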