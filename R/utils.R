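# Internal helpers shared across modules.

sigmoid <- function(x) plogis(x)

#' @noRd
stop_sfe <- function(..., call. = FALSE) stop(..., call. = call.)

# Validate an events x RBPs indicator matrix: sparse or dense, binary,
# unique non-empty dimnames. Returns the matrix coerced to dgCMatrix.
as_exs <- function(mat) {
  if (is.matrix(mat)) mat <- as(as(as(mat, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (!is(mat, "CsparseMatrix")) {
    mat <- as(as(mat, "generalMatrix"), "CsparseMatrix")
  }
  if (is(mat, "nMatrix")) mat <- as(mat, "dMatrix")
  mat <- as(mat, "generalMatrix")
  x <- mat@x
  if (length(x) && !all(x %in% c(0, 1))) {
    stop_sfe("indicator matrix must be binary (entries in {0,1})")
  }
  dn <- dimnames(mat)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]])) {
    stop_sfe("indicator matrix must carry event ids as rownames and RBP names as colnames")
  }
  if (anyDuplicated(dn[[1]])) stop_sfe("duplicate event ids in matrix rownames")
  if (anyDuplicated(dn[[2]])) stop_sfe("duplicate RBP names in matrix colnames")
  Matrix::drop0(mat)
}

# Error for an unknown name, suggesting close matches by edit distance.
unknown_name_error <- function(name, known, what) {
  d <- adist(name, known)
  near <- known[order(d)][seq_len(min(3L, length(known)))]
  stop_sfe(sprintf("unknown %s '%s'; nearest matches: %s",
                   what, name, paste(near, collapse = ", ")))
}

# Deterministic 32-bit FNV-1a hash of an R object, as 8 hex digits.
# Used only to stamp run manifests; not cryptographic. The xor touches only
# the low byte, so it is computed on h %% 256 and added back.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

check_pvalues <- function(p, what = "pvalue") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_sfe(sprintf("%s values must be finite and in [0,1]", what))
  }
  invisible(p)
}
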