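# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no interval index, no DP recursion sharing, no sparse
# algebra) so agreement is evidence, not tautology.

# All-pairs interval-overlap oracle on plain data frames with 0-based
# half-open coordinates (no interval index: every event interval is
# compared against every site). sites: chrom,start,end,strand,rbp.
# events: one row per event with a list column `ranges`, chrom, strand.
bf_exs_oracle <- function(sites, events, window = 400L, strand_mode = "ignore") {
  E <- nrow(events)
  rbps <- sort(unique(sites$rbp))
  out <- matrix(0, E, length(rbps), dimnames = list(events$event_id, rbps))
  for (i in seq_len(E)) {
    ok_strand <- if (strand_mode == "match") {
      sites$strand == "." | events$strand[i] == "." |
        sites$strand == events$strand[i]
    } else TRUE
    for (r in seq_len(nrow(events$ranges[[i]]))) {
      es <- max(0, events$ranges[[i]][r, "start"] - window)
      ee <- events$ranges[[i]][r, "end"] + window
      hit <- sites$chrom == events$chrom[i] & ok_strand &
        pmax(sites$start, es) < pmin(sites$end, ee)
      if (any(hit)) out[i, unique(sites$rbp[hit])] <- 1
    }
  }
  out
}

# Exact Poisson-Binomial upper tail by enumerating all 2^n outcomes.
poibin_enum_oracle <- function(probs, k) {
  n <- length(probs)
  bits <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- exp(bits %*% log(probs) + (1 - bits) %*% log1p(-probs))
  sum(pr[rowSums(bits) >= k])
}

# Independent Poisson-Binomial pmf via FFT polynomial products
# (stats::convolve), a different numerical route from the package's DP.
poibin_pmf_convolve <- function(probs) {
  polys <- lapply(probs, function(p) c(1 - p, p))
  Reduce(function(a, b) {
    out <- convolve(a, rev(b), type = "open")
    pmax(out, 0)
  }, polys)
}

# Direct hypergeometric upper-tail summation from binomial coefficients.
# For M <= 30 every product of choose() values is an exact integer below
# 2^53, so the sum is an exactly represented rational evaluated in doubles.
hyper_tail_oracle <- function(M, K, m, k) {
  if (k == 0) return(1)
  x <- k:min(K, m)
  sum(choose(m, x) * choose(M - m, K - x)) / choose(M, K)
}

# Full running-sum GSEA enrichment score (O(M) walk over every rank).
gsea_es_oracle <- function(w, hits, M) {
  m <- length(hits)
  v <- rep(-1 / (M - m), M)
  W <- sum(w[hits])
  if (W > 0) v[hits] <- w[hits] / W else v[hits] <- 1 / m
  run <- cumsum(v)
  mx <- max(0, max(run)); mn <- min(0, min(run))
  if (mx >= -mn) mx else mn
}

# Small random binary matrix with dimnames.
rand_exs <- function(E, S, density = 0.3) {
  m <- matrix(as.numeric(runif(E * S) < density), E, S,
              dimnames = list(sprintf("E%03d", seq_len(E)),
                              sprintf("R%02d", seq_len(S))))
  m
}

rand_stats <- function(ids, ties = FALSE) {
  p <- runif(length(ids))
  if (ties) p <- round(p, 1)
  data.frame(event_id = ids, pvalue = p,
             delta_psi = runif(length(ids), -1, 1), stringsAsFactors = FALSE)
}

make_selection <- function(ids, M) {
  structure(list(selected_ids = ids, K = length(ids), M = M),
            class = "event_selection")
}
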