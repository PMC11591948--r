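# Seeded simulators: indicator matrices with row/column density structure,
# knockdown-style event statistics with a designated causal RBP, and
# on-disk interval fixtures that rebuild to a known matrix.

#' Simulation configuration
#'
#' Defaults emulate a knockdown validation at realistic scale: 5000 tested
#' events, 244 RBPs (the size of a pooled CLIP compendium), a mean binding
#' density around 5\%, moderate event- and RBP-level density heterogeneity
#' on the logit scale, and strongly enriched Beta(0.1, 1) p-values for
#' events bound by the knocked-down RBP against a Uniform(0,1) background.
#'
#' @param n_events,n_rbps Matrix dimensions (each >= 2).
#' @param mu_mean,mu_sd Event effect distribution (logit scale); the mean
#'   cell probability is roughly \code{plogis(mu_mean + lam_mean)}.
#' @param lam_mean,lam_sd RBP effect distribution (logit scale).
#' @param target_rbp Column index or name of the knocked-down RBP
#'   (\code{NULL} when only a matrix is needed).
#' @param signal_beta_a Shape a of the Beta(a, 1) law for bound-event
#'   p-values, in (0, 1]; a = 1 is the uniform null, smaller is stronger
#'   enrichment.
#' @param dpsi_noise_sd Standard deviation of delta-PSI noise for
#'   non-signal events.
#' @param seed Integer seed; every generator consumes it deterministically.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(n_events = 5000L, n_rbps = 244L,
                         mu_mean = -3, mu_sd = 0.6,
                         lam_mean = 0, lam_sd = 0.6,
                         target_rbp = NULL, signal_beta_a = 0.1,
                         dpsi_noise_sd = 0.05, seed = NULL) {
  if (n_events < 2L || n_rbps < 2L) stop_sfe("need n_events >= 2 and n_rbps >= 2")
  if (signal_beta_a <= 0 || signal_beta_a > 1) stop_sfe("signal_beta_a must lie in (0,1]")
  structure(list(n_events = as.integer(n_events), n_rbps = as.integer(n_rbps),
                 mu_mean = mu_mean, mu_sd = mu_sd,
                 lam_mean = lam_mean, lam_sd = lam_sd,
                 target_rbp = target_rbp, signal_beta_a = signal_beta_a,
                 dpsi_noise_sd = dpsi_noise_sd, seed = seed),
            class = "synth_config")
}

#' Simulate an indicator matrix from the logistic main-effects model
#'
#' Draws \code{mu_i ~ N(mu_mean, mu_sd)}, \code{lam_j ~ N(lam_mean,
#' lam_sd)} and independent \code{y_ij ~ Bernoulli(plogis(mu_i + lam_j))}
#' — the same generative family the background model fits, with event ids
#' \code{E0001...} and RBP names \code{RBP001...}.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return List: \code{matrix} (sparse binary with dimnames), \code{mu},
#'   \code{lam} (the true effects).
#' @export
simulate_exs <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  E <- cfg$n_events; S <- cfg$n_rbps
  mu <- rnorm(E, cfg$mu_mean, cfg$mu_sd)
  lam <- rnorm(S, cfg$lam_mean, cfg$lam_sd)
  p <- sigmoid(outer(mu, lam, "+"))
  y <- which(matrix(runif(E * S), E, S) < p)
  mat <- Matrix::sparseMatrix(
    i = ((y - 1) %% E) + 1, j = ((y - 1) %/% E) + 1, x = 1,
    dims = c(E, S),
    dimnames = list(sprintf("E%04d", seq_len(E)), sprintf("RBP%03d", seq_len(S)))
  )
  list(matrix = as_exs(mat), mu = mu, lam = lam)
}

#' Simulate knockdown-style event statistics
#'
#' Events bound by the target RBP (its matrix column) draw p-values from
#' Beta(signal_beta_a, 1); unbound events draw Uniform(0,1). Delta PSI is
#' +/- Uniform(0.1, 0.6) (random sign) for bound events and N(0,
#' dpsi_noise_sd) clipped to [-1,1] for the rest. The RNG stream is seeded
#' with \code{cfg$seed + 1} so the stats are reproducible independently of
#' whether the matrix was regenerated.
#'
#' @param cfg A \code{\link{synth_config}} with \code{target_rbp} set.
#' @param mat Indicator matrix (from \code{\link{simulate_exs}} or real).
#' @return Stats table (\code{event_id, pvalue, delta_psi}) in matrix row
#'   order.
#' @export
simulate_knockdown <- function(cfg, mat) {
  mat <- as_exs(mat)
  if (is.null(cfg$target_rbp)) stop_sfe("cfg$target_rbp must be set")
  j <- cfg$target_rbp
  if (is.character(j)) {
    if (!j %in% colnames(mat)) unknown_name_error(j, colnames(mat), "RBP")
  } else if (j < 1 || j > ncol(mat)) {
    stop_sfe(sprintf("target_rbp index %d out of range 1..%d", j, ncol(mat)))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  E <- nrow(mat)
  bound <- mat[, j] != 0
  pvalue <- runif(E)
  pvalue[bound] <- rbeta(sum(bound), cfg$signal_beta_a, 1)
  dpsi <- rnorm(E, 0, cfg$dpsi_noise_sd)
  dpsi[bound] <- sample(c(-1, 1), sum(bound), replace = TRUE) * runif(sum(bound), 0.1, 0.6)
  data.frame(event_id = rownames(mat), pvalue = pvalue,
             delta_psi = pmin(pmax(dpsi, -1), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an interval fixture with a planted indicator matrix
#'
#' Lays events far apart on one chromosome and places one binding site
#' inside the windowed region of event i for every planted 1 of RBP j, so
#' that \code{\link{build_exs}} on the emitted files reproduces the
#' planted matrix exactly. Events are spaced so that no site can reach a
#' neighbouring event's window.
#'
#' @param dir Output directory (created if needed).
#' @param n_events,n_rbps Dimensions (n_events <= 1000).
#' @param density Planted nonzero density (each RBP gets at least one
#'   site so every column exists in the BED output).
#' @param window_nt Window the fixture is designed for (default 400).
#' @param seed Integer seed.
#' @return List: \code{bed}, \code{events} (file paths), \code{matrix}
#'   (the planted truth).
#' @export
emit_interval_fixture <- function(dir, n_events = 20L, n_rbps = 4L,
                                  density = 0.2, window_nt = 400L,
                                  seed = 1L) {
  if (n_events > 1000L) stop_sfe("fixture generator is meant for <= 1000 events")
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  event_len <- 200L
  spacing <- as.integer(4L * window_nt + 10L * event_len)  # windows cannot touch
  starts <- spacing * seq_len(n_events)
  event_ids <- sprintf("E%04d", seq_len(n_events))
  rbp_names <- sprintf("RBP%03d", seq_len(n_rbps))

  planted <- matrix(runif(n_events * n_rbps) < density, n_events, n_rbps)
  for (j in seq_len(n_rbps)) {
    if (!any(planted[, j])) planted[sample.int(n_events, 1L), j] <- TRUE
  }

  ones <- which(planted, arr.ind = TRUE)
  # site inside the widened region but outside the event body: at the left
  # window edge for even rows, inside the body for odd ones
  site_start <- ifelse(ones[, 1] %% 2 == 0,
                       starts[ones[, 1]] - window_nt,       # first covered base
                       starts[ones[, 1]] + 50L)
  bed <- data.frame(chrom = "chr1", start = site_start,
                    end = site_start + 30L, name = rbp_names[ones[, 2]],
                    score = 0L, strand = "+")
  bed <- bed[sample.int(nrow(bed)), ]  # shuffled on purpose: order must not matter
  bed_path <- file.path(dir, "sites.bed")
  data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)

  events <- data.frame(event_id = event_ids, gene_id = sprintf("G%03d", seq_len(n_events)),
                       event_type = "cassette", chrom = "chr1", strand = "+",
                       intervals = sprintf("%d-%d", starts, starts + event_len))
  events_path <- file.path(dir, "events.tsv")
  data.table::fwrite(events, events_path, sep = "\t")

  truth <- Matrix::sparseMatrix(i = ones[, 1], j = ones[, 2], x = 1,
                                dims = c(n_events, n_rbps),
                                dimnames = list(event_ids, rbp_names))
  list(bed = bed_path, events = events_path, matrix = as_exs(truth))
}
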