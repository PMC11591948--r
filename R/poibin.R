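# Bias-corrected enrichment: logistic main-effects background model and
# Poisson-Binomial upper tails.
#
# The naive hypergeometric test assumes every event is equally likely to be
# bound by every RBP. Real indicator matrices have strong row and column
# density structure (promiscuous RBPs, hot events), which biases that test.
# The background model assigns each cell an independent Bernoulli
# probability
#     p_ij = exp(mu_i + lambda_j) / (1 + exp(mu_i + lambda_j)),
# the maximum-likelihood main-effects logistic model. At the ML optimum the
# expected row and column sums equal the observed margins, so the model is
# fitted by margin matching: coordinate ascent with Newton updates of each
# mu_i given lambda and each lambda_j given mu (each one-dimensional
# problem is concave). Because the stationarity condition for mu_i depends
# on the data only through the row sum, rows with equal sums share one
# mu value (and likewise columns), so the fit runs on unique margins and
# never materializes a dense E x S probability matrix.

#' Fit the logistic main-effects background model
#'
#' @param mat Binary indicator matrix (at least 2 x 2).
#' @param tol Convergence tolerance on the maximum absolute difference
#'   between model-expected and observed row/column sums (default 1e-6).
#' @param max_iter Maximum coordinate-ascent sweeps (default 500); an error
#'   carrying the fit report is raised if the margins have not matched.
#' @return Object of class \code{probability_model}: \code{mu} (per event,
#'   named), \code{lam} (per RBP, named), and \code{fit_report} with
#'   \code{iterations} and \code{max_margin_error}. Degenerate margins are
#'   held out of the fit: all-zero rows/columns get \code{mu = -Inf} /
#'   \code{lam = -Inf} (probability exactly 0) and all-one rows/columns
#'   \code{+Inf} (probability 1); where a zero and a one margin cross, the
#'   zero wins. Identifiability is fixed by anchoring the weighted mean of
#'   \code{lam} at 0.
#' @export
fit_probability_model <- function(mat, tol = 1e-6, max_iter = 500L) {
  mat <- as_exs(mat)
  E <- nrow(mat); S <- ncol(mat)
  if (E < 2L || S < 2L) stop_sfe("need at least 2 events and 2 RBPs to fit the model")

  mu <- setNames(rep(NA_real_, E), rownames(mat))
  lam <- setNames(rep(NA_real_, S), colnames(mat))

  # Peel degenerate rows/columns iteratively: a row that is all-zero or
  # all-one *within the kept submatrix* cannot have a finite ML effect.
  keep_r <- rep(TRUE, E); keep_c <- rep(TRUE, S)
  repeat {
    r <- Matrix::rowSums(mat[, keep_c, drop = FALSE] != 0)
    cc <- Matrix::colSums(mat[keep_r, , drop = FALSE] != 0)
    nr0 <- keep_r & (r == 0); nr1 <- keep_r & (r == sum(keep_c))
    nc0 <- keep_c & (cc == 0); nc1 <- keep_c & (cc == sum(keep_r))
    if (sum(keep_c) == 0 || sum(keep_r) == 0) break
    new_r <- nr0 | nr1; new_c <- nc0 | nc1
    if (!any(new_r) && !any(new_c)) break
    mu[nr0] <- -Inf; mu[nr1] <- Inf
    lam[nc0] <- -Inf; lam[nc1] <- Inf
    keep_r <- keep_r & !new_r
    keep_c <- keep_c & !new_c
  }

  it <- 0L; err <- 0
  if (sum(keep_r) >= 1L && sum(keep_c) >= 1L) {
    sub <- mat[keep_r, keep_c, drop = FALSE]
    r <- Matrix::rowSums(sub != 0)
    cc <- Matrix::colSums(sub != 0)
    # group rows by their sum: one mu per unique row sum
    rg <- factor(r); cg <- factor(cc)
    r_u <- as.numeric(levels(rg)); c_u <- as.numeric(levels(cg))
    n_r <- as.numeric(table(rg)); n_c <- as.numeric(table(cg))
    mu_u <- qlogis(pmin(pmax(r_u / length(cc), 1e-6), 1 - 1e-6))
    lam_u <- rep(0, length(c_u))

    err <- Inf
    while (it < max_iter) {
      it <- it + 1L
      # Newton update of each unique mu given lam (rows are independent)
      for (s in 1:3) {
        P <- sigmoid(outer(mu_u, lam_u, "+"))       # unique-margin grid only
        f <- drop(P %*% n_c) - r_u
        fp <- drop((P * (1 - P)) %*% n_c)
        mu_u <- mu_u - pmax(pmin(f / pmax(fp, 1e-12), 5), -5)
      }
      # Newton update of each unique lam given mu
      for (s in 1:3) {
        P <- sigmoid(outer(mu_u, lam_u, "+"))
        g <- drop(crossprod(P, n_r)) - c_u
        gp <- drop(crossprod(P * (1 - P), n_r))
        lam_u <- lam_u - pmax(pmin(g / pmax(gp, 1e-12), 5), -5)
      }
      # re-anchor: weighted mean(lam) = 0, offset absorbed into mu
      shift <- sum(n_c * lam_u) / sum(n_c)
      lam_u <- lam_u - shift
      mu_u <- mu_u + shift
      P <- sigmoid(outer(mu_u, lam_u, "+"))
      err <- max(max(abs(drop(P %*% n_c) - r_u)),
                 max(abs(drop(crossprod(P, n_r)) - c_u)))
      if (err < tol) break
    }
    if (err >= tol) {
      stop_sfe(sprintf("background model did not converge in %d sweeps (max margin error %.3g)",
                       it, err))
    }
    mu[keep_r] <- mu_u[as.integer(rg)]
    lam[keep_c] <- lam_u[as.integer(cg)]
  }

  structure(list(mu = mu, lam = lam,
                 fit_report = list(iterations = it, max_margin_error = err)),
            class = "probability_model")
}

#' Background probability accessor
#'
#' Computes \code{p_ij} on demand from the fitted effects; the dense
#' probability matrix is never stored. Degenerate conventions: a
#' \code{-Inf} effect on either axis forces 0 (zero margins take precedence
#' over one margins), a \code{+Inf} effect forces 1.
#'
#' @param model A \code{probability_model}.
#' @param i,j Event / RBP indices or names (vectors are recycled to a
#'   common length).
#' @return Vector of probabilities in \code{[0,1]}.
#' @export
model_prob <- function(model, i, j) {
  mu <- resolve_effects(model$mu, i, "event")
  lam <- resolve_effects(model$lam, j, "RBP")
  n <- max(length(mu), length(lam))
  mu <- rep_len(mu, n); lam <- rep_len(lam, n)
  p <- numeric(n)
  zero <- (mu == -Inf) | (lam == -Inf)
  one <- !zero & ((mu == Inf) | (lam == Inf))
  rest <- !zero & !one
  p[one] <- 1
  p[rest] <- sigmoid(mu[rest] + lam[rest])
  p
}

resolve_effects <- function(eff, idx, what) {
  if (is.character(idx)) {
    missing <- setdiff(idx, names(eff))
    if (length(missing)) unknown_name_error(missing[1], names(eff), what)
    eff[idx]
  } else {
    eff[idx]
  }
}

#' Poisson-Binomial upper-tail probability
#'
#' \code{P(X >= k)} for \code{X = sum_i Bernoulli(p_i)} with independent,
#' non-identical success probabilities. Up to \code{dp_limit} probabilities
#' the tail is computed by exact dynamic-programming convolution (the count
#' distribution is multiplied by one Bernoulli factor at a time, entirely
#' in linear probability space); above it, a refined normal approximation
#' with skewness correction is used. The method actually used is attached
#' as attribute \code{"tail_method"} (\code{"dp"} or \code{"rna"}).
#'
#' @param probs Vector of probabilities in \code{[0,1]}.
#' @param k Observed count, \code{0 <= k <= length(probs)}; \code{k = 0}
#'   returns exactly 1.
#' @param method \code{"auto"} (default), \code{"dp"} or \code{"rna"}.
#' @param dp_limit Size boundary between exact and approximate (default
#'   5000).
#' @return P-value in \code{(0, 1]}.
#' @export
poibin_tail <- function(probs, k, method = c("auto", "dp", "rna"),
                        dp_limit = 5000L) {
  method <- match.arg(method)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_sfe("probs must lie in [0,1]")
  }
  n <- length(probs)
  if (k < 0 || k > n) stop_sfe(sprintf("k = %s outside 0..%d", format(k), n))
  if (k == 0) return(structure(1, tail_method = "exact"))
  if (method == "auto") method <- if (n <= dp_limit) "dp" else "rna"
  if (method == "dp") {
    pmf <- poibin_pmf_dp(probs)
    p <- sum(pmf[(k + 1L):(n + 1L)])
  } else {
    p <- poibin_tail_rna(probs, k)
  }
  structure(min(max(p, 0), 1), tail_method = method)
}

# Exact count distribution by iterative Bernoulli convolution.
# Returns P(X = 0..n); all values in [0,1], no log-space needed.
poibin_pmf_dp <- function(probs) {
  v <- 1
  for (p in probs) {
    v <- c(v * (1 - p), 0) + c(0, v * p)
  }
  v
}

# Refined normal approximation (second-order, skewness-corrected) to the
# upper tail, with continuity correction.
poibin_tail_rna <- function(probs, k) {
  mu <- sum(probs)
  s2 <- sum(probs * (1 - probs))
  if (s2 == 0) return(as.numeric(k <= mu))  # degenerate: all p in {0,1}
  sigma <- sqrt(s2)
  gamma <- sum(probs * (1 - probs) * (1 - 2 * probs)) / s2^1.5
  x <- (k - 0.5 - mu) / sigma
  cdf_at <- pnorm(x) + gamma * (1 - x^2) * exp(-x^2 / 2) / (6 * sqrt(2 * pi))
  1 - min(max(cdf_at, 0), 1)
}

#' Poisson-Binomial enrichment across all RBPs
#'
#' For each RBP j the null count of bound selected events is the sum of
#' independent Bernoullis with the background probabilities
#' \code{p(i, j)} of the selected events i; the p-value is the
#' Poisson-Binomial upper tail at the observed count.
#'
#' @param mat Aligned indicator matrix.
#' @param selection Selection computed on the same universe.
#' @param model \code{probability_model} fitted on the same aligned matrix.
#' @param dp_limit Passed to \code{\link{poibin_tail}}.
#' @return \code{data.frame}: \code{rbp, k, expected_k, statistic} (= k),
#'   \code{pvalue, method, tail_method}.
#' @export
poibin_enrichment <- function(mat, selection, model, dp_limit = 5000L) {
  mat <- as_exs(mat)
  check_selection(mat, selection)
  if (!inherits(model, "probability_model")) {
    stop_sfe("model must come from fit_probability_model()")
  }
  if (!identical(names(model$mu), rownames(mat)) ||
      !identical(names(model$lam), colnames(mat))) {
    stop_sfe("model was fitted on a different universe than the matrix")
  }
  sel <- which(rownames(mat) %in% selection$selected_ids)
  rbps <- colnames(mat)
  k <- if (length(sel)) Matrix::colSums(mat[sel, , drop = FALSE] != 0) else rep(0, length(rbps))
  res <- lapply(seq_along(rbps), function(j) {
    probs <- model_prob(model, sel, j)
    pv <- poibin_tail(probs, k[j], dp_limit = dp_limit)
    list(expected_k = sum(probs), pvalue = as.numeric(pv),
         tail_method = attr(pv, "tail_method"))
  })
  data.frame(rbp = rbps, k = as.integer(k),
             expected_k = vapply(res, `[[`, 0, "expected_k"),
             statistic = as.integer(k),
             pvalue = vapply(res, `[[`, 0, "pvalue"),
             method = "poibin",
             tail_method = vapply(res, `[[`, "", "tail_method"),
             row.names = NULL, stringsAsFactors = FALSE)
}
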