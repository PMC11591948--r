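# Logistic main-effects background model and Poisson-Binomial tails.

test_that("a constant-margin matrix collapses to p_ij = density", {
  # 40 x 40 circulant: every row and column has exactly 8 ones
  E <- 40; s <- 8
  m <- matrix(0, E, E, dimnames = list(sprintf("E%02d", 1:E), sprintf("R%02d", 1:E)))
  for (i in seq_len(E)) m[i, ((i + seq_len(s) - 2) %% E) + 1] <- 1
  fit <- fit_probability_model(Matrix::Matrix(m, sparse = TRUE), tol = 1e-10)
  p <- model_prob(fit, rep(1:E, 3), rep(c(1, 17, 40), each = E))
  expect_equal(p, rep(s / E, 3 * E), tolerance = 1e-8)
})

test_that("degenerate rows and columns get probability 0 or 1 and exact margins", {
  m <- rand_exs(10, 4, density = 0.5)
  m[3, ] <- 0          # all-zero row
  m[, 2] <- 1          # all-one column
  fit <- fit_probability_model(Matrix::Matrix(m, sparse = TRUE))
  # zero margins win over one margins where they cross, so the all-zero
  # row is 0 everywhere, including in the all-one column
  expect_equal(model_prob(fit, rep(3, 4), 1:4), c(0, 0, 0, 0))
  expect_true(all(model_prob(fit, 1:10, rep(2, 10))[-3] == 1))
  expect_equal(model_prob(fit, 3, 2), 0)
})

test_that("fitted margins match observed margins on model-generated data", {
  cfg <- synth_config(n_events = 200, n_rbps = 50, seed = 101,
                      mu_mean = -1.5, mu_sd = 1, lam_sd = 0.8)
  sim <- simulate_exs(cfg)
  fit <- fit_probability_model(sim$matrix, tol = 1e-6)
  # expected margins recomputed through the on-demand accessor
  exp_row <- vapply(seq_len(200), function(i) sum(model_prob(fit, rep(i, 50), 1:50)), 0)
  exp_col <- vapply(seq_len(50), function(j) sum(model_prob(fit, 1:200, rep(j, 200))), 0)
  obs_row <- Matrix::rowSums(sim$matrix)
  obs_col <- Matrix::colSums(sim$matrix)
  nz_r <- obs_row > 0 & obs_row < 50
  nz_c <- obs_col > 0 & obs_col < 200
  expect_lt(max(abs(exp_row[nz_r] - obs_row[nz_r])), 1e-6)
  expect_lt(max(abs(exp_col[nz_c] - obs_col[nz_c])), 1e-6)

  # the fit beats the constant-density background at recovering true p_ij
  p_true <- plogis(outer(sim$mu, sim$lam, "+"))
  p_fit <- vapply(seq_len(50), function(j) model_prob(fit, 1:200, rep(j, 200)), numeric(200))
  d <- Matrix::nnzero(sim$matrix) / (200 * 50)
  expect_lt(mean(abs(p_fit - p_true)), mean(abs(d - p_true)))
})

test_that("model fit is permutation-equivariant", {
  set.seed(21)
  m <- rand_exs(30, 8, density = 0.3)
  fit <- fit_probability_model(Matrix::Matrix(m, sparse = TRUE))
  pr <- sample(30); pc <- sample(8)
  fit_p <- fit_probability_model(Matrix::Matrix(m[pr, pc], sparse = TRUE))
  p1 <- vapply(1:8, function(j) model_prob(fit, 1:30, rep(j, 30)), numeric(30))
  p2 <- vapply(1:8, function(j) model_prob(fit_p, 1:30, rep(j, 30)), numeric(30))
  expect_equal(p2, p1[pr, pc], tolerance = 1e-7)
})

test_that("non-binary or tiny matrices are rejected", {
  m <- matrix(c(0, 2, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(fit_probability_model(Matrix::Matrix(m, sparse = TRUE)), "binary")
  m1 <- matrix(1, 1, 2, dimnames = list("a", c("x", "y")))
  expect_error(fit_probability_model(Matrix::Matrix(m1, sparse = TRUE)), "at least 2")
})

test_that("poibin tails match hand values, enumeration and the binomial", {
  expect_equal(as.numeric(poibin_tail(c(0.5, 0.5, 0.5), 2)), 0.5, tolerance = 1e-12)
  expect_identical(as.numeric(poibin_tail(runif(5), 0)), 1)
  expect_equal(as.numeric(poibin_tail(c(0.1, 0.2, 0.3), 2)),
               poibin_enum_oracle(c(0.1, 0.2, 0.3), 2), tolerance = 1e-12)

  set.seed(13)
  for (i in 1:25) {
    n <- sample(1:10, 1)
    probs <- runif(n)
    k <- sample(0:n, 1)
    expect_equal(as.numeric(poibin_tail(probs, k)),
                 poibin_enum_oracle(probs, k), tolerance = 1e-10)
  }

  # identical probabilities: the Poisson-Binomial is a plain binomial
  for (n in c(10, 200, 1000)) {
    p <- 0.3; k <- floor(n * p) + 3
    expect_equal(as.numeric(poibin_tail(rep(p, n), k)),
                 pbinom(k - 1, n, p, lower.tail = FALSE), tolerance = 1e-8)
  }
  expect_error(poibin_tail(c(0.5, 1.2), 1), "\\[0,1\\]")
  expect_error(poibin_tail(c(0.5, 0.5), 3), "outside")
})

test_that("poibin tail is monotone in k and in each probability", {
  set.seed(17)
  probs <- runif(12)
  tails <- vapply(0:12, function(k) as.numeric(poibin_tail(probs, k)), 0)
  expect_true(all(diff(tails) <= 1e-15))
  for (i in 1:5) {
    j <- sample(12, 1)
    bumped <- probs; bumped[j] <- min(1, bumped[j] + runif(1, 0, 1 - bumped[j]))
    for (k in c(2, 6, 10)) {
      expect_gte(as.numeric(poibin_tail(bumped, k)) + 1e-12,
                 as.numeric(poibin_tail(probs, k)))
    }
  }
})

test_that("the refined normal approximation tracks the exact tail", {
  set.seed(19)
  probs <- runif(800, 0.01, 0.3)
  k <- floor(sum(probs)) + 15
  exact <- as.numeric(poibin_tail(probs, k, method = "dp"))
  approx <- as.numeric(poibin_tail(probs, k, method = "rna"))
  expect_equal(approx, exact, tolerance = 0.05)
  expect_identical(attr(poibin_tail(probs, k, dp_limit = 100), "tail_method"), "rna")
})

test_that("poibin enrichment collapses to the binomial on homogeneous matrices", {
  E <- 40; s <- 8
  m <- matrix(0, E, E, dimnames = list(sprintf("E%02d", 1:E), sprintf("R%02d", 1:E)))
  for (i in seq_len(E)) m[i, ((i + seq_len(s) - 2) %% E) + 1] <- 1
  spm <- Matrix::Matrix(m, sparse = TRUE)
  fit <- fit_probability_model(spm, tol = 1e-10)
  sel <- make_selection(rownames(m)[1:10], E)
  res <- poibin_enrichment(spm, sel, fit)
  d <- s / E
  for (i in seq_len(nrow(res))) {
    expect_equal(res$pvalue[i],
                 if (res$k[i] == 0) 1 else pbinom(res$k[i] - 1, 10, d, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  expect_equal(res$expected_k, rep(10 * d, E), tolerance = 1e-6)
})

test_that("poibin enrichment equals an independent convolution oracle", {
  cfg <- synth_config(n_events = 100, n_rbps = 10, seed = 23, mu_mean = -1,
                      mu_sd = 0.8, lam_sd = 0.8)
  sim <- simulate_exs(cfg)
  fit <- fit_probability_model(sim$matrix)
  sel_ids <- sample(rownames(sim$matrix), 30)
  sel <- make_selection(sel_ids, 100)
  res <- poibin_enrichment(sim$matrix, sel, fit)
  rows <- which(rownames(sim$matrix) %in% sel_ids)
  for (j in seq_len(10)) {
    probs <- model_prob(fit, rows, rep(j, 30))
    pmf <- poibin_pmf_convolve(probs)
    k <- res$k[j]
    want <- if (k == 0) 1 else sum(pmf[(k + 1):length(pmf)])
    expect_equal(res$pvalue[j], want, tolerance = 1e-9)
  }
  # bound to zero selected events -> k = 0, p = 1
  zero <- res[res$k == 0, ]
  if (nrow(zero)) expect_true(all(zero$pvalue == 1))
})

test_that("universe mismatches between model and matrix are caught", {
  set.seed(29)
  m <- rand_exs(12, 4)
  fit <- fit_probability_model(Matrix::Matrix(m, sparse = TRUE))
  sel <- make_selection(rownames(m)[1:4], 12)
  other <- Matrix::Matrix(rand_exs(12, 4), sparse = TRUE)
  rownames(other) <- paste0("X", 1:12)
  expect_error(poibin_enrichment(other, make_selection(paste0("X", 1:4), 12), fit),
               "different universe")
})
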