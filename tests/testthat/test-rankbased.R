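# Pre-ranked GSEA and the sparse rank-sum test.

stats_for <- function(m, p = NULL) {
  data.frame(event_id = rownames(m),
             pvalue = if (is.null(p)) runif(nrow(m)) else p,
             delta_psi = NA_real_, stringsAsFactors = FALSE)
}

test_that("ES is 1 when the hits occupy exactly the top ranks, negative at the bottom", {
  set.seed(31)
  E <- 20
  m <- matrix(0, E, 2, dimnames = list(sprintf("E%02d", 1:E), c("top", "bottom")))
  p <- sort(runif(E))                      # E01 most significant ... E20 least
  m[1:4, "top"] <- 1
  m[(E - 3):E, "bottom"] <- 1
  st <- stats_for(m, p)
  res <- gsea_enrichment(Matrix::Matrix(m, sparse = TRUE), st,
                         n_perm = 500, seed = 1)
  expect_equal(res$ES[res$rbp == "top"], 1, tolerance = 1e-12)
  expect_lte(res$ES[res$rbp == "bottom"], 0)
  expect_gt(res$pvalue[res$rbp == "bottom"], 0.5)
  expect_gte(min(res$pvalue), 1 / (max(res$n_perm) + 1))
})

test_that("the O(m) enrichment-score walk agrees with a full running-sum oracle", {
  set.seed(37)
  for (i in 1:50) {
    M <- sample(10:80, 1)
    m <- sample(1:(M - 1), 1)
    w <- abs(rnorm(M, sd = 2))
    hits <- sort(sample(M, m))
    expect_equal(spliceRBP:::cpp_gsea_es(w, hits),
                 gsea_es_oracle(w, hits, M), tolerance = 1e-12)
  }
  # all-zero hit weights fall back to classic unweighted steps
  w0 <- c(1, 0, 0, 2, 3)
  expect_equal(spliceRBP:::cpp_gsea_es(w0, c(2L, 3L)),
               gsea_es_oracle(w0, c(2, 3), 5), tolerance = 1e-12)
})

test_that("permutation p-values match exact enumeration of hit placements", {
  set.seed(41)
  M <- 10; m <- 3
  mat <- matrix(0, M, 1, dimnames = list(sprintf("E%02d", 1:M), "RBP"))
  hit_rows <- c(1, 2, 5)
  mat[hit_rows, 1] <- 1
  p <- sort(runif(M))
  st <- stats_for(mat, p)
  w <- rev(sort(-log10(p)))  # weights in ranking order (p ascending)
  es_obs <- gsea_es_oracle(w, hit_rows, M)
  all_placements <- combn(M, m)
  es_null <- apply(all_placements, 2, function(h) gsea_es_oracle(w, h, M))
  exact <- mean(es_null >= es_obs)

  B <- 20000
  res <- gsea_enrichment(Matrix::Matrix(mat, sparse = TRUE), st,
                         n_perm = B, max_perm = B, seed = 7)
  se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(res$pvalue - exact), 3 * se + 2 / B)
})

test_that("the classic (weight 0) permutation null depends only on M and m", {
  # exhaustively enumerate ES over all placements for two unrelated stat
  # vectors: identical ES multisets
  M <- 8; m <- 2
  placements <- combn(M, m)
  es_set <- function(w) sort(apply(placements, 2, function(h) {
    v <- rep(-1 / (M - m), M); v[h] <- 1 / m
    run <- cumsum(v); mx <- max(0, max(run)); mn <- min(0, min(run))
    if (mx >= -mn) mx else mn
  }))
  expect_equal(es_set(-log10(sort(runif(M)))), es_set(-log10(sort(runif(M)))))
})

test_that("GSEA is seeded-reproducible and validates its inputs", {
  set.seed(43)
  m <- rand_exs(30, 3)
  st <- stats_for(m)
  spm <- Matrix::Matrix(m, sparse = TRUE)
  r1 <- gsea_enrichment(spm, st, n_perm = 300, seed = 5)
  r2 <- gsea_enrichment(spm, st, n_perm = 300, seed = 5)
  expect_identical(r1, r2)

  st_flat <- stats_for(m, rep(0.5, 30))
  expect_error(gsea_enrichment(spm, st_flat, n_perm = 100), "equal")

  m_empty <- m; m_empty[, 2] <- 0
  expect_warning(res <- gsea_enrichment(Matrix::Matrix(m_empty, sparse = TRUE),
                                        st, n_perm = 100, seed = 1),
                 "empty or full")
  expect_false(colnames(m)[2] %in% res$rbp)
})

test_that("adaptive escalation raises the permutation count for tiny p-values", {
  set.seed(47)
  E <- 60
  m <- matrix(0, E, 1, dimnames = list(sprintf("E%02d", 1:E), "strong"))
  p <- sort(runif(E)); p[1:10] <- p[1:10] * 1e-6
  m[1:10, 1] <- 1
  st <- stats_for(m, p)
  res <- gsea_enrichment(Matrix::Matrix(m, sparse = TRUE), st,
                         n_perm = 100, max_perm = 10000, seed = 3)
  expect_gt(res$n_perm, 100)   # escalated beyond the initial budget
  expect_gte(res$pvalue, 1 / (res$n_perm + 1))
})

test_that("average ranks share tie means and sum to M(M+1)/2", {
  st <- data.frame(event_id = c("a", "b", "c"), pvalue = c(0.1, 0.1, 0.5))
  expect_equal(rank_events(st)$ranks, c(1.5, 1.5, 3))
  st2 <- data.frame(event_id = letters[1:5], pvalue = c(0.4, 0.1, 0.3, 0.2, 0.5))
  expect_setequal(rank_events(st2)$ranks, 1:5)
  st3 <- data.frame(event_id = letters[1:4], pvalue = rep(0.2, 4))
  expect_equal(rank_events(st3)$ranks, rep(2.5, 4))
  expect_equal(sum(rank_events(st2)$ranks), 5 * 6 / 2)
})

test_that("sparse rank-sum equals wilcox.test on random instances including ties", {
  set.seed(53)
  for (i in 1:40) {
    M <- sample(20:60, 1)
    m <- rand_exs(M, 5, density = runif(1, 0.2, 0.6))
    st <- rand_stats(rownames(m), ties = i %% 2 == 0)
    rk <- rank_events(st)
    for (alt in c("less", "greater", "two_sided")) {
      res <- suppressWarnings(
        wilcoxon_enrichment(Matrix::Matrix(m, sparse = TRUE), rk, alternative = alt))
      for (r in seq_len(nrow(res))) {
        j <- res$rbp[r]
        x <- st$pvalue[m[, j] == 1]
        y <- st$pvalue[m[, j] == 0]
        ref <- suppressWarnings(
          wilcox.test(x, y, alternative = sub("_", ".", alt),
                      exact = FALSE, correct = TRUE))
        expect_equal(res$U[r], unname(ref$statistic), tolerance = 1e-10)
        expect_equal(res$pvalue[r], ref$p.value, tolerance = 1e-10)
      }
    }
  }
})

test_that("a perfectly interleaved column sits at the null center", {
  M <- 8
  m <- matrix(0, M, 1, dimnames = list(paste0("E", 1:M), "R"))
  m[c(1, 4, 5, 8), 1] <- 1   # rank sum 18 = m(M+1)/2
  st <- data.frame(event_id = paste0("E", 1:M), pvalue = (1:M) / 10)
  res <- wilcoxon_enrichment(Matrix::Matrix(m, sparse = TRUE), rank_events(st))
  expect_equal(res$z, 0)
  expect_lt(abs(res$pvalue - 0.5), 0.06)  # off-center only by the continuity correction

  m2 <- matrix(0, 4, 1, dimnames = list(paste0("E", 1:4), "R"))
  m2[1:2, 1] <- 1
  st2 <- data.frame(event_id = paste0("E", 1:4), pvalue = (1:4) / 10)
  res2 <- wilcoxon_enrichment(Matrix::Matrix(m2, sparse = TRUE), rank_events(st2))
  expect_equal(res2$U, 0)
  expect_lt(res2$pvalue, 0.5)

  expect_error(wilcoxon_enrichment(Matrix::Matrix(m2, sparse = TRUE),
                                   rank_events(st)), "match")
})

test_that("rank-sum type-I error is nominal for independent columns", {
  set.seed(59)
  M <- 100; B <- 2000
  cols <- matrix(as.numeric(runif(M * B) < 0.2), M, B,
                 dimnames = list(sprintf("E%03d", 1:M), sprintf("C%04d", 1:B)))
  st <- data.frame(event_id = rownames(cols), pvalue = runif(M))
  res <- suppressWarnings(
    wilcoxon_enrichment(Matrix::Matrix(cols, sparse = TRUE), rank_events(st)))
  rate <- mean(res$pvalue < 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), ci + 0.005)
})
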