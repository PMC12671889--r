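# independent classical-CCA oracle: generalized eigendecomposition of
# Cxx^-1 Cxy Cyy^-1 Cyx; eigenvalues are squared canonical correlations
classical_cca_oracle <- function(X, Y) {
  Cxx <- cov(X); Cyy <- cov(Y); Cxy <- cov(X, Y)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  ev <- eigen(M, only.values = TRUE)$values
  sqrt(pmax(Re(ev), 0))
}

test_that("RCCA matches the classical-CCA eigen-oracle as c -> 0", {
  set.seed(10)
  for (i in 1:10) {
    X <- scale(matrix(rnorm(50 * 4), 50, 4))
    Y <- scale(matrix(rnorm(50 * 3), 50, 3))
    colnames(X) <- paste0("x", 1:4); colnames(Y) <- paste0("y", 1:3)
    fit <- rcca_fit(X, Y, c_x = 1e-12, K = 3)
    oracle <- sort(classical_cca_oracle(X, Y), decreasing = TRUE)[1:3]
    expect_equal(fit$cancor, oracle, tolerance = 1e-6)
  }
})

test_that("RCCA at c = 1 reduces to the SVD of the cross-covariance (PLS)", {
  set.seed(11)
  X <- scale(matrix(rnorm(60 * 5), 60, 5))
  Y <- scale(matrix(rnorm(60 * 4), 60, 4))
  colnames(X) <- paste0("x", 1:5); colnames(Y) <- paste0("y", 1:4)
  fit <- rcca_fit(X, Y, c_x = 1, K = 2)
  sv <- svd(cov(X, Y))
  for (k in 1:2) {
    expect_lt(1 - abs(sum(fit$u[, k] * sv$u[, k])) /
                sqrt(sum(fit$u[, k]^2) * sum(sv$u[, k]^2)), 1e-8)
    expect_lt(1 - abs(sum(fit$v[, k] * sv$v[, k])) /
                sqrt(sum(fit$v[, k]^2) * sum(sv$v[, k]^2)), 1e-8)
  }
})

test_that("weights are normalized in the regularized metric and X = Y is exact", {
  set.seed(12)
  X <- scale(matrix(rnorm(80 * 3), 80, 3))
  colnames(X) <- paste0("x", 1:3)
  fit_self <- rcca_fit(X, X, c_x = 0, K = 1)
  expect_equal(fit_self$cancor[1], 1, tolerance = 1e-8)

  Y <- scale(matrix(rnorm(80 * 4), 80, 4)); colnames(Y) <- paste0("y", 1:4)
  for (c_ in c(0, 0.3, 0.9)) {
    fit <- rcca_fit(X, Y, c_x = c_, K = 2)
    Rxx <- (1 - c_) * cov(X) + c_ * diag(3)
    for (k in 1:2) {
      expect_equal(drop(t(fit$u[, k]) %*% Rxx %*% fit$u[, k]), 1,
                   tolerance = 1e-8)
    }
  }
  expect_error(rcca_fit(X, Y, c_x = 1.2), "\\[0, 1\\]")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(rcca_fit(Xb, Y, c_x = 0.5), "finite")
})

test_that("training canonical correlation is nonincreasing in c", {
  set.seed(13)
  X <- scale(matrix(rnorm(60 * 5), 60, 5))
  Y <- scale(matrix(rnorm(60 * 4), 60, 4))
  colnames(X) <- paste0("x", 1:5); colnames(Y) <- paste0("y", 1:4)
  rs <- vapply(default_grid(),
               function(c_) rcca_fit(X, Y, c_x = c_)$cancor[1], 1.0)
  expect_true(all(diff(rs) <= 1e-8))
})

test_that("projection is consistent, linear, and validates columns", {
  set.seed(14)
  co <- simulate_cohort(small_config(n = 4000, r = 0.5, seed = 15))
  m <- cohort_matrices(co)
  train <- 1:2000; hold <- 2001:4000
  pf <- preprocess_fit(m$X[train, ], m$Y[train, ], m$confounds[train, ])
  fit <- rcca_fit(pf$X, pf$Y, c_x = 0.5)

  sc_tr <- rcca_project(fit, pf$X, pf$Y)
  expect_equal(canonical_correlation(sc_tr, 1), fit$cancor[1],
               tolerance = 1e-10)
  sc0 <- rcca_project(fit, pf$X * 0, pf$Y * 0)
  expect_true(all(sc0$x == 0) && all(sc0$y == 0))

  ph <- preprocess_apply(pf$transforms, m$X[hold, ], m$Y[hold, ],
                         m$confounds[hold, ])
  r_hold <- canonical_correlation(rcca_project(fit, ph$X, ph$Y), 1)
  expect_true(r_hold > 0.42 && r_hold < 0.58)

  Xbad <- pf$X; colnames(Xbad)[1] <- "nope"
  expect_error(rcca_project(fit, Xbad, pf$Y), "nope")
})

test_that("independent scores give near-zero canonical correlation", {
  set.seed(16)
  sc <- structure(list(x = matrix(rnorm(10000), ncol = 1),
                       y = matrix(rnorm(10000), ncol = 1)),
                  class = "rcca_scores")
  expect_lt(abs(canonical_correlation(sc, 1)), 0.05)
  expect_error(canonical_correlation(
    structure(list(x = matrix(1, 10, 1), y = matrix(rnorm(10), 10, 1)),
              class = "rcca_scores"), 1), "Constant")
})

test_that("loadings are correlations with the score", {
  set.seed(17)
  score <- rnorm(300)
  data <- cbind(same = score,
                ortho = qr.resid(qr(cbind(1, score)), rnorm(300)),
                noise = rnorm(300))
  l <- compute_loadings(data, score)
  expect_equal(unname(l["same"]), 1, tolerance = 1e-12)
  expect_lt(abs(l["ortho"]), 1e-10)
  expect_true(all(abs(l) <= 1))

  # planted-null column at n = 4000: loading stays near zero
  cfg <- small_config(n = 4000, r = 0.5, seed = 18)
  cfg$planted_dims[[1]]$y_other <- 0     # columns outside blocks unweighted
  co <- simulate_cohort(cfg)
  ysc <- co$truth$y_scores[, 1]
  v <- co$truth$v[, 1]
  null_cols <- which(abs(v) < 1e-12)
  expect_gt(length(null_cols), 0)
  l2 <- compute_loadings(as.matrix(co$Y[-1])[, null_cols, drop = FALSE], ysc)
  expect_lt(abs(l2[[1]]), 0.05)
  expect_lt(mean(abs(l2)), 0.05)

  dc <- cbind(flat = rep(1, 300), ok = rnorm(300))
  expect_warning(l3 <- compute_loadings(dc, score), "flat")
  expect_true(is.na(l3["flat"]))
})

test_that("projection deflation removes the dimension's variance", {
  set.seed(19)
  X <- scale(matrix(rnorm(200 * 6), 200, 6))
  Y <- scale(matrix(rnorm(200 * 5), 200, 5))
  colnames(X) <- paste0("x", 1:6); colnames(Y) <- paste0("y", 1:5)
  fit <- rcca_fit(X, Y, c_x = 0.2)
  sc <- rcca_project(fit, X, Y)
  defl <- rcca_deflate(X, Y, sc, 1)
  expect_lt(max(abs(cor(defl$X, sc$x[, 1]))), 1e-10)
  expect_lt(max(abs(cor(defl$Y, sc$y[, 1]))), 1e-10)

  # deflating an already-orthogonal matrix is a no-op
  defl2 <- rcca_deflate(defl$X, defl$Y, sc, 1)
  expect_equal(defl2$X, defl$X, tolerance = 1e-12)

  # scores refit on deflated data are uncorrelated with removed scores
  fit2 <- rcca_fit(defl$X, defl$Y, c_x = 0.2)
  sc2 <- rcca_project(fit2, defl$X, defl$Y)
  expect_lt(abs(cor(sc2$x[, 1], sc$x[, 1])), 1e-8)
})

test_that("deflation then refitting recovers the second planted dimension", {
  co <- simulate_cohort(two_dim_config(n = 4000, seed = 43))
  m <- cohort_matrices(co)
  pf <- preprocess_fit(m$X, m$Y, m$confounds)
  fit1 <- rcca_fit(pf$X, pf$Y, c_x = 0.5)
  sc1 <- rcca_project(fit1, pf$X, pf$Y)
  defl <- rcca_deflate(pf$X, pf$Y, sc1, 1)
  fit2 <- rcca_fit(defl$X, defl$Y, c_x = 0.5)
  cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gte(cosine(fit1$v[, 1], co$truth$v[, 1]), 0.8)
  expect_gte(cosine(fit2$v[, 1], co$truth$v[, 2]), 0.8)
})

test_that("models round-trip through their text serialization", {
  set.seed(21)
  X <- scale(matrix(rnorm(100 * 4), 100, 4))
  Y <- scale(matrix(rnorm(100 * 3), 100, 3))
  colnames(X) <- paste0("x", 1:4); colnames(Y) <- paste0("y", 1:3)
  fit <- rcca_fit(X, Y, c_x = 0.3, K = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_rcca(fit, f)
  back <- read_rcca(f)
  expect_equal(back$u, fit$u, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$cancor, fit$cancor, tolerance = 1e-12)
  sc <- rcca_project(back, X, Y)
  expect_equal(canonical_correlation(sc, 1), fit$cancor[1],
               tolerance = 1e-10)
})

test_that("pipeline results are invariant to a joint sign flip of (u, v)", {
  set.seed(20)
  X <- scale(matrix(rnorm(150 * 4), 150, 4))
  Y <- scale(matrix(rnorm(150 * 3), 150, 3))
  colnames(X) <- paste0("x", 1:4); colnames(Y) <- paste0("y", 1:3)
  fit <- rcca_fit(X, Y, c_x = 0.3)
  flipped <- fit
  flipped$u <- -fit$u; flipped$v <- -fit$v
  sc <- rcca_project(fit, X, Y)
  scf <- rcca_project(flipped, X, Y)
  expect_equal(canonical_correlation(sc, 1), canonical_correlation(scf, 1))
  d1 <- rcca_deflate(X, Y, sc, 1)
  d2 <- rcca_deflate(X, Y, scf, 1)
  expect_equal(d1$X, d2$X, tolerance = 1e-12)
})
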