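test_that("split scheme: disjoint partitions, determinism, stratification", {
  sch <- make_splits(100, n_outer = 5, n_inner = 5, holdout_frac = 0.2,
                     seed = 1)
  for (sp in sch$outer) {
    expect_length(sp$holdout, 20)
    expect_length(intersect(sp$holdout, sp$optimization), 0)
    expect_setequal(c(sp$holdout, sp$optimization), 1:100)
    for (inn in sp$inner) {
      expect_length(intersect(inn$train, inn$test), 0)
      expect_setequal(c(inn$train, inn$test), seq_along(sp$optimization))
    }
  }
  expect_identical(make_splits(100, seed = 7), make_splits(100, seed = 7))

  lab <- rep(c("a", "b"), each = 100)
  schs <- make_splits(200, stratify_by = lab, holdout_frac = 0.2, seed = 2)
  for (sp in schs$outer) {
    tab <- table(lab[sp$holdout])
    expect_lte(abs(tab[["a"]] - tab[["b"]]), 1)
    tab_o <- table(lab[sp$optimization])
    expect_lte(abs(tab_o[["a"]] - tab_o[["b"]]), 1)
  }
  expect_error(make_splits(100, holdout_frac = 1.2), "\\(0, 1\\)")
})

test_that("weight stability: identity, sign-invariance, null level", {
  v <- rnorm(50)
  expect_equal(weight_stability(replicate(5, v, simplify = FALSE)), 1)
  expect_equal(weight_stability(list(v, -v)), 1)

  set.seed(3)
  null_level <- mean(replicate(200, {
    weight_stability(replicate(5, rnorm(100), simplify = FALSE))
  }))
  expect_lt(null_level, 0.25)

  expect_error(weight_stability(list(v)), "two")
  expect_error(weight_stability(list(rep(1, 5), rnorm(5))), "Constant")
})

test_that("hyperparameter selection prefers non-dominated candidates", {
  co <- simulate_cohort(small_config(n = 2000, r = 0.5, seed = 51))
  m <- cohort_matrices(co)
  sch <- make_splits(2000, seed = 52)
  sp <- sch$outer[[1]]
  Xo <- m$X[sp$optimization, ]; Yo <- m$Y[sp$optimization, ]
  cf <- m$confounds[sp$optimization, ]

  one <- select_hyperparameters(Xo, Yo, sp$inner, grid = 0.5,
                                confounds = cf)
  expect_equal(unname(one$chosen[["c_x"]]), 0.5)

  sel <- select_hyperparameters(Xo, Yo, sp$inner,
                                grid = c(1e-4, 0.5, 1 - 1e-4),
                                confounds = cf)
  best <- max(sel$table$mean_test_cor)
  chosen_cor <- sel$table$mean_test_cor[sel$table$chosen]
  expect_lt(best - chosen_cor, 0.1)

  # pure-noise cohort: selected candidate cannot show real test signal
  con <- simulate_cohort(null_config(n = 2000, seed = 53, n_parcels = 40,
                                     n_risk_factors = 20))
  mn <- cohort_matrices(con)
  schn <- make_splits(2000, seed = 54)
  spn <- schn$outer[[1]]
  seln <- select_hyperparameters(mn$X[spn$optimization, ],
                                 mn$Y[spn$optimization, ], spn$inner,
                                 grid = c(1e-4, 0.5, 1 - 1e-4),
                                 confounds = mn$confounds[spn$optimization, ])
  expect_lt(seln$table$mean_test_cor[seln$table$chosen], 0.15)
})

test_that("selection rank-sum rule breaks ties toward larger regularization", {
  # degenerate grid of identical candidates: both attain the same ranks
  co <- simulate_cohort(small_config(n = 400, seed = 55))
  m <- cohort_matrices(co)
  sch <- make_splits(400, seed = 56)
  sp <- sch$outer[[1]]
  sel <- select_hyperparameters(m$X[sp$optimization, ],
                                m$Y[sp$optimization, ], sp$inner,
                                grid = c(0.5, 0.5))
  expect_equal(unname(sel$chosen[["c_x"]]), 0.5)
  expect_equal(sum(sel$table$chosen), 1L)
})

test_that("permutation evaluation: p-value floor and subject-order invariance", {
  co <- simulate_cohort(small_config(n = 500, r = 0.6, seed = 61))
  m <- cohort_matrices(co)
  pf <- preprocess_fit(m$X[1:400, ], m$Y[1:400, ], m$confounds[1:400, ])
  ph <- preprocess_apply(pf$transforms, m$X[401:500, ], m$Y[401:500, ],
                         m$confounds[401:500, ])
  ev <- evaluate_dimension(pf$X, pf$Y, ph$X, ph$Y, c_x = 0.5,
                           n_perm = 200, n_splits = 5, seed = 62)
  expect_gte(ev$p_raw, 1 / 200)
  expect_gte(ev$p_corrected, 5 / 200)
  expect_lte(ev$p_corrected, 1)
  expect_length(ev$null, 200)

  # jointly permuting subject order of the optimization set leaves the
  # observed statistic unchanged
  set.seed(63)
  perm <- sample(400)
  ev2 <- evaluate_dimension(pf$X[perm, ], pf$Y[perm, ], ph$X, ph$Y,
                            c_x = 0.5, n_perm = 200, n_splits = 5,
                            seed = 62)
  expect_equal(ev2$observed, ev$observed, tolerance = 1e-10)

  expect_warning(
    evaluate_dimension(pf$X, pf$Y, ph$X, ph$Y, c_x = 0.5, n_perm = 50,
                       seed = 1),
    "100")
})

test_that("loading aggregation reproduces hand-computed mean/SD/stability", {
  # worked case: one variable with loadings {0.5, 0.5, 0.5, 0.5, -0.1}
  vals <- c(0.5, 0.5, 0.5, 0.5, -0.1)
  ly <- lapply(vals, function(v) c(varA = v, varB = 0.6, varC = 0.2))
  lx <- lapply(1:5, function(s) c(p1 = 0.3, p2 = -0.4))
  agg <- aggregate_loadings(lx, ly)
  row <- agg$loadings[agg$loadings$variable == "varA", ]
  expect_equal(row$mean, 0.38)
  expect_equal(row$sd, sd(vals))
  expect_equal(round(row$sd, 3), 0.268)
  expect_true(row$stable)   # 0.38 > 0.268

  # five identical vectors: SD zero, everything stable
  ident <- lapply(1:5, function(s) c(a = 0.4, b = -0.3, c = 0.1))
  agg2 <- aggregate_loadings(ident, ident)
  expect_true(all(agg2$loadings$sd == 0))
  expect_true(all(agg2$loadings$stable))

  # a sign-flipped split is folded back by the alignment
  flip3 <- ident; flip3[[3]] <- -ident[[3]]
  agg3 <- aggregate_loadings(flip3, flip3)
  expect_equal(agg3$loadings, agg2$loadings)
  expect_equal(agg3$flips, c(1, 1, -1, 1, 1))
})

test_that("sequential extraction respects max_dimensions and finds planted signal", {
  co <- simulate_cohort(small_config(n = 600, r = 0.6, seed = 71))
  fit1 <- run_sequential_dimensions(co$X, co$Y, confounds = co$confounds,
                                    grid = c(0.1, 0.5, 0.9), n_perm = 150,
                                    max_dimensions = 1, seed = 72)
  expect_length(fit1$dimensions, 1)
  expect_true(fit1$dimensions[[1]]$omnibus)
  expect_equal(nrow(tidy(fit1, "results")), 5)
  expect_s3_class(autoplot(fit1), "ggplot")

  # corrected p respects the Bonferroni identity
  res <- tidy(fit1, "results")
  expect_equal(res$p_corrected, pmin(1, 5 * res$p_raw))
})

test_that("leakage guard: holdout mutation never changes training-side fits", {
  co <- simulate_cohort(small_config(n = 300, seed = 81))
  m <- cohort_matrices(co)
  sch <- make_splits(300, seed = 82)
  sp <- sch$outer[[1]]

  mutate_holdout <- function(M) { M[sp$holdout, ] <- 1e6; M }
  X_mut <- mutate_holdout(m$X)
  Y_mut <- mutate_holdout(m$Y)

  sel <- select_hyperparameters(m$X[sp$optimization, ],
                                m$Y[sp$optimization, ], sp$inner,
                                grid = c(0.1, 0.9),
                                confounds = m$confounds[sp$optimization, ])
  sel_mut <- select_hyperparameters(X_mut[sp$optimization, ],
                                    Y_mut[sp$optimization, ], sp$inner,
                                    grid = c(0.1, 0.9),
                                    confounds = m$confounds[sp$optimization, ])
  expect_identical(sel, sel_mut)

  pf <- preprocess_fit(m$X[sp$optimization, ], m$Y[sp$optimization, ],
                       m$confounds[sp$optimization, ])
  pf_mut <- preprocess_fit(X_mut[sp$optimization, ],
                           Y_mut[sp$optimization, ],
                           m$confounds[sp$optimization, ])
  expect_identical(pf$transforms, pf_mut$transforms)

  ph <- preprocess_apply(pf$transforms, m$X[sp$holdout, ],
                         m$Y[sp$holdout, ], m$confounds[sp$holdout, ])
  ph_mut <- preprocess_apply(pf$transforms, X_mut[sp$holdout, ],
                             Y_mut[sp$holdout, ], m$confounds[sp$holdout, ])
  ev <- evaluate_dimension(pf$X, pf$Y, ph$X, ph$Y, c_x = 0.5,
                           n_perm = 100, seed = 83)
  ev_mut <- evaluate_dimension(pf$X, pf$Y, ph_mut$X, ph_mut$Y, c_x = 0.5,
                               n_perm = 100, seed = 83)
  expect_identical(ev$model$u, ev_mut$model$u)
  expect_identical(ev$model$v, ev_mut$model$v)
})
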