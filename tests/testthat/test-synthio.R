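test_that("parcel geometry: counts, unit norms, mirror symmetry, determinism", {
  geom <- simulate_parcel_geometry(148, seed = 1)
  expect_equal(unname(table(geom$hemisphere)[c("L", "R")]),
               c(74L, 74L), ignore_attr = TRUE)
  cent <- as.matrix(geom[, c("x", "y", "z")])
  expect_true(all(abs(sqrt(rowSums(cent^2)) - 1) < 1e-9))

  g4 <- simulate_parcel_geometry(4, seed = 2)
  left <- as.matrix(g4[g4$hemisphere == "L", c("x", "y", "z")])
  right <- as.matrix(g4[g4$hemisphere == "R", c("x", "y", "z")])
  expect_equal(right, left %*% diag(c(-1, 1, 1)), ignore_attr = TRUE)

  expect_identical(simulate_parcel_geometry(148, seed = 5),
                   simulate_parcel_geometry(148, seed = 5))
  expect_false(isTRUE(all.equal(simulate_parcel_geometry(148, seed = 5)$x,
                                simulate_parcel_geometry(148, seed = 6)$x)))

  expect_error(simulate_parcel_geometry(147), "even")
  expect_error(simulate_parcel_geometry(2), "even")
})

test_that("cohort generation is deterministic and has the study shapes", {
  cfg <- synth_config(seed = 9)   # defaults: n=7370, q=68, p=148
  co <- simulate_cohort(cfg)
  expect_equal(dim(as.matrix(co$X[-1])), c(7370L, 148L))
  expect_equal(dim(as.matrix(co$Y[-1])), c(7370L, 68L))
  expect_equal(nrow(co$confounds), 7370L)
  expect_false(anyNA(co$X) || anyNA(co$Y) || anyNA(co$confounds))
  expect_identical(co$X$subject_id, co$Y$subject_id)
  expect_identical(co$X$subject_id, co$confounds$subject_id)

  co2 <- simulate_cohort(synth_config(seed = 9))
  expect_identical(co, co2)

  # block structure: within-block correlation beats between-block by >= 0.2
  cm <- risk_factor_correlation_matrix(co$Y)
  blocks <- list(grep("^body_composition", colnames(cm)),
                 grep("^air_pollution", colnames(cm)))
  within <- unlist(lapply(blocks, function(b) {
    m <- cm[b, b]; m[upper.tri(m)]
  }))
  between <- cm[blocks[[1]], blocks[[2]]]
  expect_gt(mean(within) - mean(abs(between)), 0.2)

  # marker link: Spearman with dim-1 true risk-factor scores near -0.39
  rho <- cor(co$confounds$marker, co$truth$y_scores[, 1],
             method = "spearman")
  expect_lt(abs(rho - (-0.39)), 0.07)

  # age range matches the sampled population
  expect_true(all(co$confounds$age >= 46 & co$confounds$age <= 81))
})

test_that("planted canonical correlations are calibrated", {
  # r = 0.5 at n = 4000: truth score correlation within sampling error
  co <- simulate_cohort(small_config(n = 4000, r = 0.5, seed = 11))
  r_hat <- cor(co$truth$x_scores[, 1], co$truth$y_scores[, 1])
  expect_true(r_hat > 0.47 && r_hat < 0.53)

  # 3/sqrt(n) calibration bound at n = 2000
  co2 <- simulate_cohort(small_config(n = 2000, r = 0.3, seed = 12))
  r2 <- cor(co2$truth$x_scores[, 1], co2$truth$y_scores[, 1])
  expect_lt(abs(r2 - 0.3), 3 / sqrt(2000))

  # a planted correlation of zero is a null construction
  co0 <- simulate_cohort(small_config(n = 5000, r = 0, seed = 13))
  r0 <- cor(co0$truth$x_scores[, 1], co0$truth$y_scores[, 1])
  expect_lt(abs(r0), 3 / sqrt(5000))

  # unreachable targets rejected at configuration time
  expect_error(small_config(r = 1), "unreachable")
  expect_error(
    synth_config(planted_dims = list(
      list(canonical_correlation = 0.2, x_weight_smoothness = 0.5,
           y_block_pattern = c(a = 1, b = 0)),
      list(canonical_correlation = 0.5, x_weight_smoothness = 0.5,
           y_block_pattern = c(a = 0, b = 1)))),
    "descending")
})

test_that("configured confound effects are recoverable by regression", {
  cfg <- small_config(n = 2000, seed = 21)
  # age effect of 0.3 planted on the first parcel column only
  cfg$confound_effects <- list(age = list(x = c(0.3, rep(0, 39)), y = 0),
                               sex = list(x = 0, y = 0),
                               site = list(x = 0, y = 0))
  co <- simulate_cohort(cfg)
  age_z <- co$truth$confound_design[, "age_z"]
  rz <- fit_residualizer(co$X, data.frame(age = age_z))
  betas <- rz$coefficients["age", ]
  expect_lt(abs(betas[[1]] - 0.3), 0.05)
  expect_lt(mean(abs(betas[-1])), 0.05)
})

test_that("cohort round-trips through CSV files", {
  co <- simulate_cohort(small_config(n = 50, seed = 31))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("X.csv", "Y.csv", "confounds.csv", "geometry.csv",
                    "truth.json"))
  back <- read_cohort(dir)
  expect_equal(as.matrix(back$X[-1]), as.matrix(co$X[-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$truth$canonical_correlations,
               co$truth$canonical_correlations)
  expect_equal(unname(back$truth$v), unname(co$truth$v),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("annotation maps hit their correlation targets and stay smooth", {
  geom <- simulate_parcel_geometry(148, seed = 2)
  ref <- simulate_smooth_maps(geom, smoothness = 0.5, seed = 4)[[1]]

  maps <- simulate_annotation_maps(geom, ref, c(-0.4, 0, 0.4, 1),
                                   smoothness = 0.5, seed = 5)
  achieved <- vapply(maps, function(m) cor(m, ref), 1.0)
  expect_equal(unname(achieved), c(-0.4, 0, 0.4, 1), tolerance = 1e-10)
  expect_true(all(diff(achieved) > 0))   # ordered as the targets

  # zero-target map is spatially smoother than an IID shuffle of itself
  m0 <- maps[[2]]
  obs <- neighbour_similarity(m0, geom)
  set.seed(1)
  shuf <- replicate(50, neighbour_similarity(sample(m0), geom))
  expect_gt(obs, max(shuf))

  expect_error(simulate_annotation_maps(geom, ref, 1.2), "\\[-1, 1\\]")
  expect_error(simulate_annotation_maps(geom, ref[-1], 0.5), "length")
})
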