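# shared fixture builders; everything is generated in code at test time

# small single-dimension cohort: 40 parcels, 20 risk factors
small_config <- function(n = 600, r = 0.6, seed = 3, ...) {
  synth_config(
    n_subjects = n, n_risk_factors = 20, n_parcels = 40,
    planted_dims = list(list(
      canonical_correlation = r, x_weight_smoothness = 0.5,
      y_block_pattern = c(body_composition = -1, air_pollution = 0.5),
      y_other = 0.3)),
    rf_blocks = list(
      list(name = "body_composition", size = 6, within_correlation = 0.7),
      list(name = "air_pollution", size = 4, within_correlation = 0.7)),
    seed = seed, ...
  )
}

# cohort with no planted association (global null)
null_config <- function(n = 400, seed = 1, n_parcels = 16,
                        n_risk_factors = 10) {
  synth_config(
    n_subjects = n, n_risk_factors = n_risk_factors, n_parcels = n_parcels,
    planted_dims = list(),
    rf_blocks = list(
      list(name = "body_composition", size = 4, within_correlation = 0.5)),
    confound_effects = list(age = list(x = 0.1, y = 0.1),
                            sex = list(x = 0.05, y = 0.05),
                            site = list(x = 0, y = 0)),
    marker_link = NULL, seed = seed
  )
}

# two planted dimensions at the full study shape (148 parcels, 68 rf)
two_dim_config <- function(n = 4000, r1 = 0.5, r2 = 0.3, seed = 42) {
  synth_config(
    n_subjects = n, n_risk_factors = 68, n_parcels = 148,
    planted_dims = list(
      list(canonical_correlation = r1, x_weight_smoothness = 0.5,
           y_block_pattern = c(body_composition = -1, air_pollution = -0.3),
           y_other = 0.4),
      list(canonical_correlation = r2, x_weight_smoothness = 0.5,
           y_block_pattern = c(body_composition = 0.8, air_pollution = -0.8),
           y_other = 0.3)),
    rf_blocks = list(
      list(name = "body_composition", size = 10, within_correlation = 0.7),
      list(name = "air_pollution", size = 6, within_correlation = 0.7)),
    seed = seed
  )
}

cohort_matrices <- function(cohort) {
  list(X = as.matrix(cohort$X[-1]), Y = as.matrix(cohort$Y[-1]),
       confounds = as.data.frame(
         cohort$confounds[c("age", "sex", "site")]))
}

# mean correlation of nearest-neighbour parcel pairs: a cheap spatial
# autocorrelation statistic used to compare smooth maps with shuffles
neighbour_similarity <- function(map, geometry) {
  cent <- as.matrix(geometry[, c("x", "y", "z")])
  d <- as.matrix(dist(cent))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  z <- as.numeric(scale(map))
  mean(z * z[nn])
}
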