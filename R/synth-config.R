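#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of [simulate_cohort()]. The defaults
#' mirror the study conditions the pipeline is designed for: 7,370
#' subjects, 68 risk-factor variables, 148 cortical parcels, two planted
#' latent dimensions whose canonical correlations (0.32 and 0.10) sit at
#' the holdout ranges reported for the cardiometabolic-health and
#' physical-robustness dimensions, two blocks of highly intercorrelated
#' risk factors (body composition, air pollution), and a CRP-like
#' inflammation marker rank-linked to the first dimension at
#' Spearman -0.39.
#'
#' @param n_subjects Number of subjects.
#' @param n_risk_factors Number of risk-factor columns (the Y side).
#' @param n_parcels Number of cortical parcels (the X side); even, split
#'   across two mirrored hemispheres.
#' @param planted_dims List of planted latent dimensions. Each element is
#'   a list with `canonical_correlation` (in `[0, 1)`, listed in
#'   descending order), `x_weight_smoothness` (Gaussian length-scale, in
#'   chord-distance units on the unit sphere, of the smooth brain weight
#'   map), `y_block_pattern` (signed magnitude per risk-factor block) and
#'   optionally `y_other` (magnitude, with random signs, on columns
#'   outside all blocks; default 0).
#' @param rf_blocks List of risk-factor blocks, each a list with `name`,
#'   `size` and `within_correlation` (in `[0, 1)`). Block sizes must sum
#'   to at most `n_risk_factors`.
#' @param confound_effects Named list with elements `age`, `sex`, `site`;
#'   each a list with entries `x` and `y` giving the effect size per
#'   column (scalar recycled, or one value per column). Age enters as a
#'   z-score, sex as a 0/1 indicator; site effects are per-level offsets
#'   drawn with the stated standard deviation.
#' @param marker_link List with `dim_index` and `spearman_target` in
#'   `(-1, 1)`: the marker is generated monotone in that dimension's true
#'   risk-factor score and then exponentiated, so its Spearman
#'   correlation with the score hits the target. `NULL` for an unlinked
#'   (pure lognormal noise) marker.
#' @param noise_sd Standard deviation of the additive view noise. The
#'   default (0.3) is calibrated so planted-dimension loadings span the
#'   magnitudes typical of population cortical-structure studies
#'   (risk-factor loadings up to ~0.6-0.8 inside the driving block,
#'   brain loadings up to ~0.4-0.5).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration including this seed.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 7370,
                         n_risk_factors = 68,
                         n_parcels = 148,
                         planted_dims = list(
                           list(canonical_correlation = 0.32,
                                x_weight_smoothness = 0.5,
                                y_block_pattern = c(body_composition = -1,
                                                    air_pollution = -0.3),
                                y_other = 0.4),
                           list(canonical_correlation = 0.10,
                                x_weight_smoothness = 0.5,
                                y_block_pattern = c(body_composition = 0.8,
                                                    air_pollution = -0.8),
                                y_other = 0.3)
                         ),
                         rf_blocks = list(
                           list(name = "body_composition", size = 10,
                                within_correlation = 0.7),
                           list(name = "air_pollution", size = 6,
                                within_correlation = 0.7)
                         ),
                         confound_effects = list(
                           age = list(x = 0.1, y = 0.1),
                           sex = list(x = 0.05, y = 0.05),
                           site = list(x = 0.05, y = 0.05)
                         ),
                         marker_link = list(dim_index = 1,
                                            spearman_target = -0.39),
                         noise_sd = 0.3,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_risk_factors = as.integer(n_risk_factors),
    n_parcels = as.integer(n_parcels),
    planted_dims = planted_dims,
    rf_blocks = rf_blocks,
    confound_effects = confound_effects,
    marker_link = marker_link,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (cfg$n_subjects < 4) stop("`n_subjects` must be >= 4.", call. = FALSE)
  if (cfg$n_parcels %% 2 != 0 || cfg$n_parcels < 4) {
    stop("`n_parcels` must be an even integer >= 4.", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be positive.", call. = FALSE)

  rs <- vapply(cfg$planted_dims, function(d) d$canonical_correlation, 1.0)
  if (length(rs)) {
    if (any(rs >= 1) || any(rs < 0)) {
      stop("Planted canonical correlations must lie in [0, 1): a target ",
           ">= 1 is unreachable in the presence of noise.", call. = FALSE)
    }
    if (is.unsorted(rev(rs), strictly = FALSE) && any(diff(rs) > 0)) {
      stop("Planted canonical correlations must be sorted in descending ",
           "order.", call. = FALSE)
    }
    nb <- length(cfg$rf_blocks)
    ok <- vapply(cfg$planted_dims,
                 function(d) length(d$y_block_pattern) == nb, TRUE)
    if (!all(ok)) {
      stop("Each `y_block_pattern` must give one magnitude per risk-factor ",
           "block (", nb, " blocks configured).", call. = FALSE)
    }
  }

  sizes <- vapply(cfg$rf_blocks, function(b) as.integer(b$size), 1L)
  if (sum(sizes) > cfg$n_risk_factors) {
    stop("Risk-factor block sizes exceed `n_risk_factors`.", call. = FALSE)
  }
  wc <- vapply(cfg$rf_blocks, function(b) b$within_correlation, 1.0)
  if (any(wc < 0 | wc >= 1)) {
    stop("Block `within_correlation` values must lie in [0, 1).",
         call. = FALSE)
  }

  if (!is.null(cfg$marker_link)) {
    tgt <- cfg$marker_link$spearman_target
    if (abs(tgt) >= 1) {
      stop("`spearman_target` must lie strictly inside (-1, 1).",
           call. = FALSE)
    }
    di <- cfg$marker_link$dim_index
    if (length(cfg$planted_dims) &&
        (di < 1 || di > length(cfg$planted_dims))) {
      stop("`marker_link$dim_index` does not name a planted dimension.",
           call. = FALSE)
    }
  }
  structure(cfg, class = "synth_config")
}
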