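#' Simulate a cohort with planted brain/risk-factor latent dimensions
#'
#' Generates the two data views the analysis pipeline consumes — a
#' subjects-by-parcels brain matrix X and a subjects-by-risk-factors
#' matrix Y — together with confounds (age, sex, site), a CRP-like
#' inflammation marker, and the planted ground truth needed for
#' parameter-recovery tests.
#'
#' For each planted dimension k a pair of latent subject scores is drawn
#' from a bivariate standard normal with correlation equal to the
#' configured canonical correlation. The x-side score enters X through a
#' spatially smooth weight map over the parcel centroids (Gaussian
#' kernel on chord distance); the y-side score enters Y through a
#' block-patterned weight vector. Weight vectors are orthonormal across
#' dimensions, and the additive view noise is projected orthogonal to
#' them, so the population canonical correlation of each dimension is
#' exactly the configured value and the recorded truth scores carry it
#' too. Risk-factor blocks impose within-block correlation through
#' shared block factors; confound effects are added linearly (age as a
#' z-score, sex as 0/1, site as per-level offsets); the marker is a
#' monotone (then exponentiated, hence right-skewed and nonnegative)
#' function of one dimension's true risk-factor score, calibrated so its
#' Spearman correlation hits the configured target.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort` with elements `X`, `Y`,
#'   `confounds` (tibbles sharing a `subject_id` first column; confounds
#'   carry `age`, `sex`, `site`, `marker`), `geometry` (a
#'   `parcel_geometry` tibble) and `truth` (list with `u`, `v`,
#'   `canonical_correlations`, `x_scores`, `y_scores`, `confound_design`).
#' @export
#' @examples
#' cohort <- simulate_cohort(synth_config(n_subjects = 200, seed = 7))
#' dim(as.matrix(cohort$X[-1]))
simulate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) config <- validate_synth_config(config)
  n <- config$n_subjects
  p <- config$n_parcels
  q <- config$n_risk_factors
  K <- length(config$planted_dims)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  geometry <- simulate_parcel_geometry(p, seed = config$seed)
  centroids <- geometry_matrix(geometry)

  rf_names <- risk_factor_names(config)
  block_of <- rf_block_index(config)      # 0 = outside all blocks

  ## --- planted weights --------------------------------------------------
  if (K > 0) {
    U <- vapply(config$planted_dims, function(d) {
      smooth_sphere_map(centroids, d$x_weight_smoothness)
    }, numeric(p))
    U <- orthonormalize(matrix(U, nrow = p))

    V <- vapply(config$planted_dims, function(d) {
      w <- numeric(q)
      for (b in seq_along(config$rf_blocks)) {
        w[block_of == b] <- d$y_block_pattern[[b]]
      }
      y_other <- if (is.null(d$y_other)) 0 else d$y_other
      n_out <- sum(block_of == 0)
      if (y_other != 0 && n_out > 0) {
        w[block_of == 0] <- y_other * sample(c(-1, 1), n_out, replace = TRUE)
      }
      w
    }, numeric(q))
    V <- orthonormalize(matrix(V, nrow = q))
  } else {
    U <- matrix(0, p, 0)
    V <- matrix(0, q, 0)
  }

  ## --- latent scores ----------------------------------------------------
  rs <- vapply(config$planted_dims, function(d) d$canonical_correlation, 1.0)
  x_scores <- matrix(stats::rnorm(n * K), n, K)
  y_scores <- matrix(0, n, K)
  for (k in seq_len(K)) {
    e <- stats::rnorm(n)
    y_scores[, k] <- rs[k] * x_scores[, k] + sqrt(1 - rs[k]^2) * e
  }

  ## --- confounds --------------------------------------------------------
  age <- stats::runif(n, 46, 81)
  sex <- sample(rep(0:1, length.out = n))
  site <- factor(sample(paste0("site", 1:4), n, replace = TRUE))
  age_z <- as.numeric(scale(age))
  site_mm <- stats::model.matrix(~ site - 1)

  ## --- assemble views ---------------------------------------------------
  X <- tcrossprod_or_zero(x_scores, U) +
    project_out(matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p), U)
  N <- block_noise(n, q, block_of, config) * config$noise_sd
  Y <- tcrossprod_or_zero(y_scores, V) + project_out(N, V)

  X <- X + confound_contrib(config$confound_effects, "x", p, age_z, sex, site_mm)
  Y <- Y + confound_contrib(config$confound_effects, "y", q, age_z, sex, site_mm)

  colnames(X) <- geometry$parcel_id
  colnames(Y) <- rf_names

  ## --- marker -----------------------------------------------------------
  if (!is.null(config$marker_link) && K > 0) {
    s <- y_scores[, config$marker_link$dim_index]
    rho_s <- config$marker_link$spearman_target
    rho_p <- 2 * sin(pi * rho_s / 6)           # Spearman -> Pearson (normal)
    a <- rho_p / sqrt(1 - rho_p^2)
    marker <- exp(a * s + stats::rnorm(n))
  } else {
    marker <- exp(stats::rnorm(n))
  }

  ids <- sprintf("S%05d", seq_len(n))
  out <- list(
    X = dplyr::bind_cols(tibble::tibble(subject_id = ids),
                         tibble::as_tibble(X)),
    Y = dplyr::bind_cols(tibble::tibble(subject_id = ids),
                         tibble::as_tibble(Y)),
    confounds = tibble::tibble(subject_id = ids, age = age, sex = sex,
                               site = site, marker = marker),
    geometry = geometry,
    truth = list(u = U, v = V, canonical_correlations = rs,
                 x_scores = x_scores, y_scores = y_scores,
                 confound_design = cbind(age_z = age_z, sex = sex, site_mm)),
    config = config
  )
  class(out) <- "synth_cohort"
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", nrow(x$X), " subjects, ",
      ncol(x$X) - 1L, " parcels, ", ncol(x$Y) - 1L, " risk factors, ",
      length(x$truth$canonical_correlations), " planted dimension(s) [r = ",
      paste(format(x$truth$canonical_correlations, digits = 2),
            collapse = ", "), "]\n", sep = "")
  invisible(x)
}

risk_factor_names <- function(config) {
  block_of <- rf_block_index(config)
  nm <- character(config$n_risk_factors)
  for (b in seq_along(config$rf_blocks)) {
    idx <- which(block_of == b)
    nm[idx] <- sprintf("%s_%02d", config$rf_blocks[[b]]$name, seq_along(idx))
  }
  idx <- which(block_of == 0)
  nm[idx] <- sprintf("rf_%02d", seq_along(idx))
  nm
}

rf_block_index <- function(config) {
  block_of <- integer(config$n_risk_factors)
  pos <- 1L
  for (b in seq_along(config$rf_blocks)) {
    sz <- as.integer(config$rf_blocks[[b]]$size)
    block_of[pos:(pos + sz - 1L)] <- b
    pos <- pos + sz
  }
  block_of
}

# one draw from a GP with kernel exp(-d^2 / (2 sigma^2)) on chord distance
smooth_sphere_map <- function(centroids, sigma) {
  d2 <- as.matrix(stats::dist(centroids))^2
  Kc <- exp(-d2 / (2 * sigma^2))
  ev <- eigen(Kc, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  as.numeric(ev$vectors %*% (sqrt(lam) * stats::rnorm(nrow(centroids))))
}

orthonormalize <- function(M) {
  if (ncol(M) == 0) return(M)
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) {
    stop("Planted weight patterns are collinear; make block patterns ",
         "linearly independent.", call. = FALSE)
  }
  Q <- qr.Q(qr_)
  # keep each column pointing the way its raw pattern did
  s <- sign(colSums(Q * M))
  s[s == 0] <- 1
  sweep(Q, 2, s, `*`)
}

project_out <- function(E, U) {
  if (ncol(U) == 0) return(E)
  E - (E %*% U) %*% t(U)
}

tcrossprod_or_zero <- function(S, W) {
  if (ncol(W) == 0) matrix(0, nrow(S), nrow(W)) else tcrossprod(S, W)
}

block_noise <- function(n, q, block_of, config) {
  N <- matrix(stats::rnorm(n * q), n, q)
  for (b in seq_along(config$rf_blocks)) {
    rho <- config$rf_blocks[[b]]$within_correlation
    idx <- which(block_of == b)
    g <- stats::rnorm(n)
    N[, idx] <- sqrt(rho) * g + sqrt(1 - rho) * N[, idx]
  }
  N
}

confound_contrib <- function(effects, side, ncol_out, age_z, sex, site_mm) {
  n <- length(age_z)
  out <- matrix(0, n, ncol_out)
  grab <- function(nm) {
    e <- effects[[nm]][[side]]
    if (is.null(e)) return(NULL)
    rep_len(e, ncol_out)
  }
  b_age <- grab("age")
  if (!is.null(b_age)) out <- out + outer(age_z, b_age)
  b_sex <- grab("sex")
  if (!is.null(b_sex)) out <- out + outer(sex, b_sex)
  e_site <- effects$site[[side]]
  if (!is.null(e_site) && any(e_site != 0)) {
    offsets <- matrix(stats::rnorm(ncol(site_mm) * ncol_out,
                                   sd = rep_len(e_site, 1)),
                      ncol(site_mm), ncol_out)
    out <- out + site_mm %*% offsets
  }
  out
}

#' Write / read a synthetic cohort as plain CSV files
#'
#' `write_cohort()` writes `X.csv`, `Y.csv`, `confounds.csv` (confounds
#' plus marker) and `geometry.csv`, all with a `subject_id` or
#' `parcel_id` leading column, plus a `truth.json` sidecar used only by
#' recovery tests. `read_cohort()` restores the object.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `synth_cohort` (without the generating config).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$X, file.path(dir, "X.csv"), row.names = FALSE)
  utils::write.csv(cohort$Y, file.path(dir, "Y.csv"), row.names = FALSE)
  utils::write.csv(cohort$confounds, file.path(dir, "confounds.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$geometry, file.path(dir, "geometry.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth_json <- lapply(truth, function(x) if (is.matrix(x)) unclass(as.data.frame(x)) else x)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) tibble::as_tibble(utils::read.csv(file.path(dir, f)))
  geometry <- rd("geometry.csv")
  class(geometry) <- c("parcel_geometry", class(geometry))
  confounds <- rd("confounds.csv")
  confounds$site <- factor(confounds$site)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    for (nm in c("u", "v", "x_scores", "y_scores", "confound_design")) {
      if (!is.null(truth[[nm]])) truth[[nm]] <- as.matrix(as.data.frame(truth[[nm]]))
    }
  }
  out <- list(X = rd("X.csv"), Y = rd("Y.csv"), confounds = confounds,
              geometry = geometry, truth = truth, config = NULL)
  class(out) <- "synth_cohort"
  out
}
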