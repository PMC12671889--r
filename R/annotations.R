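#' Simulate spatially smooth annotation maps with target correlations
#'
#' Builds parcel-wise maps that stand in for an annotation battery
#' (receptor densities, metabolic maps, functional gradients, ...) when
#' real annotation vectors are not available. Each map is a mixture of
#' the z-scored reference map and an independent smooth map that has
#' been residualized on the reference, so the in-sample Pearson
#' correlation with the reference equals the target exactly while the
#' map keeps spatial autocorrelation at the stated length-scale.
#'
#' @param geometry A `parcel_geometry` (see [simulate_parcel_geometry()]).
#' @param reference_map Numeric parcel-wise vector, one value per parcel
#'   in `geometry` order.
#' @param target_correlations Numeric vector of target Pearson
#'   correlations with the reference, each in `[-1, 1]`; a target of
#'   exactly +/-1 returns a rescaled (sign-flipped) copy of the
#'   reference.
#' @param smoothness Gaussian length-scale (chord distance) of the
#'   independent smooth component.
#' @param seed Integer seed.
#' @return A named list of parcel-wise numeric vectors (`map_1`, ...),
#'   one per target.
#' @export
simulate_annotation_maps <- function(geometry, reference_map,
                                     target_correlations,
                                     smoothness = 0.5, seed = 1L) {
  assert_parcel_geometry(geometry)
  centroids <- geometry_matrix(geometry)
  p <- nrow(centroids)
  if (length(reference_map) != p) {
    stop("`reference_map` length must match the geometry (", p, " parcels).",
         call. = FALSE)
  }
  if (any(abs(target_correlations) > 1)) {
    stop("Annotation correlation targets must lie in [-1, 1].", call. = FALSE)
  }
  if (stats::sd(reference_map) == 0) {
    stop("`reference_map` is constant; correlations are undefined.",
         call. = FALSE)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  ref_z <- as.numeric(scale(reference_map))
  maps <- lapply(seq_along(target_correlations), function(i) {
    t <- target_correlations[i]
    if (abs(t) == 1) return(t * reference_map / stats::sd(reference_map))
    g <- smooth_sphere_map(centroids, smoothness)
    # orthogonalize the smooth component to the reference in-sample
    g_perp <- stats::lm.fit(cbind(1, ref_z), g)$residuals
    g_perp <- as.numeric(scale(g_perp))
    t * ref_z + sqrt(1 - t^2) * g_perp
  })
  names(maps) <- sprintf("map_%d", seq_along(maps))
  maps
}

#' Draw independent spatially smooth parcel maps
#'
#' Gaussian-process draws on the parcel centroids with kernel
#' `exp(-d^2 / (2 * smoothness^2))` on chord distance — the package's
#' model of a spatially autocorrelated cortical map. Used to build
#' calibration fixtures for the spin test.
#'
#' @param geometry A `parcel_geometry`.
#' @param smoothness Gaussian length-scale (chord distance).
#' @param n_maps Number of independent draws.
#' @param seed Integer seed.
#' @return A list of `n_maps` parcel-wise numeric vectors.
#' @export
simulate_smooth_maps <- function(geometry, smoothness = 0.5, n_maps = 1L,
                                 seed = 1L) {
  assert_parcel_geometry(geometry)
  centroids <- geometry_matrix(geometry)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  d2 <- as.matrix(stats::dist(centroids))^2
  Kc <- exp(-d2 / (2 * smoothness^2))
  ev <- eigen(Kc, symmetric = TRUE)
  B <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  lapply(seq_len(n_maps), function(i) {
    as.numeric(B %*% stats::rnorm(nrow(centroids)))
  })
}
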