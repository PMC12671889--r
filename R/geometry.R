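#' Generate a synthetic parcel geometry on the unit sphere
#'
#' Builds quasi-uniform parcel centroids for two mirrored cortical
#' hemispheres. The left hemisphere is laid out as a Fibonacci-style
#' lattice restricted to the x < 0 half of the unit sphere; the right
#' hemisphere is its exact mirror image through the x = 0 plane. The
#' mirror symmetry is what the spin-permutation null assumes, so it is
#' guaranteed by construction. Real centroid tables (e.g., Destrieux
#' atlas centroids) can be supplied to downstream functions in the same
#' format instead.
#'
#' @param n_parcels Total number of parcels (even, at least 4); split
#'   equally across hemispheres. The Destrieux cortical parcellation used
#'   for the default study conditions has 148 parcels.
#' @param seed Integer seed; controls the rotational offset of the
#'   lattice inside the hemisphere so that different seeds give different
#'   (but equally uniform) layouts.
#'
#' @return A tibble of class `parcel_geometry` with columns `parcel_id`,
#'   `hemisphere` (`"L"`/`"R"`) and unit-norm centroid coordinates
#'   `x`, `y`, `z`.
#' @export
#' @examples
#' geom <- simulate_parcel_geometry(148, seed = 1)
#' table(geom$hemisphere)
simulate_parcel_geometry <- function(n_parcels, seed = 1L) {
  if (!is.numeric(n_parcels) || length(n_parcels) != 1L || n_parcels < 4 ||
      n_parcels %% 2 != 0) {
    stop("`n_parcels` must be an even integer >= 4.", call. = FALSE)
  }
  n_parcels <- as.integer(n_parcels)
  m <- n_parcels %/% 2L

  offset <- withr_seed_runif(seed)
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  golden <- pi * (3 - sqrt(5))
  # azimuth confined to (pi/2, 3*pi/2) => x < 0: the left half-sphere
  phi <- pi / 2 + ((i * golden + offset * pi) %% pi)
  r_xy <- sqrt(pmax(0, 1 - z^2))
  left <- cbind(x = r_xy * cos(phi), y = r_xy * sin(phi), z = z)
  left <- left / sqrt(rowSums(left^2))
  right <- left
  right[, "x"] <- -right[, "x"]

  out <- tibble::tibble(
    parcel_id = c(sprintf("L_%03d", seq_len(m)), sprintf("R_%03d", seq_len(m))),
    hemisphere = rep(c("L", "R"), each = m),
    x = c(left[, "x"], right[, "x"]),
    y = c(left[, "y"], right[, "y"]),
    z = c(left[, "z"], right[, "z"])
  )
  class(out) <- c("parcel_geometry", class(out))
  out
}

# uniform draw under a private RNG state, leaving the caller's untouched
withr_seed_runif <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  stats::runif(1)
}

geometry_matrix <- function(geometry) {
  stopifnot(all(c("x", "y", "z", "hemisphere", "parcel_id") %in% names(geometry)))
  m <- as.matrix(geometry[, c("x", "y", "z")])
  rownames(m) <- geometry$parcel_id
  m
}

#' @keywords internal
assert_parcel_geometry <- function(geometry) {
  m <- geometry_matrix(geometry)
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop("All parcel centroids must lie on the unit sphere.", call. = FALSE)
  }
  tab <- table(geometry$hemisphere)
  if (length(tab) != 2L || tab[["L"]] != tab[["R"]]) {
    stop("Geometry must contain equal parcel counts in hemispheres L and R.",
         call. = FALSE)
  }
  invisible(geometry)
}
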