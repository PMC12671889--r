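#' Generate spin permutations for a parcellated geometry
#'
#' Builds a spatial null for parcel-wise cortical maps: each
#' permutation draws a uniform random 3D rotation (QR orthonormalization
#' of a Gaussian matrix, determinant forced to +1), applies it to the
#' left-hemisphere centroids and the x-mirrored rotation to the right,
#' and reassigns every parcel the value of the nearest original
#' centroid in the same hemisphere (Euclidean metric; duplicate
#' assignments permitted). Rotating both hemispheres with mirrored
#' rotations preserves the left/right correspondence; the
#' nearest-centroid reassignment preserves spatial autocorrelation,
#' which is what distinguishes this null from an IID shuffle.
#'
#' Permutation 0 is reserved as the identity and excluded from the null
#' count.
#'
#' @param geometry A `parcel_geometry` with mirrored hemispheres.
#' @param n_perm Number of random rotations (default 10000).
#' @param seed Integer seed.
#' @return An object of class `spin_null`: an `(n_perm + 1) x n_parcels`
#'   integer matrix of source-parcel indices (row 1 = identity), plus
#'   `n_perm` and the hemisphere layout.
#' @export
generate_spin_permutations <- function(geometry, n_perm = 10000L,
                                       seed = 1L) {
  assert_parcel_geometry(geometry)
  cent <- geometry_matrix(geometry)
  hemi <- geometry$hemisphere
  idx_L <- which(hemi == "L")
  idx_R <- which(hemi == "R")
  cl <- cent[idx_L, , drop = FALSE]
  cr <- cent[idx_R, , drop = FALSE]
  mirror <- diag(c(-1, 1, 1))

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  perms <- matrix(NA_integer_, n_perm + 1L, nrow(cent))
  perms[1L, ] <- seq_len(nrow(cent))
  for (i in seq_len(n_perm)) {
    R <- random_rotation()
    Rm <- mirror %*% R %*% mirror
    rot_L <- cl %*% t(R)
    rot_R <- cr %*% t(Rm)
    # parcel j takes the value of the original parcel nearest to its
    # rotated position (same hemisphere)
    perms[i + 1L, idx_L] <- idx_L[nearest_index(rot_L, cl)]
    perms[i + 1L, idx_R] <- idx_R[nearest_index(rot_R, cr)]
  }
  structure(list(perms = perms, n_perm = n_perm, hemisphere = hemi,
                 parcel_id = geometry$parcel_id, seed = seed),
            class = "spin_null")
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

nearest_index <- function(points, reference) {
  # argmin Euclidean distance; on the unit sphere this is argmax dot product
  apply(points %*% t(reference), 1, which.max)
}

#' Spin-permutation correlation test between two parcel maps
#'
#' The observed statistic is the correlation between the two maps; the
#' null distribution is the correlation between spun versions of
#' `map_a` and the unrotated `map_b`. The test is two-sided on the
#' absolute correlation: `p = (1 + #(|null| >= |observed|)) /
#' (n_perm + 1)`, so p is always positive and valid under the null.
#'
#' @param map_a,map_b Parcel-wise numeric vectors in geometry order.
#' @param null A [generate_spin_permutations()] object.
#' @param corr_type `"spearman"` (default) or `"pearson"`.
#' @param name_a,name_b Optional map labels for the output.
#' @return A one-row tibble of class `map_comparison`: `map_a`,
#'   `map_b`, `corr_type`, `observed`, `p_raw`, with the null
#'   distribution in attribute `"null"`.
#' @export
spin_correlation_test <- function(map_a, map_b, null,
                                  corr_type = c("spearman", "pearson"),
                                  name_a = "map_a", name_b = "map_b") {
  corr_type <- match.arg(corr_type)
  stopifnot(inherits(null, "spin_null"))
  p_parc <- ncol(null$perms)
  if (length(map_a) != p_parc || length(map_b) != p_parc) {
    stop("Maps must match the geometry length (", p_parc, ").",
         call. = FALSE)
  }
  if (anyNA(map_a) || anyNA(map_b)) {
    stop("Maps contain undefined values.", call. = FALSE)
  }
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("Constant map: correlation undefined.", call. = FALSE)
  }
  observed <- stats::cor(map_a, map_b, method = corr_type)
  spun <- matrix(map_a[t(null$perms[-1L, , drop = FALSE])], nrow = p_parc)
  if (corr_type == "spearman") {
    # duplicate reassignments break rank invariance: re-rank each spun map
    spun <- apply(spun, 2, rank)
    rb <- rank(map_b)
  } else {
    rb <- map_b
  }
  nulls <- as.numeric(stats::cor(spun, rb))
  p_raw <- (1 + sum(abs(nulls) >= abs(observed))) / (null$n_perm + 1)
  out <- tibble::tibble(map_a = name_a, map_b = name_b,
                        corr_type = corr_type,
                        observed = observed, p_raw = p_raw)
  attr(out, "null") <- nulls
  class(out) <- c("map_comparison", class(out))
  out
}

#' Compare a loading map against an annotation battery
#'
#' One spin test (Spearman) per annotation map, Bonferroni-corrected
#' over the battery size; an association is significant when its
#' corrected p falls below `alpha`. Output is sorted by the magnitude
#' of the observed correlation.
#'
#' @param loading_map Parcel-wise loading vector.
#' @param annotations Named list of parcel-wise vectors, or a data
#'   frame with a `parcel_id` column plus one column per annotation.
#' @param null A [generate_spin_permutations()] object.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `map`, `observed`, `p_raw`, `p_corrected`,
#'   `significant`, sorted by `|observed|` descending.
#' @export
characterize_against_annotations <- function(loading_map, annotations,
                                             null, alpha = 0.05) {
  if (is.data.frame(annotations)) {
    annotations <- as.list(annotations[setdiff(names(annotations),
                                               "parcel_id")])
  }
  if (anyDuplicated(names(annotations))) {
    stop("Duplicate annotation names.", call. = FALSE)
  }
  m <- length(annotations)
  rows <- purrr::imap(annotations, function(ann, nm) {
    tst <- spin_correlation_test(loading_map, ann, null,
                                 corr_type = "spearman",
                                 name_a = "loadings", name_b = nm)
    tibble::tibble(map = nm, observed = tst$observed, p_raw = tst$p_raw)
  })
  out <- dplyr::bind_rows(rows)
  out$p_corrected <- pmin(1, m * out$p_raw)
  out$significant <- out$p_corrected < alpha
  dplyr::arrange(out, dplyr::desc(abs(.data$observed)))
}

#' Compare loading profiles between two models
#'
#' Risk-factor profiles are compared with a plain Pearson correlation
#' and its analytic p-value (Bonferroni-corrected over the declared
#' number of cross-model comparisons); brain profiles are parcel maps
#' and are delegated to the spin test.
#'
#' @param loadings_a,loadings_b Loading vectors with matched variable
#'   order.
#' @param side `"risk_factor"` or `"brain"`.
#' @param null Spin null, required for `side = "brain"`.
#' @param n_comparisons Bonferroni family size (default 1).
#' @return A one-row tibble: `side`, `observed`, `p_raw`, `p_corrected`.
#' @export
compare_loading_profiles <- function(loadings_a, loadings_b,
                                     side = c("risk_factor", "brain"),
                                     null = NULL, n_comparisons = 1L) {
  side <- match.arg(side)
  if (length(loadings_a) != length(loadings_b)) {
    stop("Loading profiles differ in length.", call. = FALSE)
  }
  if (side == "brain") {
    if (is.null(null)) stop("Brain-side comparison needs a spin null.",
                            call. = FALSE)
    tst <- spin_correlation_test(loadings_a, loadings_b, null,
                                 corr_type = "pearson")
    return(tibble::tibble(side = side, observed = tst$observed,
                          p_raw = tst$p_raw,
                          p_corrected = pmin(1, n_comparisons * tst$p_raw)))
  }
  ct <- stats::cor.test(loadings_a, loadings_b, method = "pearson")
  tibble::tibble(side = side, observed = unname(ct$estimate),
                 p_raw = ct$p.value,
                 p_corrected = pmin(1, n_comparisons * ct$p.value))
}
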