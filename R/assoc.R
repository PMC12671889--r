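#' Subject-wise latent scores averaged across outer-split models
#'
#' Projects every subject through each outer split's fitted model
#' (with that split's training-estimated preprocessing when transforms
#' are supplied), sign-aligns the splits with the flips derived during
#' loading aggregation, and averages. By default all subjects are
#' scored under every model; holdout-only scoring is available for
#' leakage-sensitive uses via `holdout_only` together with the scheme.
#'
#' @param models List of fitted `rcca` models, one per outer split.
#' @param X,Y Full-cohort data (all subjects).
#' @param flips Per-split sign vector (element `flips` of
#'   [aggregate_loadings()], or stored in a `latent_dims` dimension).
#' @param transforms Optional list of per-split preprocessing
#'   transforms (as produced inside [run_sequential_dimensions()]); when
#'   `NULL`, `X` and `Y` are assumed already preprocessed.
#' @param confounds Confound table, required when `transforms` includes
#'   confound regression.
#' @param subject_id Optional subject identifiers for the output.
#' @return A tibble of class `subject_scores`: `subject_id`,
#'   `x_score`, `y_score`, `n_models`.
#' @export
compute_subject_scores <- function(models, X, Y, flips,
                                   transforms = NULL, confounds = NULL,
                                   subject_id = NULL) {
  S <- length(models)
  if (S == 0) stop("No models supplied.", call. = FALSE)
  if (any(vapply(models, is.null, TRUE))) {
    stop("Missing model for at least one split.", call. = FALSE)
  }
  if (length(flips) != S) stop("One sign flip per model required.",
                               call. = FALSE)
  Xm <- as_numeric_matrix(X)
  Ym <- as_numeric_matrix(Y)

  acc_x <- 0; acc_y <- 0
  for (s in seq_len(S)) {
    if (!is.null(transforms)) {
      pp <- preprocess_apply(transforms[[s]], Xm, Ym, confounds)
      sc <- rcca_project(models[[s]], pp$X, pp$Y)
    } else {
      sc <- rcca_project(models[[s]], Xm, Ym)
    }
    acc_x <- acc_x + flips[s] * sc$x[, 1]
    acc_y <- acc_y + flips[s] * sc$y[, 1]
  }
  ids <- if (!is.null(subject_id)) subject_id
         else if (is.data.frame(X) && "subject_id" %in% names(X)) X$subject_id
         else sprintf("S%05d", seq_len(nrow(Xm)))
  out <- tibble::tibble(subject_id = ids,
                        x_score = acc_x / S, y_score = acc_y / S,
                        n_models = S)
  class(out) <- c("subject_scores", class(out))
  out
}

#' Subject scores for one extracted dimension of a fitted pipeline
#'
#' For each outer split: apply that split's training-estimated
#' preprocessing to the full cohort, deflate through all earlier
#' dimensions with the split's models and optimization-estimated
#' slopes, project through the split's model for the requested
#' dimension, sign-align, and average. With `holdout_only = TRUE` each
#' subject is averaged only over the splits that held it out (subjects
#' never held out get `NA`).
#'
#' @param fit A `latent_dims` object from [run_sequential_dimensions()].
#' @param X,Y Full-cohort data in the original (pre-preprocessing)
#'   space.
#' @param confounds Confound table matching what the fit used.
#' @param dimension Which extracted dimension to score.
#' @param holdout_only Restrict each split's contribution to its
#'   holdout subjects.
#' @return A `subject_scores` tibble (see [compute_subject_scores()]).
#' @export
subject_scores_for_dimension <- function(fit, X, Y, confounds = NULL,
                                         dimension = 1L,
                                         holdout_only = FALSE) {
  stopifnot(inherits(fit, "latent_dims"))
  dm <- fit$dimensions[[dimension]]
  if (is.null(dm)) stop("Dimension not present in fit.", call. = FALSE)
  Xm <- as_numeric_matrix(X)
  Ym <- as_numeric_matrix(Y)
  confounds <- if (!is.null(confounds)) drop_subject_id(confounds)
  S <- length(dm$models)
  n <- nrow(Xm)
  acc_x <- acc_y <- numeric(n)
  wt <- numeric(n)
  for (s in seq_len(S)) {
    pp <- preprocess_apply(fit$split_transforms[[s]], Xm, Ym, confounds)
    for (e in seq_len(dimension - 1L)) {
      sc_e <- rcca_project(fit$dimensions[[e]]$models[[s]], pp$X, pp$Y)
      defl <- rcca_deflate(pp$X, pp$Y, sc_e, 1L,
                           slopes = fit$dimensions[[e]]$slopes[[s]])
      pp <- list(X = defl$X, Y = defl$Y)
    }
    sc <- rcca_project(dm$models[[s]], pp$X, pp$Y)
    w <- if (holdout_only) {
      as.numeric(seq_len(n) %in% fit$scheme$outer[[s]]$holdout)
    } else rep(1, n)
    acc_x <- acc_x + w * dm$flips[s] * sc$x[, 1]
    acc_y <- acc_y + w * dm$flips[s] * sc$y[, 1]
    wt <- wt + w
  }
  ids <- if (is.data.frame(X) && "subject_id" %in% names(X)) X$subject_id
         else sprintf("S%05d", seq_len(n))
  out <- tibble::tibble(subject_id = ids,
                        x_score = ifelse(wt > 0, acc_x / wt, NA_real_),
                        y_score = ifelse(wt > 0, acc_y / wt, NA_real_),
                        n_models = wt)
  class(out) <- c("subject_scores", class(out))
  out
}

#' Spearman association of latent scores with an external variable
#'
#' Rank-based (hence invariant under strictly monotone transforms of
#' either input) association of subject-wise latent scores with an
#' external marker such as C-reactive protein. Ties are handled by
#' midranks; the p-value is the analytic large-sample approximation,
#' Bonferroni-corrected over the declared battery size.
#'
#' @param scores Numeric vector of subject scores (or a
#'   `subject_scores` tibble, in which case `column` picks the side).
#' @param external Numeric vector, same subjects.
#' @param n_comparisons Bonferroni family size (default 1); the family
#'   size is a reporting choice and is echoed in the output.
#' @param column Which score column when `scores` is a tibble
#'   (default `"y_score"`, the risk-factor side).
#' @return A one-row tibble: `rho`, `p_raw`, `p_corrected`,
#'   `n`, `n_comparisons`.
#' @export
spearman_association <- function(scores, external, n_comparisons = 1L,
                                 column = "y_score") {
  if (is.data.frame(scores)) scores <- scores[[column]]
  if (length(scores) != length(external)) {
    stop("`scores` and `external` must have equal length.", call. = FALSE)
  }
  if (length(scores) < 10) stop("Need at least 10 pairs.", call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(external) == 0) {
    stop("Constant vector: Spearman correlation undefined.", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(scores, external, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_raw = ct$p.value,
                 p_corrected = min(1, n_comparisons * ct$p.value),
                 n = length(scores), n_comparisons = n_comparisons)
}

#' Risk-factor intercorrelation matrix
#'
#' Symmetric Pearson correlation matrix of the risk-factor table, the
#' standard first look at the collinearity structure (e.g., the
#' body-composition and air-pollution blocks). Zero-variance columns
#' yield `NA` rows/columns with a warning.
#'
#' @param Y Risk-factor data (matrix or data frame; a `subject_id`
#'   column is dropped).
#' @return A q x q correlation matrix with unit diagonal.
#' @export
risk_factor_correlation_matrix <- function(Y) {
  Y <- as_numeric_matrix(Y)
  if (anyNA(Y)) stop("Missing values are not supported.", call. = FALSE)
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0)) {
    warning("Zero-variance column(s) flagged as NA: ",
            paste(colnames(Y)[sds == 0], collapse = ", "), call. = FALSE)
  }
  suppressWarnings(stats::cor(Y))
}

#' Waist-to-hip ratio column transform
#'
#' Adds the derived ratio of waist to hip circumference, the standard
#' anthropometric index used alongside the raw circumferences.
#'
#' @param data A data frame.
#' @param waist,hip Column names (strings).
#' @param name Name of the derived column.
#' @return The data frame with the added column.
#' @export
add_waist_hip_ratio <- function(data, waist = "waist_circumference",
                                hip = "hip_circumference",
                                name = "waist_to_hip_ratio") {
  if (!all(c(waist, hip) %in% names(data))) {
    stop("Columns `", waist, "` and `", hip, "` are required.",
         call. = FALSE)
  }
  data[[name]] <- data[[waist]] / data[[hip]]
  data
}
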