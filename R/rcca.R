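#' Fit a regularized canonical correlation analysis
#'
#' Finds paired linear combinations of two standardized data views —
#' brain weights `u` on X and risk-factor weights `v` on Y — that
#' maximize the correlation of the projected scores `Xu` and `Yv`.
#' Regularization shrinks each within-view covariance toward the
#' identity, `(1 - c) * C + c * I`, which adds an L2-type constraint on
#' the weights and curbs overfitting in high-dimensional views: `c = 0`
#' is classical CCA, `c = 1` the partial-least-squares limit where only
#' the cross-covariance matters.
#'
#' The solution is computed in the primal: whitening transforms
#' `W = ((1 - c) C + c I)^(-1/2)` are formed by symmetric
#' eigendecomposition (eigenvalue floor 1e-12) and the singular value
#' decomposition of `W_x C_xy W_y` gives the weights
#' `u = W_x a`, `v = W_y b`. Weight columns are normalized in the
#' regularized metric, `u' ((1-c) C_xx + c I) u = 1`, and ordered by
#' nonincreasing training canonical correlation. The sign of each
#' weight pair is indeterminate; downstream aggregation handles
#' alignment explicitly.
#'
#' @param X,Y Numeric matrices or data frames (equal row counts);
#'   columns are expected to be standardized.
#' @param c_x,c_y Regularization levels in `[0, 1]` (`c_y` defaults to
#'   `c_x`).
#' @param K Number of component pairs to retain (`K <= min(p, q)`).
#' @return An object of class `rcca` with elements `u` (p x K), `v`
#'   (q x K), `c_x`, `c_y`, `K`, `cancor` (training canonical
#'   correlations), `n`, and the training column names.
#' @export
#' @examples
#' X <- matrix(rnorm(300), 100, 3); Y <- X + matrix(rnorm(300), 100, 3)
#' fit <- rcca_fit(scale(X), scale(Y), c_x = 0.1)
#' fit$cancor[1]
rcca_fit <- function(X, Y, c_x, c_y = c_x, K = 1L) {
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  check_rcca_inputs(X, Y, c_x, c_y, K)
  n <- nrow(X)
  Cxx <- stats::cov(X)
  Cyy <- stats::cov(Y)
  Cxy <- stats::cov(X, Y)
  fit <- rcca_from_cov(Cxx, Cyy, Cxy, c_x, c_y, K)
  sc <- list(x = X %*% fit$u, y = Y %*% fit$v)
  fit$cancor <- vapply(seq_len(K),
                       function(k) stats::cor(sc$x[, k], sc$y[, k]),
                       1.0)
  fit$n <- n
  fit$x_names <- colnames(X)
  fit$y_names <- colnames(Y)
  class(fit) <- "rcca"
  fit
}

check_rcca_inputs <- function(X, Y, c_x, c_y, K) {
  if (nrow(X) != nrow(Y)) stop("X and Y must share rows.", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("Non-finite values in input.", call. = FALSE)
  }
  for (c_ in c(c_x, c_y)) {
    if (c_ < 0 || c_ > 1) {
      stop("Regularization levels must lie in [0, 1].", call. = FALSE)
    }
  }
  if (K < 1 || K > min(ncol(X), ncol(Y))) {
    stop("`K` must lie in 1..min(p, q).", call. = FALSE)
  }
}

# solver on precomputed covariances; shared by the fast permutation and
# grid-selection paths (row-shuffling Y leaves Cxx and Cyy untouched)
rcca_from_cov <- function(Cxx, Cyy, Cxy, c_x, c_y, K) {
  Wx <- inv_sqrt_reg(Cxx, c_x)
  Wy <- inv_sqrt_reg(Cyy, c_y)
  M <- Wx %*% Cxy %*% Wy
  sv <- svd(M, nu = K, nv = K)
  list(u = Wx %*% sv$u, v = Wy %*% sv$v,
       d = sv$d[seq_len(K)], c_x = c_x, c_y = c_y, K = K,
       Wx = Wx, Wy = Wy)
}

inv_sqrt_reg <- function(C, c_, floor = 1e-12) {
  R <- (1 - c_) * C
  diag(R) <- diag(R) + c_
  ev <- eigen(R, symmetric = TRUE)
  lam <- pmax(ev$values, floor)
  ev$vectors %*% (t(ev$vectors) / sqrt(lam))
}

#' Project data through a fitted RCCA model
#'
#' Computes subject-wise scores `Xu` and `Yv` with the training
#' weights; nothing is refitted, so the projection is valid for test
#' and holdout rows.
#'
#' @param model A fitted [rcca_fit()] object.
#' @param X,Y Matrices/data frames whose columns match the training
#'   columns in name and order.
#' @return A list of class `rcca_scores` with `x` and `y` score
#'   matrices (n x K).
#' @export
rcca_project <- function(model, X, Y) {
  stopifnot(inherits(model, "rcca"))
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  bad_x <- !identical(colnames(X), model$x_names)
  bad_y <- !identical(colnames(Y), model$y_names)
  if (bad_x || bad_y) {
    off <- c(if (bad_x) setdiff(colnames(X), model$x_names),
             if (bad_y) setdiff(colnames(Y), model$y_names))
    stop("Column mismatch with the trained model: ",
         paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(x = X %*% model$u, y = Y %*% model$v),
            class = "rcca_scores")
}

#' Canonical correlation of a score pair
#'
#' @param scores An `rcca_scores` object (see [rcca_project()]).
#' @param k Component index.
#' @return Pearson correlation of `x` and `y` scores for component `k`.
#' @export
canonical_correlation <- function(scores, k = 1L) {
  sx <- scores$x[, k]
  sy <- scores$y[, k]
  if (length(sx) < 3) stop("Need at least 3 rows.", call. = FALSE)
  if (stats::sd(sx) == 0 || stats::sd(sy) == 0) {
    stop("Constant score vector: canonical correlation undefined.",
         call. = FALSE)
  }
  stats::cor(sx, sy)
}

#' Loadings: correlations of original variables with a score
#'
#' Loadings are the interpretation device of the analysis: the Pearson
#' correlation of each original variable with the same-side score
#' vector. Zero-variance columns get an `NA` loading with a warning.
#'
#' @param data Original (same-side) data matrix/data frame.
#' @param score A single score vector for the same rows.
#' @return A named numeric vector of loadings in `[-1, 1]`.
#' @export
compute_loadings <- function(data, score) {
  data <- as_numeric_matrix(data)
  if (nrow(data) != length(score)) stop("Row mismatch.", call. = FALSE)
  sds <- apply(data, 2, stats::sd)
  out <- rep(NA_real_, ncol(data))
  names(out) <- colnames(data)
  ok <- sds > 0
  if (any(!ok)) {
    warning("Zero-variance column(s), loading undefined: ",
            paste(colnames(data)[!ok], collapse = ", "), call. = FALSE)
  }
  out[ok] <- as.numeric(stats::cor(data[, ok, drop = FALSE], score))
  out
}

#' Projection deflation: remove a latent dimension's variance
#'
#' Residualizes every column of X on the component's x-score and every
#' column of Y on the y-score, so the next dimension is sought in data
#' orthogonal to the removed scores. For out-of-sample rows, pass the
#' regression `slopes` estimated on the training partition (returned by
#' this function) together with the out-of-sample scores.
#'
#' @param X,Y Data matrices.
#' @param scores `rcca_scores` computed from the same rows.
#' @param k Component index to remove.
#' @param slopes Optional training-estimated slopes (element `slopes` of
#'   a previous call) to apply instead of re-estimating.
#' @return List with deflated `X`, `Y` and the `slopes` used.
#' @export
rcca_deflate <- function(X, Y, scores, k = 1L, slopes = NULL) {
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  sx <- scores$x[, k]
  sy <- scores$y[, k]
  if (length(sx) != nrow(X)) stop("Scores/rows mismatch.", call. = FALSE)
  nx2 <- sum(sx^2); ny2 <- sum(sy^2)
  if (nx2 == 0 || ny2 == 0) {
    stop("Zero-norm score: cannot deflate.", call. = FALSE)
  }
  if (is.null(slopes)) {
    slopes <- list(x = crossprod(sx, X) / nx2,
                   y = crossprod(sy, Y) / ny2)
  }
  list(X = X - outer(sx, as.numeric(slopes$x)),
       Y = Y - outer(sy, as.numeric(slopes$y)),
       slopes = slopes)
}

#' Serialize / restore a fitted RCCA model as structured text
#'
#' Writes the regularization levels, weights, training canonical
#' correlations and column names to a single JSON file, so a model
#' fitted once can be reused by the evaluation and permutation stages
#' or projected onto new data later.
#'
#' @param model A fitted `rcca`.
#' @param path File path.
#' @return `write_rcca()` returns `path` invisibly; `read_rcca()` the
#'   restored `rcca` object.
#' @export
write_rcca <- function(model, path) {
  stopifnot(inherits(model, "rcca"))
  payload <- list(c_x = model$c_x, c_y = model$c_y, K = model$K,
                  n = model$n, cancor = model$cancor,
                  x_names = model$x_names, y_names = model$y_names,
                  u = asplit(model$u, 2), v = asplit(model$v, 2))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rcca
#' @export
read_rcca <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # columns were written as a list of vectors; simplification may give a
  # K x p matrix (one row per column) or keep the list
  as_cols <- function(x, K) {
    if (is.matrix(x)) t(x) else matrix(unlist(x), ncol = K)
  }
  out <- list(u = as_cols(p$u, p$K),
              v = as_cols(p$v, p$K),
              d = NULL, c_x = p$c_x, c_y = p$c_y, K = p$K,
              cancor = p$cancor, n = p$n,
              x_names = p$x_names, y_names = p$y_names)
  class(out) <- "rcca"
  out
}

#' @export
print.rcca <- function(x, ...) {
  cat("<rcca> K = ", x$K, ", c_x = ", format(x$c_x), ", c_y = ",
      format(x$c_y), ", n = ", x$n, "\n", sep = "")
  cat("training canonical correlations: ",
      paste(format(x$cancor, digits = 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}
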