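#' Stability of weight vectors across splits
#'
#' Mean over all unordered pairs of the absolute Pearson correlation
#' between weight vectors estimated on different splits. The absolute
#' value absorbs the sign indeterminacy of the CCA solution, so a
#' vector and its negation count as perfectly stable.
#'
#' @param weights A list of equal-length numeric vectors (or a matrix
#'   with one vector per column), at least two.
#' @return A value in `[0, 1]`.
#' @export
weight_stability <- function(weights) {
  if (is.matrix(weights)) weights <- asplit(weights, 2)
  if (length(weights) < 2) stop("Need at least two vectors.", call. = FALSE)
  lens <- lengths(weights)
  if (length(unique(lens)) != 1) stop("Unequal vector lengths.", call. = FALSE)
  if (any(vapply(weights, stats::sd, 1.0) == 0)) {
    stop("Constant weight vector: stability undefined.", call. = FALSE)
  }
  W <- do.call(cbind, lapply(weights, as.numeric))
  cm <- abs(stats::cor(W))
  mean(cm[upper.tri(cm)])
}

#' Hyperparameter selection by test correlation and weight stability
#'
#' For every candidate regularization level: fit the RCCA on each inner
#' training set (preprocessing — confound residualization when
#' `confounds` is supplied, then standardization — is fitted on the
#' inner training rows only and applied to the inner test rows), record
#' the first test canonical correlation, and compute the cross-split
#' stability of the weights (mean of the u-side and v-side
#' [weight_stability()]). Candidates are ranked by mean test
#' correlation (descending) and by stability (descending); the minimal
#' rank sum wins, with ties going to the larger regularization level.
#'
#' @param X,Y Optimization-set data (matrices/data frames).
#' @param inner_splits List of `(train, test)` index pairs into the rows
#'   of `X`/`Y` (element `inner` of a [make_splits()] outer split).
#' @param grid Numeric vector of candidate regularization levels
#'   (shared `c_x = c_y`), or a two-column matrix of `(c_x, c_y)` pairs.
#' @param confounds Optional confound table for the same rows; when
#'   given, confound regression is fitted within each inner training
#'   set.
#' @param K Number of components fitted (selection uses the first).
#' @return A list of class `selection_result`: `chosen` (named vector
#'   `c_x`, `c_y`) and `table`, a tibble with one row per candidate
#'   (mean test correlation, stability, ranks, `chosen` flag).
#' @export
select_hyperparameters <- function(X, Y, inner_splits, grid,
                                   confounds = NULL, K = 1L) {
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  grid <- as_grid(grid)
  if (nrow(grid) == 0) stop("Empty candidate grid.", call. = FALSE)
  confounds <- if (!is.null(confounds)) as.data.frame(confounds)

  # preprocessing and covariances per inner split are candidate-invariant
  prepped <- lapply(inner_splits, function(sp) {
    cf_tr <- if (!is.null(confounds)) confounds[sp$train, , drop = FALSE]
    pf <- preprocess_fit(X[sp$train, , drop = FALSE],
                         Y[sp$train, , drop = FALSE], cf_tr)
    cf_te <- if (!is.null(confounds)) confounds[sp$test, , drop = FALSE]
    te <- preprocess_apply(pf$transforms, X[sp$test, , drop = FALSE],
                           Y[sp$test, , drop = FALSE], cf_te)
    list(Cxx = stats::cov(pf$X), Cyy = stats::cov(pf$Y),
         Cxy = stats::cov(pf$X, pf$Y), X_test = te$X, Y_test = te$Y)
  })

  eval_candidate <- function(c_x, c_y) {
    fits <- lapply(prepped, function(pr) {
      tryCatch({
        f <- rcca_from_cov(pr$Cxx, pr$Cyy, pr$Cxy, c_x, c_y, K)
        r <- stats::cor(pr$X_test %*% f$u[, 1], pr$Y_test %*% f$v[, 1])
        list(r = r, u = f$u[, 1], v = f$v[, 1])
      }, error = function(e) NULL)
    })
    fits <- fits[!vapply(fits, is.null, TRUE)]
    if (length(fits) < 2) return(NULL)
    stab <- mean(c(weight_stability(lapply(fits, `[[`, "u")),
                   weight_stability(lapply(fits, `[[`, "v"))))
    tibble::tibble(c_x = c_x, c_y = c_y,
                   mean_test_cor = mean(vapply(fits, `[[`, 1.0, "r")),
                   stability = stab)
  }

  rows <- purrr::pmap(list(grid$c_x, grid$c_y), eval_candidate)
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) {
    stop("All candidates failed to fit on the inner splits.", call. = FALSE)
  }
  tab$rank_cor <- rank(-tab$mean_test_cor, ties.method = "min")
  tab$rank_stability <- rank(-tab$stability, ties.method = "min")
  tab$rank_sum <- tab$rank_cor + tab$rank_stability
  best <- which(tab$rank_sum == min(tab$rank_sum))
  # ties broken toward the more regularized candidate
  best <- best[order(tab$c_x[best] + tab$c_y[best], decreasing = TRUE)][1]
  tab$chosen <- seq_len(nrow(tab)) == best
  structure(list(chosen = c(c_x = tab$c_x[best], c_y = tab$c_y[best]),
                 table = tab),
            class = "selection_result")
}

as_grid <- function(grid) {
  if (is.numeric(grid) && is.null(dim(grid))) {
    tibble::tibble(c_x = as.numeric(grid), c_y = as.numeric(grid))
  } else {
    g <- as.data.frame(grid)
    names(g) <- c("c_x", "c_y")
    tibble::as_tibble(g)
  }
}

#' Default regularization grid
#'
#' @return Candidate shared regularization levels spanning classical
#'   CCA (near 0) to the PLS limit (near 1).
#' @export
default_grid <- function() c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 0.99, 1 - 1e-4)

#' Permutation evaluation of one outer split
#'
#' Refits the RCCA on the (preprocessed) optimization set with fixed
#' hyperparameters, projects the holdout set, and takes the first
#' holdout canonical correlation as the observed statistic. Under the
#' null, the rows of Y are shuffled independently within the
#' optimization and holdout sets; the model is refit on the permuted
#' optimization set with the same hyperparameters and the permuted
#' holdout is projected, giving one null correlation per iteration.
#' Because a row shuffle of Y leaves the within-view covariances
#' untouched, the whitening transforms are precomputed and only the
#' cross-covariance is recomputed per iteration — algebraically
#' identical to a full refit. A refit failure inside an iteration is
#' recorded conservatively as a null value at least as large as the
#' observed one.
#'
#' The p-value is one-sided on the signed correlation:
#' `p = (1 + #(null >= observed)) / n_perm`, then Bonferroni-corrected
#' over the `n_splits` outer splits, `min(1, n_splits * p)`.
#'
#' @param X_opt,Y_opt,X_hold,Y_hold Preprocessed optimization and
#'   holdout partitions.
#' @param c_x,c_y Selected regularization levels.
#' @param n_perm Number of permutations (default 1000; fewer than 100
#'   draws triggers a warning).
#' @param n_splits Bonferroni family size (number of outer splits).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `dimension_evaluation`: `observed`, `p_raw`,
#'   `p_corrected`, `null` (the permutation distribution), `model`
#'   (the refit `rcca`), `scores_opt`, `scores_hold`.
#' @export
evaluate_dimension <- function(X_opt, Y_opt, X_hold, Y_hold,
                               c_x, c_y = c_x, n_perm = 1000L,
                               n_splits = 5L, seed = 1L) {
  if (n_perm < 100) {
    warning("Fewer than 100 permutations: p-values will be coarse.",
            call. = FALSE)
  }
  X_opt <- as_numeric_matrix(X_opt); Y_opt <- as_numeric_matrix(Y_opt)
  X_hold <- as_numeric_matrix(X_hold); Y_hold <- as_numeric_matrix(Y_hold)

  model <- rcca_fit(X_opt, Y_opt, c_x, c_y, K = 1L)
  sc_opt <- rcca_project(model, X_opt, Y_opt)
  sc_hold <- rcca_project(model, X_hold, Y_hold)
  observed <- canonical_correlation(sc_hold, 1L)

  n_o <- nrow(X_opt)
  Xc <- sweep(X_opt, 2, colMeans(X_opt))
  Yc <- sweep(Y_opt, 2, colMeans(Y_opt))
  Wx <- inv_sqrt_reg(stats::cov(X_opt), c_x)
  Wy <- inv_sqrt_reg(stats::cov(Y_opt), c_y)
  WxXc <- Xc %*% Wx   # so C_xy(perm) enters as crossprod(WxXc, Yc[perm,]) Wy

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  null <- vapply(seq_len(n_perm), function(i) {
    perm_o <- sample.int(n_o)
    perm_h <- sample.int(nrow(Y_hold))
    r <- tryCatch({
      M <- crossprod(WxXc, Yc[perm_o, , drop = FALSE] %*% Wy) / (n_o - 1)
      sv <- svd(M, nu = 1L, nv = 1L)
      u <- Wx %*% sv$u
      v <- Wy %*% sv$v
      stats::cor(X_hold %*% u, Y_hold[perm_h, , drop = FALSE] %*% v)[1, 1]
    }, error = function(e) NA_real_)
    if (is.na(r)) observed else r    # conservative on refit failure
  }, 1.0)

  p_raw <- (1 + sum(null >= observed)) / n_perm
  structure(list(observed = observed,
                 p_raw = min(1, p_raw),
                 p_corrected = min(1, n_splits * p_raw),
                 null = null, model = model,
                 scores_opt = sc_opt, scores_hold = sc_hold),
            class = "dimension_evaluation")
}

#' Aggregate loadings across outer splits with a stability mask
#'
#' Sign-aligns splits 2..S to split 1 (a split's sign is flipped when
#' the Pearson correlation of its risk-factor loading vector with split
#' 1's is negative; the same flip is applied to that split's brain
#' loadings), then reports the per-variable mean and standard deviation
#' across splits. A loading is flagged *stable* when its one-SD error
#' bar does not cross zero, i.e., `|mean| > SD`.
#'
#' @param loadings_x List of brain-side loading vectors, one per outer
#'   split (matched parcel order).
#' @param loadings_y List of risk-factor-side loading vectors (matched
#'   variable order).
#' @return A list: `loadings` — tibble with `variable`, `side`
#'   (`"brain"`/`"risk_factor"`), `mean`, `sd`, `stable` — and `flips`,
#'   the per-split sign used.
#' @export
aggregate_loadings <- function(loadings_x, loadings_y) {
  S <- length(loadings_y)
  stopifnot(length(loadings_x) == S, S >= 2)
  flips <- vapply(seq_len(S), function(s) {
    if (s == 1) return(1)
    a <- stats::cor(loadings_y[[s]], loadings_y[[1]])
    if (is.na(a) || abs(a) <= 0.1) {
      warning("Loading alignment correlation near zero for split ", s,
              ": dimension matching across splits may be unreliable.",
              call. = FALSE)
    }
    if (!is.na(a) && a < 0) -1 else 1
  }, 1.0)

  agg_side <- function(lst, side) {
    M <- do.call(cbind, Map(`*`, lst, flips))
    tibble::tibble(
      variable = if (!is.null(names(lst[[1]]))) names(lst[[1]]) else
        sprintf("%s_%03d", side, seq_len(nrow(M))),
      side = side,
      mean = unname(rowMeans(M)),
      sd = unname(apply(M, 1, stats::sd))
    )
  }
  out <- dplyr::bind_rows(agg_side(loadings_x, "brain"),
                          agg_side(loadings_y, "risk_factor"))
  out$stable <- abs(out$mean) - out$sd > 0
  list(loadings = out, flips = flips)
}
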