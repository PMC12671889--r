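#' Sequential extraction of significant latent dimensions
#'
#' Runs the full multiple-holdout analysis: per outer split, preprocess
#' (brain-size scaling, confound regression, standardization — all
#' fitted on the optimization rows and applied to the holdout rows),
#' select the regularization level on the inner splits, evaluate the
#' holdout canonical correlation against a Y-row-shuffle permutation
#' null with Bonferroni correction over the outer splits, and combine
#' the splits with the omnibus rule: the dimension is significant if at
#' least one split's corrected p falls below `alpha`. After a
#' significant dimension, its variance is removed from every split's
#' optimization and holdout partitions by projection deflation (holdout
#' rows use the optimization-estimated regression slopes) and the next
#' dimension is sought; the loop stops at the first non-significant
#' dimension or after `max_dimensions`.
#'
#' Loadings are computed on each split's optimization partition,
#' sign-aligned across splits, and averaged, with a one-SD stability
#' mask (see [aggregate_loadings()]).
#'
#' @param X,Y Subjects-by-variables data (data frames with an optional
#'   `subject_id` column, or matrices): brain parcels and risk factors.
#' @param confounds Optional confound table (same rows).
#' @param grid Candidate regularization levels (see
#'   [select_hyperparameters()]); defaults to [default_grid()].
#' @param n_outer,n_inner,holdout_frac,test_frac Split-scheme
#'   parameters (see [make_splits()]).
#' @param scaling Brain-size scaling mode for X: `"raw"`,
#'   `"proportional"` or `"corrected"`.
#' @param n_perm Permutations per split (default 1000).
#' @param alpha Significance level for the omnibus decision.
#' @param max_dimensions Upper bound on extracted dimensions.
#' @param stratify_by Optional stratification labels for the splits.
#' @param seed Integer master seed; every downstream random stream is
#'   derived from it.
#' @return An object of class `latent_dims`: a list with `dimensions`
#'   (one record per extracted dimension: per-split results tibble,
#'   omnibus verdict, aggregated loadings, fitted models),
#'   `n_significant`, the `scheme`, and the call parameters. Use
#'   [tidy.latent_dims()], [glance.latent_dims()] and
#'   [autoplot.latent_dims()] on it.
#' @export
run_sequential_dimensions <- function(X, Y, confounds = NULL,
                                      grid = default_grid(),
                                      n_outer = 5L, n_inner = 5L,
                                      holdout_frac = 0.2, test_frac = 0.2,
                                      scaling = "raw",
                                      n_perm = 1000L, alpha = 0.05,
                                      max_dimensions = 3L,
                                      stratify_by = NULL, seed = 1L) {
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  confounds <- if (!is.null(confounds)) drop_subject_id(confounds)
  n <- nrow(X)
  scheme <- make_splits(n, n_outer, n_inner, holdout_frac, test_frac,
                        stratify_by = stratify_by, seed = seed)

  # per-split state in preprocessed space; deflation updates it in place
  states <- lapply(scheme$outer, function(sp) {
    cf_o <- if (!is.null(confounds)) confounds[sp$optimization, , drop = FALSE]
    cf_h <- if (!is.null(confounds)) confounds[sp$holdout, , drop = FALSE]
    X_o_raw <- X[sp$optimization, , drop = FALSE]
    Y_o_raw <- Y[sp$optimization, , drop = FALSE]
    pf <- preprocess_fit(X_o_raw, Y_o_raw, cf_o, scaling = scaling)
    ph <- preprocess_apply(pf$transforms, X[sp$holdout, , drop = FALSE],
                           Y[sp$holdout, , drop = FALSE], cf_h)
    list(Xo = pf$X, Yo = pf$Y, Xh = ph$X, Yh = ph$Y,
         X_o_raw = X_o_raw, Y_o_raw = Y_o_raw, cf_o = cf_o,
         inner = sp$inner, transforms = pf$transforms)
  })

  dims <- list()
  for (d in seq_len(max_dimensions)) {
    split_rows <- list()
    models <- list()
    lx <- list(); ly <- list()
    scores_opt <- list(); scores_hold <- list()

    for (s in seq_len(n_outer)) {
      st <- states[[s]]
      sel <- if (d == 1L) {
        # dimension 1: full leakage-free preprocessing inside each inner
        # training split, from the raw optimization data
        select_hyperparameters(st$X_o_raw, st$Y_o_raw, st$inner, grid,
                               confounds = st$cf_o)
      } else {
        # later dimensions live in the outer-preprocessed deflated space;
        # inner-split preprocessing reduces to re-standardization
        select_hyperparameters(st$Xo, st$Yo, st$inner, grid)
      }
      ev <- evaluate_dimension(st$Xo, st$Yo, st$Xh, st$Yh,
                               c_x = sel$chosen[["c_x"]],
                               c_y = sel$chosen[["c_y"]],
                               n_perm = n_perm, n_splits = n_outer,
                               seed = seed + 811L * d + s)
      split_rows[[s]] <- tibble::tibble(
        dimension = d, split = s,
        c_x = sel$chosen[["c_x"]], c_y = sel$chosen[["c_y"]],
        holdout_r = ev$observed, p_raw = ev$p_raw,
        p_corrected = ev$p_corrected
      )
      models[[s]] <- ev$model
      scores_opt[[s]] <- ev$scores_opt
      scores_hold[[s]] <- ev$scores_hold
      lx[[s]] <- compute_loadings(st$Xo, ev$scores_opt$x[, 1])
      ly[[s]] <- compute_loadings(st$Yo, ev$scores_opt$y[, 1])
    }

    results <- dplyr::bind_rows(split_rows)
    omnibus <- any(results$p_corrected < alpha)
    agg <- aggregate_loadings(lx, ly)
    dims[[d]] <- list(dimension = d, results = results, omnibus = omnibus,
                      loadings = agg$loadings, flips = agg$flips,
                      models = models)

    if (!omnibus) break
    if (d == max_dimensions) break
    slopes_d <- list()
    for (s in seq_len(n_outer)) {
      defl_o <- rcca_deflate(states[[s]]$Xo, states[[s]]$Yo,
                             scores_opt[[s]], 1L)
      defl_h <- rcca_deflate(states[[s]]$Xh, states[[s]]$Yh,
                             scores_hold[[s]], 1L, slopes = defl_o$slopes)
      states[[s]]$Xo <- defl_o$X; states[[s]]$Yo <- defl_o$Y
      states[[s]]$Xh <- defl_h$X; states[[s]]$Yh <- defl_h$Y
      slopes_d[[s]] <- defl_o$slopes
    }
    dims[[d]]$slopes <- slopes_d
  }

  structure(list(dimensions = dims,
                 n_significant = sum(vapply(dims, `[[`, TRUE, "omnibus")),
                 scheme = scheme,
                 split_transforms = lapply(states, `[[`, "transforms"),
                 params = list(grid = grid, scaling = scaling,
                               n_perm = n_perm, alpha = alpha,
                               max_dimensions = max_dimensions,
                               seed = seed)),
            class = "latent_dims")
}

#' Diagnostic: was confound variance properly removed?
#'
#' Appends the numeric confound columns to the Y side conceptually by
#' computing, per outer split, the loading (correlation on that split's
#' optimization rows) of each numeric confound column against the
#' split's risk-factor score. When the confound regression worked,
#' these loadings are zero up to floating point, because each
#' residualized Y column — and hence any linear score — is exactly
#' orthogonal to the numeric confounds on the rows the regression was
#' fitted on.
#'
#' @param fit A `latent_dims` object.
#' @param X,Y,confounds The data the fit was run on.
#' @param dimension Which extracted dimension to check.
#' @return A tibble with `split`, `confound`, `loading`.
#' @export
check_confound_removal <- function(fit, X, Y, confounds, dimension = 1L) {
  stopifnot(inherits(fit, "latent_dims"))
  Xm <- as_numeric_matrix(X)
  Ym <- as_numeric_matrix(Y)
  conf <- drop_subject_id(confounds)
  num <- vapply(conf, is.numeric, TRUE)
  rows <- lapply(seq_len(fit$scheme$n_outer), function(s) {
    opt <- fit$scheme$outer[[s]]$optimization
    pp <- preprocess_apply(fit$split_transforms[[s]],
                           Xm[opt, , drop = FALSE], Ym[opt, , drop = FALSE],
                           conf[opt, , drop = FALSE])
    for (e in seq_len(dimension - 1L)) {
      sc_e <- rcca_project(fit$dimensions[[e]]$models[[s]], pp$X, pp$Y)
      defl <- rcca_deflate(pp$X, pp$Y, sc_e, 1L,
                           slopes = fit$dimensions[[e]]$slopes[[s]])
      pp <- list(X = defl$X, Y = defl$Y)
    }
    sc <- rcca_project(fit$dimensions[[dimension]]$models[[s]], pp$X, pp$Y)
    tibble::tibble(split = s, confound = names(conf)[num],
                   loading = vapply(which(num), function(j) {
                     stats::cor(conf[opt, j], sc$y[, 1])
                   }, 1.0))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.latent_dims <- function(x, ...) {
  cat("<latent_dims> ", length(x$dimensions), " dimension(s) evaluated, ",
      x$n_significant, " significant (omnibus, alpha = ",
      format(x$params$alpha), ")\n", sep = "")
  for (d in x$dimensions) {
    rng_r <- range(d$results$holdout_r)
    rng_p <- range(d$results$p_corrected)
    cat(sprintf("  dim %d: holdout r = %.3f-%.3f, corrected p = %.3g-%.3g%s\n",
                d$dimension, rng_r[1], rng_r[2], rng_p[1], rng_p[2],
                if (d$omnibus) "  *" else ""))
  }
  invisible(x)
}

drop_subject_id <- function(x) {
  x <- as.data.frame(x)
  x[setdiff(names(x), c("subject_id", "marker"))]
}
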