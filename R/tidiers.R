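#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sequential latent-dimension result
#'
#' @param x A `latent_dims` object from [run_sequential_dimensions()].
#' @param type `"results"` for the per-split evaluation table (one row
#'   per dimension and outer split: selected regularization, holdout
#'   canonical correlation, raw and Bonferroni-corrected permutation p,
#'   omnibus verdict) or `"loadings"` for the aggregated loading table
#'   (per variable: mean, SD, stability flag).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy latent_dims
#' @export
tidy.latent_dims <- function(x, type = c("results", "loadings"), ...) {
  type <- match.arg(type)
  if (type == "results") {
    out <- dplyr::bind_rows(lapply(x$dimensions, function(d) {
      dplyr::mutate(d$results, omnibus = d$omnibus)
    }))
  } else {
    out <- dplyr::bind_rows(lapply(x$dimensions, function(d) {
      dplyr::mutate(d$loadings, dimension = d$dimension, .before = 1)
    }))
  }
  tibble::as_tibble(out)
}

#' Summarize a sequential latent-dimension result
#'
#' @param x A `latent_dims` object.
#' @param ... Unused.
#' @return One-row tibble: dimensions evaluated, number significant,
#'   permutations per split, alpha, seed.
#' @method glance latent_dims
#' @export
glance.latent_dims <- function(x, ...) {
  tibble::tibble(n_dimensions = length(x$dimensions),
                 n_significant = x$n_significant,
                 n_outer = x$scheme$n_outer,
                 n_inner = x$scheme$n_inner,
                 n_perm = x$params$n_perm,
                 alpha = x$params$alpha,
                 seed = x$params$seed)
}

#' Tidy a fitted RCCA model
#'
#' @param x An `rcca` object.
#' @param ... Unused.
#' @return Tibble with `variable`, `side`, `component`, `weight`.
#' @method tidy rcca
#' @export
tidy.rcca <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(x$K), function(k) {
    dplyr::bind_rows(
      tibble::tibble(variable = x$x_names, side = "brain",
                     component = k, weight = x$u[, k]),
      tibble::tibble(variable = x$y_names, side = "risk_factor",
                     component = k, weight = x$v[, k])
    )
  }))
}

#' Summarize a fitted RCCA model
#'
#' @param x An `rcca` object.
#' @param ... Unused.
#' @return One-row tibble with dimensions, regularization and the first
#'   training canonical correlation.
#' @method glance rcca
#' @export
glance.rcca <- function(x, ...) {
  tibble::tibble(n = x$n, p = length(x$x_names), q = length(x$y_names),
                 K = x$K, c_x = x$c_x, c_y = x$c_y,
                 cancor_1 = x$cancor[1])
}

#' Loading profile plot for an extracted latent dimension
#'
#' Dot-and-error-bar display of the aggregated loadings (mean over the
#' outer splits, one-SD error bars), with the conventional shaded band
#' marking loadings between -0.2 and 0.2; unstable loadings (error bar
#' crossing zero) are greyed out.
#'
#' @param object A `latent_dims` object.
#' @param dimension Which extracted dimension to plot.
#' @param side `"risk_factor"` or `"brain"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot latent_dims
#' @export
autoplot.latent_dims <- function(object, dimension = 1L,
                                 side = c("risk_factor", "brain"), ...) {
  side <- match.arg(side)
  d <- object$dimensions[[dimension]]
  df <- dplyr::filter(d$loadings, .data$side == !!side)
  df <- dplyr::mutate(df,
                      variable = stats::reorder(.data$variable, .data$mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$variable)) +
    ggplot2::annotate("rect", xmin = -0.2, xmax = 0.2,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean - .data$sd,
                   xmax = .data$mean + .data$sd),
      height = 0, linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stable), size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#00688B",
                                            `FALSE` = "grey65")) +
    ggplot2::labs(x = "loading (mean over outer splits, ± 1 SD)",
                  y = NULL, colour = "stable",
                  title = sprintf("Latent dimension %d — %s loadings",
                                  dimension, gsub("_", " ", side)))
}

#' Annotation battery plot
#'
#' @param battery Tibble from [characterize_against_annotations()].
#' @return A ggplot bar chart of observed spin-test correlations,
#'   significant entries highlighted.
#' @export
plot_annotation_battery <- function(battery) {
  df <- dplyr::mutate(battery,
                      map = stats::reorder(.data$map, .data$observed))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$map,
                                   fill = .data$significant)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "spin-test correlation with loadings", y = NULL,
                  fill = "significant (Bonferroni)")
}

#' @importFrom rlang .data
NULL
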