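#' Read and validate a run configuration
#'
#' The configuration is a YAML key/value file covering input paths (or
#' a simulate block), preprocessing, split-scheme parameters, the
#' regularization grid, permutation counts, and the output directory.
#' Unknown keys are rejected before any computation starts, so typos
#' fail fast rather than silently falling back to defaults.
#'
#' Recognized keys: `paths` (`x`, `y`, `confounds`, `geometry`,
#' `annotations`), `simulate` (any [synth_config()] argument),
#' `scaling` (`raw`/`proportional`/`corrected`), `sample_mode`
#' (`mixed`/`women`/`men`; in sex-stratified modes sex is dropped from
#' the confound set and rows are filtered), `confound_columns`, `grid`,
#' `n_outer`, `n_inner`, `holdout_frac`, `test_frac`, `n_perm`,
#' `n_perm_spin`, `alpha`, `max_dimensions`, `marker_column`,
#' `marker_comparisons`, `seed`, `out_dir`.
#'
#' @param path YAML file path, or a named list with the same keys.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("paths", "simulate", "scaling", "sample_mode",
             "confound_columns", "grid", "n_outer", "n_inner",
             "holdout_frac", "test_frac", "n_perm", "n_perm_spin",
             "alpha", "max_dimensions", "marker_column",
             "marker_comparisons", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("Unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(scaling = "raw", sample_mode = "mixed",
                   confound_columns = c("age", "sex", "site"),
                   grid = default_grid(), n_outer = 5L, n_inner = 5L,
                   holdout_frac = 0.2, test_frac = 0.2, n_perm = 1000L,
                   n_perm_spin = 10000L, alpha = 0.05,
                   max_dimensions = 3L, marker_column = "marker",
                   marker_comparisons = 1L, seed = 1L, out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$paths) && is.null(cfg$simulate)) {
    stop("Config must provide input `paths` or a `simulate` block.",
         call. = FALSE)
  }
  if (!cfg$scaling %in% c("raw", "proportional", "corrected")) {
    stop("`scaling` must be raw, proportional or corrected.",
         call. = FALSE)
  }
  if (!cfg$sample_mode %in% c("mixed", "women", "men")) {
    stop("`sample_mode` must be mixed, women or men.", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("`alpha` must lie in (0, 1).", call. = FALSE)
  }
  if (cfg$max_dimensions < 0) stop("`max_dimensions` must be >= 0.",
                                   call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-load, preprocessing, sequential latent-dimension
#' extraction, spin-test characterization against an annotation battery
#' (when annotations are available), and the marker association, then
#' writes per-dimension result and loading tables (CSV), a JSON summary,
#' and a manifest with the configuration and every consumed seed so a
#' rerun with the same config is bit-identical.
#'
#' @param config A [read_run_config()] object, a path to one, or a
#'   named list of config keys.
#' @return A list of class `pipeline_result` with `fit` (the
#'   `latent_dims` object), `battery` (annotation comparisons per
#'   significant dimension, or `NULL`), `marker` (Spearman association
#'   tibble, or `NULL`), `subject_scores`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)

  ## ---- inputs ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- simulate_cohort(do.call(synth_config, sim_args))
  } else {
    cohort <- read_cohort_paths(config$paths)
  }

  keep <- rep(TRUE, nrow(cohort$X))
  confound_cols <- config$confound_columns
  if (config$sample_mode == "women") {
    keep <- cohort$confounds$sex == 0
    confound_cols <- setdiff(confound_cols, "sex")
  } else if (config$sample_mode == "men") {
    keep <- cohort$confounds$sex == 1
    confound_cols <- setdiff(confound_cols, "sex")
  }
  X <- cohort$X[keep, , drop = FALSE]
  Y <- cohort$Y[keep, , drop = FALSE]
  conf_all <- cohort$confounds[keep, , drop = FALSE]
  confounds <- conf_all[intersect(confound_cols, names(conf_all))]

  if (config$max_dimensions == 0L) {
    return(structure(list(fit = NULL, battery = NULL, marker = NULL,
                          subject_scores = NULL,
                          manifest = pipeline_manifest(config)),
                     class = "pipeline_result"))
  }

  ## ---- sequential latent dimensions ------------------------------------
  fit <- run_sequential_dimensions(
    X, Y, confounds = confounds, grid = config$grid,
    n_outer = config$n_outer, n_inner = config$n_inner,
    holdout_frac = config$holdout_frac, test_frac = config$test_frac,
    scaling = config$scaling, n_perm = config$n_perm,
    alpha = config$alpha, max_dimensions = config$max_dimensions,
    seed = config$seed
  )

  ## ---- spatial characterization ---------------------------------------
  battery <- NULL
  annotations <- pipeline_annotations(config, cohort)
  if (!is.null(annotations) && fit$n_significant > 0) {
    null <- generate_spin_permutations(cohort$geometry,
                                       n_perm = config$n_perm_spin,
                                       seed = config$seed + 7411L)
    battery <- dplyr::bind_rows(lapply(
      which(vapply(fit$dimensions, `[[`, TRUE, "omnibus")),
      function(d) {
        lmap <- dplyr::filter(fit$dimensions[[d]]$loadings,
                              .data$side == "brain")$mean
        dplyr::mutate(
          characterize_against_annotations(lmap, annotations, null,
                                           alpha = config$alpha),
          dimension = d, .before = 1)
      }))
  }

  ## ---- marker association ----------------------------------------------
  marker <- NULL
  scores <- NULL
  if (fit$n_significant > 0 &&
      config$marker_column %in% names(conf_all)) {
    sig <- which(vapply(fit$dimensions, `[[`, TRUE, "omnibus"))
    scores <- dplyr::bind_rows(lapply(sig, function(d) {
      dplyr::mutate(
        subject_scores_for_dimension(fit, X, Y, confounds, dimension = d),
        dimension = d, .before = 1)
    }))
    marker <- dplyr::bind_rows(lapply(sig, function(d) {
      sc <- dplyr::filter(scores, .data$dimension == d)
      dplyr::mutate(
        spearman_association(sc$y_score, conf_all[[config$marker_column]],
                             n_comparisons = config$marker_comparisons),
        dimension = d, .before = 1)
    }))
  }

  result <- structure(list(fit = fit, battery = battery, marker = marker,
                           subject_scores = scores,
                           manifest = pipeline_manifest(config)),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$marker)) {
    cat("marker association (Spearman):\n")
    print(as.data.frame(x$marker), digits = 3)
  }
  invisible(x)
}

read_cohort_paths <- function(paths) {
  rd <- function(f) tibble::as_tibble(utils::read.csv(f))
  geometry <- NULL
  if (!is.null(paths$geometry)) {
    geometry <- rd(paths$geometry)
    class(geometry) <- c("parcel_geometry", class(geometry))
  }
  confounds <- rd(paths$confounds)
  if ("site" %in% names(confounds)) confounds$site <- factor(confounds$site)
  structure(list(X = rd(paths$x), Y = rd(paths$y), confounds = confounds,
                 geometry = geometry, truth = NULL, config = NULL),
            class = "synth_cohort")
}

pipeline_annotations <- function(config, cohort) {
  if (!is.null(config$paths$annotations)) {
    ann <- utils::read.csv(config$paths$annotations)
    return(as.list(ann[setdiff(names(ann), "parcel_id")]))
  }
  NULL
}

pipeline_manifest <- function(config) {
  cfg_plain <- unclass(config)
  list(package_version = as.character(utils::packageVersion("holdoutcca")),
       r_version = as.character(getRversion()),
       config = cfg_plain,
       config_hash = config_hash(cfg_plain))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_result <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) {
    if (!is.null(x)) utils::write.csv(x, file.path(config$out_dir, f),
                                      row.names = FALSE)
  }
  if (!is.null(result$fit)) {
    wr(tidy(result$fit, "results"), "dimension_results.csv")
    wr(tidy(result$fit, "loadings"), "loadings.csv")
  }
  wr(result$battery, "annotation_battery.csv")
  wr(result$marker, "marker_association.csv")
  wr(result$subject_scores, "subject_scores.csv")
  summary_json <- list(
    n_significant = if (!is.null(result$fit)) result$fit$n_significant else 0L,
    manifest = result$manifest
  )
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(result)
}
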