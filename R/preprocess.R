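#' Fit a cross-validation-consistent confound residualizer
#'
#' Estimates, by ordinary least squares on training rows only, the
#' regression of every data column on the confound design (intercept +
#' numeric confounds + dummy-coded categorical confounds, first level
#' dropped). The fitted object is then applied to any partition with
#' [apply_residualizer()], so confound removal never leaks information
#' from test or holdout rows into the fit.
#'
#' @param data Numeric matrix or data frame of training rows (columns =
#'   variables to be residualized).
#' @param confounds Data frame of confound columns for the same rows;
#'   factors/characters are dummy-coded.
#' @return An object of class `residualizer`.
#' @export
fit_residualizer <- function(data, confounds) {
  data <- as_numeric_matrix(data)
  confounds <- as.data.frame(confounds)
  if (anyNA(data) || anyNA(confounds)) {
    stop("Missing values are not supported; complete records required.",
         call. = FALSE)
  }
  design <- confound_design(confounds)
  if (nrow(data) < ncol(design) + 2L) {
    stop("Need at least ", ncol(design) + 2L, " training rows for ",
         ncol(design), " design columns.", call. = FALSE)
  }
  qr_ <- qr(design)
  if (qr_$rank < ncol(design)) {
    bad <- colnames(design)[qr_$pivot[(qr_$rank + 1L):ncol(design)]]
    stop("Confound design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qr_, data)
  structure(
    list(coefficients = coef,
         design_columns = colnames(design),
         confound_names = names(confounds),
         levels = lapply(confounds, function(x) {
           if (is.factor(x) || is.character(x)) levels(as.factor(x))
         }),
         target_columns = colnames(data)),
    class = "residualizer"
  )
}

#' Remove fitted confound effects from a data partition
#'
#' @param model A fitted [fit_residualizer()] object.
#' @param data Matrix/data frame with the same columns as at fit time.
#' @param confounds Confound table for these rows; categorical levels
#'   must have been seen at fit time (no silent extrapolation).
#' @return The residual matrix `data - design %*% coefficients`.
#' @export
apply_residualizer <- function(model, data, confounds) {
  stopifnot(inherits(model, "residualizer"))
  data <- as_numeric_matrix(data)
  confounds <- as.data.frame(confounds)
  if (!identical(colnames(data), model$target_columns)) {
    stop("Data columns do not match the fitted residualizer: expected ",
         paste(utils::head(model$target_columns, 3), collapse = ", "),
         " ...", call. = FALSE)
  }
  design <- confound_design(confounds, template = model)
  data - design %*% model$coefficients
}

confound_design <- function(confounds, template = NULL) {
  if (!is.null(template)) {
    if (!identical(names(confounds), template$confound_names)) {
      stop("Confound columns do not match the fitted residualizer.",
           call. = FALSE)
    }
    for (nm in names(confounds)) {
      lv <- template$levels[[nm]]
      if (!is.null(lv)) {
        x <- as.character(confounds[[nm]])
        unseen <- setdiff(unique(x), lv)
        if (length(unseen)) {
          stop("Unseen level(s) in confound `", nm, "`: ",
               paste(unseen, collapse = ", "), call. = FALSE)
        }
        confounds[[nm]] <- factor(x, levels = lv)
      }
    }
  } else {
    for (nm in names(confounds)) {
      if (is.character(confounds[[nm]])) {
        confounds[[nm]] <- factor(confounds[[nm]])
      }
    }
  }
  mm <- stats::model.matrix(~ ., data = confounds)
  if (!is.null(template) &&
      !identical(colnames(mm), template$design_columns)) {
    stop("Confound design columns do not match the fitted residualizer.",
         call. = FALSE)
  }
  mm
}

#' Brain-size scaling of parcel-wise measures
#'
#' Three variants of global-size handling for parcel-wise cortical
#' measures: `raw` leaves values untouched; `proportional` divides each
#' subject's parcels by that subject's global reference (mean cortical
#' thickness, or a TIV-like volume); `corrected` regresses each parcel
#' on the global reference with a residualizer fitted on training rows
#' only, so the correction is cross-validation consistent.
#'
#' @param brain Numeric matrix/data frame, subjects x parcels.
#' @param mode One of `"raw"`, `"proportional"`, `"corrected"`.
#' @param global_reference Subject-wise numeric vector (mean CT or TIV).
#'   If `NULL` and needed, the row mean of `brain` is used.
#' @param residualizer For `"corrected"`: a [fit_residualizer()] object
#'   fitted on training rows with the global reference as sole covariate.
#' @return The scaled matrix.
#' @export
brain_scaling <- function(brain,
                          mode = c("raw", "proportional", "corrected"),
                          global_reference = NULL, residualizer = NULL) {
  mode <- match.arg(mode)
  brain <- as_numeric_matrix(brain)
  if (mode == "raw") return(brain)
  if (is.null(global_reference)) global_reference <- rowMeans(brain)
  if (any(global_reference <= 0)) {
    stop("Global reference values must be positive.", call. = FALSE)
  }
  if (mode == "proportional") return(brain / global_reference)
  if (is.null(residualizer)) {
    stop("`corrected` scaling needs a residualizer fitted on training rows ",
         "with the global reference as sole covariate.", call. = FALSE)
  }
  apply_residualizer(residualizer, brain,
                     data.frame(global_reference = global_reference))
}

#' Column standardization fitted on training rows
#'
#' `fit_standardizer()` stores per-column means and standard deviations
#' of the training partition; `apply_standardizer()` z-scores any
#' partition with those training parameters.
#'
#' @param data Training matrix/data frame.
#' @return `fit_standardizer()`: an object of class `standardizer`.
#' @export
fit_standardizer <- function(data) {
  data <- as_numeric_matrix(data)
  mu <- colMeans(data)
  sd_ <- apply(data, 2, stats::sd)
  if (any(sd_ == 0)) {
    bad <- colnames(data)[sd_ == 0]
    stop("Zero-variance training column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu, sd = sd_, columns = colnames(data)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param model A fitted `standardizer`.
#' @export
apply_standardizer <- function(model, data) {
  stopifnot(inherits(model, "standardizer"))
  data <- as_numeric_matrix(data)
  if (!identical(colnames(data), model$columns)) {
    stop("Data columns do not match the fitted standardizer.", call. = FALSE)
  }
  sweep(sweep(data, 2, model$mean, `-`), 2, model$sd, `/`)
}

# full training-fitted preprocessing: scaling -> confound removal ->
# standardization (fixed composition order); returns transforms + data
preprocess_fit <- function(X, Y, confounds = NULL,
                           scaling = "raw", global_reference = NULL) {
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  scale_rz <- NULL
  if (scaling == "corrected") {
    gr <- if (is.null(global_reference)) rowMeans(X) else global_reference
    scale_rz <- fit_residualizer(X, data.frame(global_reference = gr))
    X <- brain_scaling(X, "corrected", gr, scale_rz)
  } else if (scaling == "proportional") {
    X <- brain_scaling(X, "proportional", global_reference)
  }
  rz_x <- rz_y <- NULL
  if (!is.null(confounds) && ncol(as.data.frame(confounds)) > 0) {
    rz_x <- fit_residualizer(X, confounds)
    X <- apply_residualizer(rz_x, X, confounds)
    rz_y <- fit_residualizer(Y, confounds)
    Y <- apply_residualizer(rz_y, Y, confounds)
  }
  sx <- fit_standardizer(X)
  sy <- fit_standardizer(Y)
  list(X = apply_standardizer(sx, X), Y = apply_standardizer(sy, Y),
       transforms = list(scaling = scaling, scale_rz = scale_rz,
                         rz_x = rz_x, rz_y = rz_y, sx = sx, sy = sy))
}

preprocess_apply <- function(transforms, X, Y, confounds = NULL,
                             global_reference = NULL) {
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  if (transforms$scaling == "corrected") {
    gr <- if (is.null(global_reference)) rowMeans(X) else global_reference
    X <- brain_scaling(X, "corrected", gr, transforms$scale_rz)
  } else if (transforms$scaling == "proportional") {
    X <- brain_scaling(X, "proportional", global_reference)
  }
  if (!is.null(transforms$rz_x)) {
    X <- apply_residualizer(transforms$rz_x, X, confounds)
    Y <- apply_residualizer(transforms$rz_y, Y, confounds)
  }
  list(X = apply_standardizer(transforms$sx, X),
       Y = apply_standardizer(transforms$sy, Y))
}

as_numeric_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("subject_id" %in% names(x)) x <- x[setdiff(names(x), "subject_id")]
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stop("Expected a numeric matrix.", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  x
}
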