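#' Build the multiple-holdout split scheme
#'
#' Two nested levels of random splits: each *outer* split divides all
#' subjects into an optimization set and a holdout set (used for
#' statistical evaluation); each *inner* split divides that outer
#' split's optimization set into training and test sets (used for
#' hyperparameter selection). Splits are independent random repetitions,
#' not folds. Optionally stratified so each partition keeps label
#' proportions within one subject of the overall prevalence.
#'
#' @param n_subjects Number of subjects.
#' @param n_outer,n_inner Numbers of outer and inner splits (default 5
#'   each).
#' @param holdout_frac Fraction of subjects held out per outer split.
#' @param test_frac Fraction of the optimization set used as inner test.
#' @param stratify_by Optional label vector (length `n_subjects`).
#' @param seed Integer seed; identical arguments give identical splits.
#' @return A list of class `split_scheme`: per outer split, integer
#'   indices `holdout`, `optimization`, and `inner` — a list of
#'   `(train, test)` index pairs *relative to the optimization vector*.
#' @export
make_splits <- function(n_subjects, n_outer = 5L, n_inner = 5L,
                        holdout_frac = 0.2, test_frac = 0.2,
                        stratify_by = NULL, seed = 1L) {
  stopifnot(n_subjects >= 10, n_outer >= 1, n_inner >= 1)
  if (holdout_frac <= 0 || holdout_frac >= 1 || test_frac <= 0 ||
      test_frac >= 1) {
    stop("Split fractions must lie in (0, 1).", call. = FALSE)
  }
  if (!is.null(stratify_by) && length(stratify_by) != n_subjects) {
    stop("`stratify_by` must have one label per subject.", call. = FALSE)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  outer <- lapply(seq_len(n_outer), function(o) {
    hold <- stratified_sample(seq_len(n_subjects), holdout_frac, stratify_by)
    opt <- setdiff(seq_len(n_subjects), hold)
    labels_opt <- if (is.null(stratify_by)) NULL else stratify_by[opt]
    inner <- lapply(seq_len(n_inner), function(i) {
      test <- stratified_sample(seq_along(opt), test_frac, labels_opt)
      list(train = setdiff(seq_along(opt), test), test = test)
    })
    list(holdout = hold, optimization = opt, inner = inner)
  })

  structure(list(outer = outer, n_outer = n_outer, n_inner = n_inner,
                 holdout_frac = holdout_frac, test_frac = test_frac,
                 seed = seed),
            class = "split_scheme")
}

# sample ~frac of idx; with labels, per-level counts keep proportions
# within one subject of the target
stratified_sample <- function(idx, frac, labels = NULL) {
  n <- length(idx)
  target <- round(frac * n)
  if (target < 1 || target >= n) {
    stop("Split fraction yields an empty partition.", call. = FALSE)
  }
  if (is.null(labels)) return(sort(sample(idx, target)))
  labels <- as.factor(labels)
  take <- floor(frac * table(labels))
  rem <- target - sum(take)
  if (rem > 0) {
    frac_part <- frac * table(labels) - take
    extra <- names(sort(frac_part, decreasing = TRUE))[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  if (any(take > table(labels))) {
    stop("Stratification infeasible for these label counts.", call. = FALSE)
  }
  out <- unlist(lapply(levels(labels), function(l) {
    pool <- idx[labels == l]
    sample(pool, take[[l]])
  }))
  sort(out)
}
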