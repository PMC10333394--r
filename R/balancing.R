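#' Balancing specification
#'
#' A sampling "ratio" is the minority-to-majority count ratio targeted
#' *after* the step (the sampling-strategy convention). The pipeline applies
#' SMOTE first, then random under-sampling on the result: the large
#' under-sampling ratios used in practice (e.g. 0.9) are only attainable
#' after the minority class has been oversampled.
#'
#' @param smote_ratio minority/majority ratio after SMOTE, in (0, 1], or
#'   NULL to skip oversampling.
#' @param under_ratio minority/majority ratio after random under-sampling,
#'   in (0, 1], or NULL to skip.
#' @param k_neighbors number of nearest minority neighbors used by SMOTE
#'   (default 5).
#' @param seed integer seed.
#' @return object of class \code{balance_spec}.
#' @export
balance_spec <- function(smote_ratio = NULL, under_ratio = NULL,
                         k_neighbors = 5L, seed = 1L) {
  for (r in c(smote_ratio, under_ratio))
    if (!is.null(r) && !(r > 0 && r <= 1)) stop("ratios must lie in (0, 1]")
  structure(list(smote_ratio = smote_ratio, under_ratio = under_ratio,
                 k_neighbors = as.integer(k_neighbors), seed = as.integer(seed)),
            class = "balance_spec")
}

#' Per-model balancing defaults
#'
#' The SMOTE / random-under-sampling ratio pairs used by each model family:
#' logistic (0.75, 0.9), neural_net (0.4, 0.5), xgboost (0.5, 0.85),
#' random_forest (0.8, 0.9), balanced_random_forest (0.35, 0.75),
#' balanced_bagging (0.4, 0.6).
#'
#' @param family model family name, or NULL for the full table.
#' @param seed seed stored in the returned spec.
#' @return a \code{\link{balance_spec}} (or a named list of them).
#' @export
default_balance_spec <- function(family = NULL, seed = 1L) {
  tab <- list(
    logistic               = c(0.75, 0.90),
    neural_net             = c(0.40, 0.50),
    xgboost                = c(0.50, 0.85),
    random_forest          = c(0.80, 0.90),
    balanced_random_forest = c(0.35, 0.75),
    balanced_bagging       = c(0.40, 0.60)
  )
  mk <- function(v) balance_spec(v[1], v[2], seed = seed)
  if (is.null(family)) return(lapply(tab, mk))
  if (!family %in% names(tab)) stop("unknown model family: ", family)
  mk(tab[[family]])
}

# class bookkeeping: minority = the rarer label
class_split <- function(fm) {
  if (is.null(fm$y)) stop("feature matrix has no labels")
  n1 <- sum(fm$y == 1); n0 <- sum(fm$y == 0)
  minority <- if (n1 <= n0) 1L else 0L
  list(min_ix = which(fm$y == minority), maj_ix = which(fm$y != minority),
       minority = minority)
}

#' SMOTE oversampling
#'
#' Appends synthetic minority rows until
#' \code{minority_count = round(ratio * majority_count)}. Each synthetic row
#' is \code{x + u * (x_nn - x)} with \code{u} uniform on [0, 1] and
#' \code{x_nn} one of the \code{k_neighbors} nearest minority neighbors of
#' minority row \code{x} (Euclidean distance on the encoded matrix; one-hot
#' columns are interpolated fractionally, as in the standard algorithm).
#' Base rows are cycled in order so the synthetic sample spreads evenly over
#' the minority class. Majority rows are untouched. Deterministic given
#' \code{seed}.
#'
#' @param fm a labeled \code{\link{feature_matrix}}.
#' @param ratio target minority/majority ratio after oversampling.
#' @param k_neighbors nearest-neighbor count, default 5.
#' @param seed integer seed.
#' @return a \code{feature_matrix}; synthetic rows get case ids
#'   \code{"syn_<i>"}. If \code{ratio} does not exceed the current class
#'   ratio the input is returned unchanged with a warning.
#' @export
smote_oversample <- function(fm, ratio, k_neighbors = 5L, seed = 1L) {
  cs <- class_split(fm)
  n_min <- length(cs$min_ix); n_maj <- length(cs$maj_ix)
  if (n_min <= k_neighbors)
    stop("minority class has ", n_min, " members; needs more than k_neighbors = ",
         k_neighbors, " - use a smaller k")
  target <- round(ratio * n_maj)
  if (target <= n_min) {
    if (target < n_min)
      warning("SMOTE ratio ", ratio, " is below the current class ratio; no-op")
    return(fm)
  }
  n_syn <- target - n_min
  M <- fm$x[cs$min_ix, , drop = FALSE]
  d <- as.matrix(stats::dist(M))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  syn <- withr::with_seed(seed, {
    base <- rep_len(seq_len(n_min), n_syn)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_syn, replace = TRUE))]
    u <- stats::runif(n_syn)
    M[base, , drop = FALSE] + u * (M[pick, , drop = FALSE] - M[base, , drop = FALSE])
  })
  feature_matrix(rbind(fm$x, syn),
                 c(fm$y, rep(cs$minority, n_syn)),
                 c(fm$case_id, sprintf("syn_%05d", seq_len(n_syn))))
}

#' Random under-sampling of the majority class
#'
#' Uniformly subsamples majority rows without replacement down to
#' \code{round(minority_count / ratio)}; minority rows are untouched.
#' Deterministic given \code{seed}.
#'
#' @inheritParams smote_oversample
#' @param ratio target minority/majority ratio after under-sampling.
#' @return a \code{feature_matrix} (original row order preserved).
#' @export
random_undersample <- function(fm, ratio, seed = 1L) {
  cs <- class_split(fm)
  n_min <- length(cs$min_ix); n_maj <- length(cs$maj_ix)
  target <- round(n_min / ratio)
  if (target > n_maj)
    stop("under-sampling ratio ", ratio, " would require upsampling the ",
         "majority class (", target, " > ", n_maj, ")")
  keep_maj <- withr::with_seed(seed, sample(cs$maj_ix, target))
  fm_subset(fm, sort(c(cs$min_ix, keep_maj)))
}

#' Combined SMOTE + under-sampling pipeline
#'
#' Applies \code{\link{smote_oversample}} then
#' \code{\link{random_undersample}} according to a
#' \code{\link{balance_spec}}; either step is skipped when its ratio is
#' NULL. Intended for training rows only: the cross-validation engine and
#' pipeline never pass evaluation rows through this function.
#'
#' @param fm a labeled \code{\link{feature_matrix}} of training rows.
#' @param spec a \code{\link{balance_spec}}.
#' @return a balanced \code{feature_matrix}.
#' @export
balance_pipeline <- function(fm, spec) {
  stopifnot(inherits(spec, "balance_spec"))
  if (!is.null(spec$smote_ratio))
    fm <- smote_oversample(fm, spec$smote_ratio, spec$k_neighbors, spec$seed)
  if (!is.null(spec$under_ratio))
    fm <- random_undersample(fm, spec$under_ratio, spec$seed + 1L)
  fm
}
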