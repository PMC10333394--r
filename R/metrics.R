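#' Area under the ROC curve (rank statistic)
#'
#' Wilcoxon/Mann-Whitney form with midrank tie correction: tied
#' positive-negative score pairs count 1/2, so a constant score gives
#' AUC = 0.5.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 (or logical) labels aligned to scores.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# sensitivity/specificity at a probability threshold (>= threshold = positive)
sens_spec <- function(risk, y, threshold) {
  c(sensitivity = mean(risk[y == 1] >= threshold),
    specificity = mean(risk[y == 0] < threshold))
}

#' Calibration by risk deciles
#'
#' Bins are equal-count quantile bins of predicted risk (ties broken by
#' stable sort order); each bin reports its case count, mean predicted risk
#' and observed event rate. The count-weighted mean of observed rates
#' equals the overall prevalence by construction.
#'
#' @param risk predicted probabilities.
#' @param labels 0/1 labels aligned to \code{risk}.
#' @param n_bins number of bins, default 10.
#' @return data.frame with columns \code{bin}, \code{n}, \code{mean_pred},
#'   \code{obs_rate}.
#' @export
calibration_curve <- function(risk, labels, n_bins = 10L) {
  y <- as.integer(labels)
  stopifnot(length(risk) == length(y), n_bins >= 2L)
  n <- length(risk)
  if (n < n_bins) stop("need at least n_bins = ", n_bins, " observations")
  ord <- order(risk)          # stable: ties keep input order
  bin_of <- integer(n)
  bin_of[ord] <- ceiling(seq_len(n) * n_bins / n)
  agg <- function(f) vapply(seq_len(n_bins), function(b) f(bin_of == b), numeric(1))
  data.frame(bin = seq_len(n_bins),
             n = agg(function(i) sum(i)),
             mean_pred = agg(function(i) mean(risk[i])),
             obs_rate = agg(function(i) mean(y[i])))
}

#' Evaluation report for a risk predictor
#'
#' AUC, and sensitivity/specificity at a probability threshold, each with a
#' 95% confidence interval from a label-stratified bootstrap (positives and
#' negatives resampled separately, preserving prevalence), plus a decile
#' calibration table.
#'
#' @param risk predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold classification threshold, default 0.5.
#' @param n_boot bootstrap resamples, default 2000.
#' @param seed integer seed for the bootstrap.
#' @param n_bins calibration bins (skipped when fewer rows than bins).
#' @return object of class \code{eval_report}.
#' @export
eval_report <- function(risk, labels, threshold = 0.5, n_boot = 2000L,
                        seed = 1L, n_bins = 10L) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("evaluation set has a single class")
  point <- c(auc = auc_score(risk, y), sens_spec(risk, y, threshold))
  pos <- which(y == 1); neg <- which(y == 0)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ix <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      c(auc_score(risk[ix], y[ix]), sens_spec(risk[ix], y[ix], threshold))
    }, numeric(3))
  })
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975))
  metric <- function(i) list(estimate = unname(point[i]),
                             ci_lower = unname(ci[1, i]),
                             ci_upper = unname(ci[2, i]))
  structure(list(
    auc = metric(1), sensitivity = metric(2), specificity = metric(3),
    threshold = threshold,
    calibration = if (length(y) >= n_bins) calibration_curve(risk, y, n_bins),
    n_eval = length(y), n_boot = n_boot
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  f <- function(m, nm) cat(sprintf("  %-12s %.3f (%.3f, %.3f)\n",
                                   nm, m$estimate, m$ci_lower, m$ci_upper))
  cat("Evaluation on", x$n_eval, "cases (threshold", x$threshold, "):\n")
  f(x$auc, "AUC"); f(x$sensitivity, "Sensitivity"); f(x$specificity, "Specificity")
  invisible(x)
}

#' Serialize an evaluation report as JSON
#' @param report an \code{eval_report}.
#' @param path file path.
#' @export
write_eval_report <- function(report, path) {
  x <- unclass(report)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
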