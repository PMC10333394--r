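#' Empirical prolonged-stay threshold
#'
#' Returns the empirical quantile of observed PACU LOS at the given level,
#' using the linear-interpolation convention between order statistics
#' (\code{stats::quantile} type 7). The pipeline's canonical outcome
#' threshold is fixed at 180 minutes; this operation exists to verify or
#' re-derive that threshold on a cohort, where the 75th percentile and
#' 180 need not coincide exactly.
#'
#' @param los_values numeric vector of LOS minutes, all >= 0.
#' @param quantile quantile level, default 0.75.
#' @return threshold in minutes.
#' @export
compute_prolonged_threshold <- function(los_values, quantile = 0.75) {
  if (length(los_values) == 0) stop("los_values must be non-empty")
  if (any(los_values < 0)) stop("LOS values must be >= 0")
  unname(stats::quantile(los_values, quantile, type = 7))
}

#' Label prolonged PACU stays
#'
#' TRUE iff \code{pacu_los >= threshold}; the boundary is inclusive
#' (a 180-minute stay counts as prolonged under the default).
#'
#' @param pacu_los numeric vector of minutes, >= 0.
#' @param threshold minutes, default 180.
#' @return logical vector.
#' @export
label_prolonged <- function(pacu_los, threshold = 180) {
  if (any(pacu_los < 0)) stop("negative PACU LOS")
  pacu_los >= threshold
}

#' Feature matrix container
#'
#' A numeric design matrix with an aligned binary label vector and case ids.
#'
#' @param x numeric matrix (rows = cases, named columns).
#' @param y integer/logical label vector (1 = prolonged) or NULL.
#' @param case_id character vector of case ids.
#' @return object of class \code{feature_matrix}.
#' @export
feature_matrix <- function(x, y = NULL, case_id = rownames(x)) {
  if (!is.null(y)) {
    y <- as.integer(y)
    stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  }
  if (is.null(case_id)) case_id <- as.character(seq_len(nrow(x)))
  structure(list(x = x, y = y, case_id = case_id), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "cases x", ncol(x$x), "features")
  if (!is.null(x$y)) cat(";", sum(x$y), "positive")
  cat("\n")
  invisible(x)
}

#' Number of rows of a feature matrix
#' @param fm a \code{feature_matrix}.
#' @export
fm_nrow <- function(fm) nrow(fm$x)

# subset rows of a feature matrix
fm_subset <- function(fm, i) {
  feature_matrix(fm$x[i, , drop = FALSE],
                 if (!is.null(fm$y)) fm$y[i], fm$case_id[i])
}

#' One-hot encode a case table into a feature matrix
#'
#' Numeric features (age, bmi, scheduled_duration) pass through unscaled;
#' sex, ASA Physical Status (fixed domain 1-4) and procedure become one-hot
#' groups with deterministic, sorted column ordering; the 16 comorbidity
#' flags become 0/1 columns. Scaling, where a model family needs it, is that
#' family's concern.
#'
#' @param cases data.frame of cases (complete fields).
#' @param procedure_levels explicit procedure level set; defaults to the
#'   sorted levels observed in \code{cases}. An unseen level at encoding
#'   time raises an error naming the level.
#' @return a \code{\link{feature_matrix}}; labels are taken from a
#'   \code{prolonged} column when present.
#' @export
encode_features <- function(cases, procedure_levels = NULL) {
  if (is.null(procedure_levels)) procedure_levels <- sort(unique(cases$procedure))
  unseen <- setdiff(unique(cases$procedure), procedure_levels)
  if (length(unseen))
    stop("unseen procedure level(s): ", paste(unseen, collapse = ", "))
  if (!all(cases$asa_ps %in% 1:4)) stop("asa_ps outside {1,2,3,4}")
  if (!all(cases$sex %in% c("female", "male"))) stop("unseen sex level")
  one_hot <- function(values, levels, prefix) {
    m <- vapply(levels, function(l) as.numeric(values == l),
                numeric(length(values)))
    if (length(values) == 1L) m <- matrix(m, nrow = 1)
    colnames(m) <- paste0(prefix, levels)
    m
  }
  flags <- vapply(comorbidity_names(), function(nm) as.numeric(cases[[nm]]),
                  numeric(nrow(cases)))
  if (nrow(cases) == 1L)
    flags <- matrix(flags, nrow = 1, dimnames = list(NULL, comorbidity_names()))
  x <- cbind(
    age = as.numeric(cases$age),
    bmi = as.numeric(cases$bmi),
    scheduled_duration = as.numeric(cases$scheduled_duration),
    one_hot(cases$sex, c("female", "male"), "sex_"),
    one_hot(cases$asa_ps, 1:4, "asa_"),
    one_hot(cases$procedure, procedure_levels, "procedure_"),
    flags
  )
  rownames(x) <- NULL
  feature_matrix(x, y = if ("prolonged" %in% names(cases)) cases$prolonged,
                 case_id = cases$case_id)
}

#' Decode categorical fields from an encoded matrix
#'
#' Inverse of the categorical part of \code{\link{encode_features}};
#' numeric features pass back as-is. Used to verify the encoding is
#' lossless.
#'
#' @param fm a \code{feature_matrix} produced by \code{encode_features}.
#' @return data.frame with case_id, numeric features, sex, asa_ps,
#'   procedure, and the comorbidity flags.
#' @export
decode_features <- function(fm) {
  x <- fm$x
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix), colnames(x), value = TRUE)
    lv <- sub(paste0("^", prefix), "", cols)
    lv[apply(x[, cols, drop = FALSE], 1, which.max)]
  }
  out <- data.frame(
    case_id = fm$case_id,
    age = x[, "age"], bmi = x[, "bmi"],
    scheduled_duration = x[, "scheduled_duration"],
    sex = pick("sex_"),
    asa_ps = as.integer(pick("asa_")),
    procedure = pick("procedure_"),
    stringsAsFactors = FALSE
  )
  for (nm in comorbidity_names()) out[[nm]] <- x[, nm] == 1
  out
}

#' Label-stratified train/test split
#'
#' Randomly assigns \code{round(ratio * n_class)} rows of each class to the
#' training set, so class prevalence is preserved on both sides (an exact
#' stratified split). Deterministic given \code{seed}.
#'
#' @param fm a \code{feature_matrix} with labels.
#' @param ratio training fraction, default 0.8.
#' @param seed integer seed.
#' @return object of class \code{split_result}: list with \code{train},
#'   \code{test}, \code{ratio}, \code{seed}.
#' @export
split_train_test <- function(fm, ratio = 0.8, seed = 1L) {
  if (is.null(fm$y)) stop("feature matrix has no labels")
  if (fm_nrow(fm) < 10L) stop("need at least 10 rows to split")
  if (length(unique(fm$y)) < 2L) stop("both classes must be present")
  train_ix <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(fm_nrow(fm)), fm$y), function(ix)
      sample(ix, round(ratio * length(ix)))), use.names = FALSE)
  })
  train_ix <- sort(train_ix)
  structure(list(train = fm_subset(fm, train_ix),
                 test = fm_subset(fm, setdiff(seq_len(fm_nrow(fm)), train_ix)),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_result")
}

#' Write split membership to CSV
#' @param split a \code{split_result}.
#' @param path file path.
#' @export
write_split_csv <- function(split, path) {
  df <- data.frame(
    case_id = c(split$train$case_id, split$test$case_id),
    set = c(rep("train", fm_nrow(split$train)), rep("test", fm_nrow(split$test))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
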