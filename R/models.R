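#' Model registry: default hyperparameters per family
#'
#' The six classifier families and their shipped hyperparameter defaults:
#' \describe{
#'   \item{logistic}{L2-penalized logistic regression, C = 6 (inverse
#'     regularization strength, scikit-learn convention).}
#'   \item{neural_net}{one hidden layer of 128 ReLU units, 100 epochs,
#'     batch size 64, learning rate 1e-4 (Adam).}
#'   \item{xgboost}{objective binary:hinge, column subsample 0.55, learning
#'     rate 0.01, max depth 300, 500 rounds, L2 term 1.5. A max depth this
#'     large is almost certainly a transcription artifact of the source
#'     tuning report and badly overfits; it is shipped as-is but
#'     \code{train_model} warns when depth exceeds 30, and the pipeline
#'     default overrides it to 3 (see \code{\link{pipeline_config}}).}
#'   \item{random_forest}{500 trees.}
#'   \item{balanced_random_forest}{2000 trees, each grown on a bootstrap
#'     under-sampled to minority/majority = 0.95.}
#'   \item{balanced_bagging}{1200 bagged trees on bootstraps under-sampled
#'     to class parity, all features eligible at each split.}
#' }
#'
#' @param family family name, or NULL for the whole registry.
#' @return named list of hyperparameters (or list of lists).
#' @export
model_registry <- function(family = NULL) {
  reg <- list(
    logistic = list(C = 6),
    neural_net = list(hidden_layers = 1L, hidden_units = 128L, max_iter = 100L,
                      batch_size = 64L, learning_rate = 1e-4,
                      activation = "relu"),
    xgboost = list(objective = "binary:hinge", colsample_bytree = 0.55,
                   eta = 0.01, max_depth = 300L, nrounds = 500L, lambda = 1.5),
    random_forest = list(num_trees = 500L),
    balanced_random_forest = list(num_trees = 2000L, sampling_strategy = 0.95),
    balanced_bagging = list(num_trees = 1200L, sampling_strategy = 1.0)
  )
  if (is.null(family)) return(reg)
  if (!family %in% names(reg)) stop("unknown model family: ", family)
  reg[[family]]
}

#' Model specification
#'
#' @param family one of \code{logistic}, \code{neural_net}, \code{xgboost},
#'   \code{random_forest}, \code{balanced_random_forest},
#'   \code{balanced_bagging}.
#' @param hyperparameters overrides merged onto
#'   \code{\link{model_registry}(family)}.
#' @param balance a \code{\link{balance_spec}} applied to training rows, or
#'   NULL for none. \code{default_balance_spec(family)} gives the shipped
#'   per-family ratios.
#' @param seed integer seed.
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(family, hyperparameters = list(), balance = NULL,
                       seed = 1L) {
  hp <- utils::modifyList(model_registry(family), hyperparameters)
  if (!is.null(balance)) stopifnot(inherits(balance, "balance_spec"))
  structure(list(family = family, hyperparameters = hp, balance = balance,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a classifier
#'
#' Applies the spec's balancing (training rows only), then fits the family.
#' Tree and linear families are deterministic given the seed; the neural
#' net is deterministic too since all of its randomness flows through R's
#' RNG.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param train a labeled \code{\link{feature_matrix}}.
#' @return object of class \code{pacu_model}.
#' @export
train_model <- function(spec, train) {
  stopifnot(inherits(spec, "model_spec"), inherits(train, "feature_matrix"))
  if (is.null(train$y) || length(unique(train$y)) < 2L)
    stop("training labels are degenerate (need both classes)")
  if (!is.null(spec$balance)) train <- balance_pipeline(train, spec$balance)
  hp <- spec$hyperparameters
  x <- train$x; y <- train$y
  fit <- switch(spec$family,
    logistic = {
      lambda <- 1 / (nrow(x) * hp$C)
      glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                     standardize = FALSE, thresh = 1e-12)
    },
    neural_net = mlp_fit(x, y, hidden = hp$hidden_units, epochs = hp$max_iter,
                         batch_size = hp$batch_size,
                         learning_rate = hp$learning_rate, seed = spec$seed),
    xgboost = {
      if (hp$max_depth > 30L)
        warning("xgboost max_depth = ", hp$max_depth,
                " grows implausibly deep trees and is likely to overfit; ",
                "consider a depth of 3-8")
      xgboost::xgb.train(
        params = list(objective = hp$objective, eta = hp$eta,
                      max_depth = hp$max_depth,
                      colsample_bytree = hp$colsample_bytree,
                      lambda = hp$lambda, tree_method = "hist",
                      nthread = 1, seed = spec$seed),
        data = xgboost::xgb.DMatrix(x, label = y), nrounds = hp$nrounds,
        verbose = 0)
    },
    random_forest = ranger::ranger(x = x, y = factor(y, levels = 0:1),
                                   num.trees = hp$num_trees,
                                   probability = TRUE, seed = spec$seed,
                                   num.threads = 1),
    balanced_random_forest = ranger_balanced(x, y, hp$num_trees,
                                             hp$sampling_strategy, spec$seed),
    balanced_bagging = ranger_balanced(x, y, hp$num_trees,
                                       hp$sampling_strategy, spec$seed,
                                       mtry = ncol(x), min_node = 1L),
    stop("unknown model family: ", spec$family)
  )
  structure(list(family = spec$family, spec = spec, fit = fit,
                 features = colnames(x)),
            class = "pacu_model")
}

# Bootstrap-balanced random forest: each tree draws (with replacement) all
# minority cases and minority/strategy majority cases, the per-bootstrap
# under-sampling behind balanced random forests and balanced bagging.
ranger_balanced <- function(x, y, num_trees, strategy, seed,
                            mtry = NULL, min_node = NULL) {
  n <- nrow(x)
  n_min <- min(sum(y == 1), sum(y == 0))
  minority <- if (sum(y == 1) <= sum(y == 0)) "1" else "0"
  frac <- c(`0` = 0, `1` = 0)
  frac[minority] <- n_min / n
  frac[setdiff(c("0", "1"), minority)] <- (n_min / strategy) / n
  ranger::ranger(x = x, y = factor(y, levels = 0:1), num.trees = num_trees,
                 replace = TRUE, sample.fraction = unname(frac[c("0", "1")]),
                 mtry = mtry, min.node.size = min_node,
                 probability = TRUE, seed = seed, num.threads = 1)
}

#' Predict prolonged-stay risk
#'
#' Returns P(prolonged) per row. For the hinge-objective gradient booster
#' the raw margin is mapped through the logistic function - a documented
#' monotone link to (0, 1), so rankings (and hence AUC and resequencing
#' order) are unaffected by the choice of link.
#'
#' @param model a \code{pacu_model}.
#' @param fm a \code{\link{feature_matrix}} with the training columns.
#' @return numeric probability vector aligned to rows.
#' @export
predict_risk <- function(model, fm) {
  stopifnot(inherits(model, "pacu_model"))
  x <- fm$x
  if (!identical(colnames(x), model$features)) {
    missing <- setdiff(model$features, colnames(x))
    extra <- setdiff(colnames(x), model$features)
    if (length(missing) || length(extra))
      stop("feature columns do not match training columns; missing: [",
           paste(missing, collapse = ", "), "], unexpected: [",
           paste(extra, collapse = ", "), "]")
    x <- x[, model$features, drop = FALSE]
  }
  switch(model$family,
    logistic = as.numeric(stats::predict(model$fit, newx = x, type = "response")),
    neural_net = mlp_predict(model$fit, x),
    xgboost = stats::plogis(stats::predict(model$fit, xgboost::xgb.DMatrix(x),
                                           outputmargin = TRUE)),
    # probability forests
    stats::predict(model$fit, data = x, num.threads = 1)$predictions[, "1"]
  )
}

#' Stratified k-fold cross-validation
#'
#' Folds are label-stratified; balancing (when the spec carries one) is
#' applied inside each fold to the fold-training portion only, so no
#' synthetic or resampled row ever reaches evaluation. Out-of-fold
#' predictions are pooled and metrics computed once on the pooled vector.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param train a labeled \code{\link{feature_matrix}}.
#' @param k number of folds, default 10.
#' @param seed fold-assignment seed.
#' @param ... passed to \code{\link{eval_report}} (e.g. \code{n_boot}).
#' @return an \code{eval_report}; \code{n_eval} equals \code{fm_nrow(train)}.
#' @export
cross_validate <- function(spec, train, k = 10L, seed = 1L, ...) {
  n <- fm_nrow(train)
  if (k < 2L) stop("k must be >= 2")
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cls in unique(train$y)) {
      ix <- which(train$y == cls)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  for (f in seq_len(k))
    if (length(unique(train$y[fold == f])) < 2L)
      stop("fold ", f, " lacks a class; use a smaller k")
  risk <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    hold <- fold == f
    model <- train_model(spec, fm_subset(train, which(!hold)))
    risk[hold] <- predict_risk(model, fm_subset(train, which(hold)))
  }
  stopifnot(!anyNA(risk))  # pooled out-of-fold count == training size
  eval_report(risk, train$y, seed = seed, ...)
}

#' Evaluate a fitted model on a held-out test set
#'
#' @param model a \code{pacu_model}.
#' @param test a labeled \code{\link{feature_matrix}}, untouched by
#'   balancing.
#' @param threshold probability threshold for sensitivity/specificity.
#' @param n_boot bootstrap resamples for the 95% CIs.
#' @param seed bootstrap seed.
#' @return an \code{eval_report}.
#' @export
evaluate_on_test <- function(model, test, threshold = 0.5, n_boot = 2000L,
                             seed = 1L) {
  risk <- predict_risk(model, test)
  eval_report(risk, test$y, threshold = threshold, n_boot = n_boot, seed = seed)
}

#' Feature importance ranking
#'
#' For the gradient booster, per-feature mean absolute Shapley attribution
#' (TreeSHAP via \code{predcontrib}); for other families, permutation
#' importance (mean AUC drop over shuffles of each column). The method used
#' is flagged in the output.
#'
#' @param model a \code{pacu_model}.
#' @param fm a labeled \code{\link{feature_matrix}} to attribute on.
#' @param method \code{"auto"} (TreeSHAP where supported, else
#'   permutation), \code{"shap"}, or \code{"permutation"}.
#' @param n_repeats shuffles per feature for permutation importance.
#' @param seed permutation seed.
#' @return data.frame (feature, importance, method) sorted descending.
#' @export
feature_importance <- function(model, fm, method = c("auto", "shap",
                                                     "permutation"),
                               n_repeats = 5L, seed = 1L) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (model$family == "xgboost") "shap" else "permutation"
  if (method == "shap" && model$family != "xgboost") {
    message("Shapley attribution unavailable for family '", model$family,
            "'; falling back to permutation importance")
    method <- "permutation"
  }
  if (method == "shap") {
    contrib <- stats::predict(model$fit, xgboost::xgb.DMatrix(fm$x),
                              predcontrib = TRUE)
    imp <- colMeans(abs(contrib[, model$features, drop = FALSE]))
  } else {
    if (is.null(fm$y)) stop("permutation importance needs labels")
    base <- auc_score(predict_risk(model, fm), fm$y)
    imp <- withr::with_seed(seed, vapply(model$features, function(col) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        x2 <- fm$x
        x2[, col] <- sample(x2[, col])
        base - auc_score(predict_risk(model,
          feature_matrix(x2, fm$y, fm$case_id)), fm$y)
      }, numeric(1))
      mean(drops)
    }, numeric(1)))
  }
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    method = method, stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}
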