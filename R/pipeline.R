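#' End-to-end pipeline configuration
#'
#' Ties the stages together: generate (or load) a cohort, label, encode,
#' split, balance + train, evaluate, resequence, report. All randomness
#' flows from \code{master_seed}; each stage derives its own substream, so
#' reruns with the same configuration are bit-identical.
#'
#' @param cohort a \code{\link{cohort_config}} (its seed is overridden by
#'   \code{master_seed}).
#' @param model_family one of the six registry families.
#' @param hyperparameters overrides onto \code{\link{model_registry}}. The
#'   default overrides the gradient booster's printed max depth of 300 to
#'   3: shallow trees are the standard choice for boosting with a small
#'   learning rate, and the printed depth badly overfits (see
#'   \code{\link{model_registry}}).
#' @param balance a \code{\link{balance_spec}}; defaults to the family's
#'   shipped ratios.
#' @param split_ratio training fraction.
#' @param threshold probability threshold for classification and for the
#'   resequenced-day rule.
#' @param cutoff after-hours clock time.
#' @param full_day_cutoff full-day clock time.
#' @param turnover minutes between cases.
#' @param yates continuity correction for the chi-square test.
#' @param n_boot bootstrap resamples for evaluation CIs.
#' @param master_seed master seed for every stage.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            model_family = "xgboost",
                            hyperparameters = if (model_family == "xgboost")
                              list(max_depth = 3L) else list(),
                            balance = default_balance_spec(model_family),
                            split_ratio = 0.8,
                            threshold = 0.5,
                            cutoff = "19:00",
                            full_day_cutoff = "15:00",
                            turnover = 0,
                            yates = FALSE,
                            n_boot = 2000L,
                            master_seed = 1L) {
  cohort$seed <- as.integer(master_seed)
  balance$seed <- derive_seed(master_seed, "balance")
  structure(list(cohort = cohort, model_family = model_family,
                 hyperparameters = hyperparameters, balance = balance,
                 split_ratio = split_ratio, threshold = threshold,
                 cutoff = cutoff, full_day_cutoff = full_day_cutoff,
                 turnover = turnover, yates = yates, n_boot = n_boot,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate -> label -> encode -> split -> balance + train ->
#' evaluate -> resequence -> report, optionally writing every artifact
#' (cohort CSV, OR-day CSV, split CSV, evaluation JSON, calibration CSV,
#' risk CSV, schedule CSV, resequencing JSON, and a provenance log with
#' seeds and package versions) under \code{out_dir}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir directory for artifacts, or NULL to skip writing.
#' @return list with \code{cohort}, \code{split}, \code{model},
#'   \code{evaluation}, \code{risk}, \code{days}, \code{resequencing},
#'   \code{config}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$cohort)
  fm <- encode_features(cohort$cases)
  split <- split_train_test(fm, config$split_ratio,
                            seed = derive_seed(config$master_seed, "split"))
  spec <- model_spec(config$model_family, config$hyperparameters,
                     balance = config$balance,
                     seed = derive_seed(config$master_seed, "model"))
  model <- train_model(spec, split$train)
  evaluation <- evaluate_on_test(model, split$test,
                                 threshold = config$threshold,
                                 n_boot = config$n_boot,
                                 seed = derive_seed(config$master_seed, "eval"))
  risk <- stats::setNames(predict_risk(model, split$test), split$test$case_id)
  # The test cases are reassembled into fresh OR days: a random case-level
  # split leaves only fragments of the original days on the test side, so
  # the held-out day structure (median 4 [3, 6] cases, full-day mix) is
  # re-drawn from the same generative day mechanics over test cases only.
  test_cases <- cohort$cases[cohort$cases$case_id %in% split$test$case_id, ]
  day_cfg <- config$cohort
  day_cfg$n_cases <- nrow(test_cases)
  day_cfg$seed <- derive_seed(config$master_seed, "testdays")
  test_cases <- assemble_or_days(test_cases, day_cfg)$cases
  days <- reconstruct_or_days(test_cases,
                              full_day_cutoff = config$full_day_cutoff,
                              turnover = config$turnover, full_only = TRUE)
  resequencing <- compare_schedules(days, test_cases, risk,
                                    cutoff = config$cutoff,
                                    turnover = config$turnover,
                                    threshold = config$threshold,
                                    yates = config$yates)
  result <- list(cohort = cohort, split = split, model = model,
                 evaluation = evaluation, risk = risk,
                 test_cases = test_cases, days = days,
                 resequencing = resequencing, config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @keywords internal
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_cohort_csv(result$cohort$cases, p("cohort.csv"))
  write_or_day_csv(result$cohort$or_days, p("or_days.csv"))
  write_split_csv(result$split, p("split.csv"))
  write_eval_report(result$evaluation, p("evaluation.json"))
  if (!is.null(result$evaluation$calibration))
    utils::write.csv(result$evaluation$calibration, p("calibration.csv"),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(case_id = names(result$risk),
                              risk = unname(result$risk)),
                   p("risk.csv"), row.names = FALSE, quote = FALSE)
  write_schedule_csv(result$days, result$test_cases, result$risk,
                     p("schedules.csv"),
                     cutoff = result$config$cutoff,
                     turnover = result$config$turnover,
                     threshold = result$config$threshold)
  write_resequencing_report(result$resequencing, p("resequencing.json"))
  cfg <- result$config
  log <- list(
    master_seed = cfg$master_seed,
    stage_seeds = list(split = derive_seed(cfg$master_seed, "split"),
                       balance = cfg$balance$seed,
                       model = derive_seed(cfg$master_seed, "model"),
                       eval = derive_seed(cfg$master_seed, "eval")),
    model_family = cfg$model_family,
    hyperparameters = result$model$spec$hyperparameters,
    balance = unclass(cfg$balance),
    split_ratio = cfg$split_ratio, threshold = cfg$threshold,
    cutoff = cfg$cutoff, turnover = cfg$turnover, yates = cfg$yates,
    versions = list(
      pacuseq = as.character(utils::packageVersion("pacuseq")),
      R = paste(R.version$major, R.version$minor, sep = "."),
      xgboost = as.character(utils::packageVersion("xgboost")),
      ranger = as.character(utils::packageVersion("ranger")),
      glmnet = as.character(utils::packageVersion("glmnet")))
  )
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, digits = NA)
  write_cohort_config(cfg$cohort, p("cohort_config.yaml"))
  invisible(out_dir)
}
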