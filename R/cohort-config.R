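#' @keywords internal
comorbidity_names <- function() {
  c("active_smoker", "alcohol_abuse_history", "anxiety", "asthma", "ckd",
    "copd", "chronic_pain", "cad", "depression", "dm", "dysrhythmias",
    "gerd", "seizure_history", "hypertension", "hypothyroidism", "osa")
}

#' Default comorbidity prevalences
#'
#' Marginal prevalences of the 16 binary comorbidity flags in the reference
#' (non-prolonged) ambulatory-surgery population.
#'
#' @return named numeric vector of fractions.
#' @export
default_comorbidity_prevalences <- function() {
  c(active_smoker = 0.024, alcohol_abuse_history = 0.055, anxiety = 0.091,
    asthma = 0.055, ckd = 0.006, copd = 0.007, chronic_pain = 0.024,
    cad = 0.015, depression = 0.065, dm = 0.017, dysrhythmias = 0.019,
    gerd = 0.093, seizure_history = 0.007, hypertension = 0.151,
    hypothyroidism = 0.059, osa = 0.053)
}

#' @keywords internal
default_procedure_weights <- function() {
  c(general = 0.18, orthopedics = 0.17, ent = 0.14, urology = 0.12,
    gynecology = 0.11, plastics = 0.10, ophthalmology = 0.10, pain = 0.08)
}

#' Configuration for the synthetic surgical cohort generator
#'
#' Defaults emulate an ambulatory surgery center population: a 5.31%
#' prevalence of prolonged PACU stay (>= 180 min), short/prolonged-stay
#' median LOS of 81 and 210 minutes, 38.4% male sex, median age 51 [37, 63]
#' years, median BMI 26.5 [23.3, 30.6] kg/m2, median scheduled case duration
#' 60 [38, 95] minutes, and operating-room days with a median of 4 [3, 6]
#' cases starting at 07:30.
#'
#' PACU LOS is generated from a log-linear model
#' \code{log(LOS) = b0 + b_f I(female) + b_d log(duration) + b_b z(BMI) +
#' b_a z(age) + eps}, with Gaussian \code{eps}. The total log-scale spread is
#' derived from the configured prevalence target and the two conditional LOS
#' medians, the residual standard deviation absorbs whatever the linear
#' predictor does not explain, and the intercept \code{b0} is calibrated
#' numerically (see \code{\link{calibrate_los_intercept}}) so that the
#' marginal fraction of LOS >= \code{prolonged_threshold} matches
#' \code{prolonged_prevalence_target}.
#'
#' @param n_cases number of surgical cases to generate.
#' @param prolonged_prevalence_target target fraction of cases with
#'   LOS >= \code{prolonged_threshold}; must lie in (0, 0.5).
#' @param prolonged_threshold minutes defining a prolonged stay (default 180).
#' @param median_los_short,median_los_long target median LOS (minutes) below
#'   and at/above the threshold.
#' @param sex_male_fraction fraction of male cases.
#' @param age_median,age_iqr median and quartiles (years) of age, drawn from
#'   a normal truncated to [18, 90].
#' @param bmi_median,bmi_iqr median and quartiles (kg/m2) of BMI (log-normal).
#' @param duration_median,duration_iqr median and quartiles (minutes) of
#'   scheduled case duration (log-normal, floored at 15 min, whole minutes).
#' @param asa_weights probability vector over ASA Physical Status 1-4.
#' @param comorbidity_prevalences named fractions for the 16 flags.
#' @param procedure_weights named probability vector over procedure
#'   categories.
#' @param effect_sizes named log-scale LOS effects: \code{female_sex}
#'   (additive for female patients), \code{log_duration} (per log-minute),
#'   \code{bmi} and \code{age} (per IQR-based standard deviation).
#' @param los_log_sd residual log-scale standard deviation; \code{NULL}
#'   (default) derives it from the prevalence target and LOS medians.
#' @param cases_per_day_weights probability vector over 1..k cases per
#'   operating-room day (default has median 4, quartiles [3, 6]).
#' @param day_start first-case start time, \code{"HH:MM"} or minutes.
#' @param turnover minutes between consecutive cases in a room.
#' @param full_day_cutoff a day is "full" when its last case's scheduled end
#'   reaches this time (default 15:00).
#' @param seed master seed; per-stage substreams are derived from it.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_cases = 10928,
                          prolonged_prevalence_target = 0.0531,
                          prolonged_threshold = 180,
                          median_los_short = 81,
                          median_los_long = 210,
                          sex_male_fraction = 0.384,
                          age_median = 51, age_iqr = c(37, 63),
                          bmi_median = 26.5, bmi_iqr = c(23.3, 30.6),
                          duration_median = 60, duration_iqr = c(38, 95),
                          asa_weights = c(`1` = 0.1914, `2` = 0.0017,
                                          `3` = 0.5707, `4` = 0.2362),
                          comorbidity_prevalences = default_comorbidity_prevalences(),
                          procedure_weights = default_procedure_weights(),
                          effect_sizes = c(female_sex = 0.17, log_duration = 0.25,
                                           bmi = 0.08, age = 0.08),
                          los_log_sd = NULL,
                          cases_per_day_weights = c(0.01, 0.05, 0.19, 0.25, 0.01,
                                                    0.24, 0.12, 0.08, 0.05),
                          day_start = "07:30",
                          turnover = 0,
                          full_day_cutoff = "15:00",
                          seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases),
    prolonged_prevalence_target = prolonged_prevalence_target,
    prolonged_threshold = prolonged_threshold,
    median_los_short = median_los_short,
    median_los_long = median_los_long,
    sex_male_fraction = sex_male_fraction,
    age_median = age_median, age_iqr = age_iqr,
    bmi_median = bmi_median, bmi_iqr = bmi_iqr,
    duration_median = duration_median, duration_iqr = duration_iqr,
    asa_weights = asa_weights / sum(asa_weights),
    comorbidity_prevalences = comorbidity_prevalences,
    procedure_weights = procedure_weights / sum(procedure_weights),
    effect_sizes = effect_sizes,
    los_log_sd = los_log_sd,
    cases_per_day_weights = cases_per_day_weights / sum(cases_per_day_weights),
    day_start = parse_hm(day_start),
    turnover = turnover,
    full_day_cutoff = parse_hm(full_day_cutoff),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @keywords internal
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_cases < 1L) stop("n_cases must be >= 1")
  p <- cfg$prolonged_prevalence_target
  if (!(p > 0 && p < 0.5)) stop("prolonged_prevalence_target must be in (0, 0.5)")
  if (!(cfg$median_los_long > cfg$median_los_short && cfg$median_los_short > 0))
    stop("require median_los_long > median_los_short > 0")
  if (cfg$duration_median <= 0 || any(cfg$duration_iqr <= 0))
    stop("scheduled durations must be positive")
  for (nm in c("asa_weights", "procedure_weights", "cases_per_day_weights")) {
    w <- cfg[[nm]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop(nm, " must be a probability vector summing to 1")
  }
  cp <- cfg$comorbidity_prevalences
  if (!setequal(names(cp), comorbidity_names()))
    stop("comorbidity_prevalences must name exactly the 16 known flags")
  if (any(cp < 0 | cp > 1)) stop("comorbidity prevalences must be in [0, 1]")
  req <- c("female_sex", "log_duration", "bmi", "age")
  if (!all(req %in% names(cfg$effect_sizes)))
    stop("effect_sizes must name: ", paste(req, collapse = ", "))
  invisible(cfg)
}

#' Read / write a cohort configuration as YAML
#'
#' Every generator default is a named key, so a run's effective configuration
#' can be archived alongside its artifacts.
#'
#' @param cfg a \code{cohort_config}.
#' @param path file path.
#' @return \code{read_cohort_config} returns a \code{cohort_config}.
#' @export
write_cohort_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$day_start <- format_hm(x$day_start)
  x$full_day_cutoff <- format_hm(x$full_day_cutoff)
  for (nm in c("asa_weights", "comorbidity_prevalences", "procedure_weights",
               "effect_sizes"))
    x[[nm]] <- as.list(x[[nm]])   # yaml drops names of atomic vectors
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("asa_weights", "comorbidity_prevalences", "procedure_weights",
               "effect_sizes"))
    x[[nm]] <- unlist(x[[nm]])
  x$cases_per_day_weights <- unlist(x$cases_per_day_weights)
  do.call(cohort_config, x)
}

# Deterministic substream seed for a named stage, kept below 2^31.
#' @keywords internal
derive_seed <- function(master, stage) {
  offs <- c(cases = 11L, los = 23L, calibration = 37L, days = 51L,
            split = 67L, balance = 79L, model = 97L, eval = 113L,
            testdays = 131L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (as.integer(master) %% 20000000L) * 101L + offs[[stage]]
}
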