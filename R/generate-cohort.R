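## Synthetic ambulatory-surgery cohort generator.
##
## Continuous features come from log-normal / truncated-normal families
## parameterized by their configured median and IQR; comorbidity flags are
## independent Bernoulli draws; PACU LOS follows a log-linear model whose
## intercept is calibrated against the configured prevalence target.

# sd implied by an IQR under normality on the given scale
iqr_sd <- function(iqr) (iqr[2] - iqr[1]) / (2 * stats::qnorm(0.75))

# z-score against the configured reference median/IQR (not the sample)
config_z <- function(x, med, iqr) (x - med) / iqr_sd(iqr)

#' Generate synthetic surgical cases
#'
#' Draws \code{config$n_cases} cases: age from a normal truncated to
#' [18, 90], BMI and scheduled duration log-normal (duration floored at
#' 15 whole minutes), sex/ASA/procedure categorical, and 16 independent
#' Bernoulli comorbidity flags. Deterministic given \code{config$seed}.
#' PACU LOS is added separately by \code{\link{generate_pacu_los}}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame with one row per case.
#' @export
generate_cases <- function(config) {
  validate_cohort_config(config)
  n <- config$n_cases
  withr::with_seed(derive_seed(config$seed, "cases"), {
    sex <- ifelse(stats::runif(n) < config$sex_male_fraction, "male", "female")
    a_sd <- iqr_sd(config$age_iqr)
    plo <- stats::pnorm(18, config$age_median, a_sd)
    phi <- stats::pnorm(90, config$age_median, a_sd)
    age <- round(stats::qnorm(stats::runif(n, plo, phi), config$age_median, a_sd))
    bmi <- round(exp(stats::rnorm(n, log(config$bmi_median),
                                  iqr_sd(log(config$bmi_iqr)))), 1)
    dur <- pmax(15, round(exp(stats::rnorm(n, log(config$duration_median),
                                           iqr_sd(log(config$duration_iqr))))))
    asa <- sample(1:4, n, replace = TRUE, prob = config$asa_weights)
    proc <- sample(names(config$procedure_weights), n, replace = TRUE,
                   prob = config$procedure_weights)
    flags <- vapply(comorbidity_names(), function(nm)
      stats::runif(n) < config$comorbidity_prevalences[[nm]], logical(n))
    if (n == 1L) flags <- matrix(flags, nrow = 1,
                                 dimnames = list(NULL, comorbidity_names()))
    cases <- data.frame(
      case_id = sprintf("C%06d", seq_len(n)),
      age = age, sex = sex, bmi = bmi, asa_ps = asa, procedure = proc,
      scheduled_duration = dur,
      stringsAsFactors = FALSE
    )
    cbind(cases, as.data.frame(flags))
  })
}

# linear predictor of the log-LOS model, excluding the intercept
los_linear_predictor <- function(cases, config) {
  b <- config$effect_sizes
  b[["female_sex"]] * (cases$sex == "female") +
    b[["log_duration"]] * log(cases$scheduled_duration) +
    b[["bmi"]] * config_z(cases$bmi, config$bmi_median, config$bmi_iqr) +
    b[["age"]] * config_z(cases$age, config$age_median, config$age_iqr)
}

# Total log-scale spread implied by the prevalence target and the
# prolonged-stay median: with prevalence p and threshold T, the threshold
# sits at the (1-p) quantile of log-LOS and the prolonged median at the
# (1-p/2) quantile, which pins the normal scale. The short-stay median
# (~81 min under the defaults) then follows without a free parameter.
los_total_sd <- function(config) {
  p <- config$prolonged_prevalence_target
  z0 <- stats::qnorm(1 - p)
  z1 <- stats::qnorm(1 - p / 2)
  if (config$median_los_long <= config$prolonged_threshold)
    stop("median_los_long must exceed the prolonged threshold")
  (log(config$median_los_long) - log(config$prolonged_threshold)) / (z1 - z0)
}

los_residual_sd <- function(config, lp) {
  if (!is.null(config$los_log_sd)) return(config$los_log_sd)
  s2 <- los_total_sd(config)^2 - stats::var(lp)
  sqrt(max(s2, 1e-4))
}

#' Calibrate the log-LOS intercept against the prevalence target
#'
#' Numerical search over the intercept \code{b0} at fixed effect sizes and
#' residual sd: a calibration cohort of \code{n} cases is generated from a
#' dedicated substream of \code{config$seed}, and \code{b0} is solved so
#' that the fraction of simulated LOS at or above the prolonged threshold
#' equals the target. Because the fraction is monotone in \code{b0}, the
#' search reduces to an empirical-quantile solve:
#' \code{b0 = log(threshold) - Q_{1-p}(lp + eps)}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n calibration sample size (default 10000).
#' @return list with \code{b0}, \code{residual_sd} and the achieved
#'   calibration fraction.
#' @export
calibrate_los_intercept <- function(config, n = 10000) {
  cal_cfg <- config
  cal_cfg$n_cases <- as.integer(n)
  cal_cfg$seed <- derive_seed(config$seed, "calibration")
  cal <- generate_cases(cal_cfg)
  lp <- los_linear_predictor(cal, config)
  sd_resid <- los_residual_sd(config, lp)
  eps <- withr::with_seed(derive_seed(config$seed, "calibration") + 1L,
                          stats::rnorm(n, 0, sd_resid))
  tot <- lp + eps
  p <- config$prolonged_prevalence_target
  b0 <- log(config$prolonged_threshold) -
    unname(stats::quantile(tot, 1 - p, type = 7))
  list(b0 = b0, residual_sd = sd_resid,
       achieved = mean(b0 + tot >= log(config$prolonged_threshold)))
}

#' Generate PACU length of stay for synthetic cases
#'
#' \code{LOS = exp(b0 + b_f I(female) + b_d log(duration) + b_b z(BMI) +
#' b_a z(age) + eps)}, \code{eps} Gaussian, rounded to whole minutes
#' (floored at 1). The intercept comes from
#' \code{\link{calibrate_los_intercept}} so the marginal prolonged fraction
#' matches the configured target. Deterministic given \code{config$seed}.
#'
#' @param cases data.frame from \code{\link{generate_cases}}.
#' @param config a \code{\link{cohort_config}}.
#' @return numeric vector of minutes, aligned to \code{cases} rows.
#' @export
generate_pacu_los <- function(cases, config) {
  need <- c("sex", "scheduled_duration", "bmi", "age")
  miss <- setdiff(need, names(cases))
  if (length(miss)) stop("cases lack required fields: ", paste(miss, collapse = ", "))
  lp <- los_linear_predictor(cases, config)
  cal <- calibrate_los_intercept(config)
  eps <- withr::with_seed(derive_seed(config$seed, "los"),
                          stats::rnorm(nrow(cases), 0, cal$residual_sd))
  pmax(1, round(exp(cal$b0 + lp + eps)))
}

#' Partition cases into operating-room days
#'
#' Per-day case counts are drawn from \code{config$cases_per_day_weights}
#' (last day truncated to exhaust the cases). Each day gets one synthetic
#' surgeon and a calendar date; scheduled starts are assigned sequentially
#' from \code{config$day_start} using the scheduled durations plus
#' \code{config$turnover}. A day is flagged full when its last case's
#' scheduled end reaches \code{config$full_day_cutoff} (default 15:00).
#'
#' @param cases data.frame of cases (in generation order).
#' @param config a \code{\link{cohort_config}}.
#' @param start_date first calendar date to use.
#' @return list with \code{cases} (input plus \code{date}, \code{surgeon_id},
#'   \code{scheduled_start}) and \code{days} (one row per OR day:
#'   \code{day_id}, \code{date}, \code{surgeon_id}, \code{n_cases},
#'   \code{day_start}, \code{scheduled_end}, \code{full_day},
#'   \code{case_ids} joined with ";").
#' @export
assemble_or_days <- function(cases, config, start_date = as.Date("2023-01-02")) {
  n <- nrow(cases)
  if (n < 1L) stop("cases must be non-empty")
  counts <- withr::with_seed(derive_seed(config$seed, "days"), {
    k <- length(config$cases_per_day_weights)
    out <- integer(0); tot <- 0L
    while (tot < n) {
      out <- c(out, sample.int(k, 1L, prob = config$cases_per_day_weights))
      tot <- tot + out[length(out)]
    }
    out[length(out)] <- out[length(out)] - (tot - n)
    out[out > 0L]
  })
  day_of <- rep(seq_along(counts), counts)
  cases$date <- format(start_date + (day_of - 1L), "%Y-%m-%d")
  cases$surgeon_id <- sprintf("S%04d", day_of)
  start_min <- numeric(n)
  ends <- numeric(length(counts))
  pos <- 1L
  for (d in seq_along(counts)) {
    ix <- pos:(pos + counts[d] - 1L)
    durs <- cases$scheduled_duration[ix]
    starts <- config$day_start +
      cumsum(c(0, durs[-length(durs)] + config$turnover))
    start_min[ix] <- starts
    ends[d] <- starts[length(starts)] + durs[length(durs)]
    pos <- pos + counts[d]
  }
  cases$scheduled_start <- format_hm(start_min)
  days <- data.frame(
    day_id = sprintf("D%04d", seq_along(counts)),
    date = format(start_date + seq_along(counts) - 1L, "%Y-%m-%d"),
    surgeon_id = sprintf("S%04d", seq_along(counts)),
    n_cases = counts,
    day_start = format_hm(config$day_start),
    scheduled_end = format_hm(ends),
    full_day = ends >= config$full_day_cutoff,
    case_ids = vapply(split(cases$case_id, day_of), paste,
                      character(1), collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(cases = cases, days = days)
}

#' Generate a complete synthetic cohort
#'
#' Runs \code{\link{generate_cases}}, \code{\link{generate_pacu_los}},
#' prolonged labeling at the configured threshold, and
#' \code{\link{assemble_or_days}}. Fully deterministic given the config.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return object of class \code{synthetic_cohort}: list with \code{cases},
#'   \code{or_days} and \code{config}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  cases <- generate_cases(config)
  cases$pacu_los <- generate_pacu_los(cases, config)
  cases$prolonged <- label_prolonged(cases$pacu_los, config$prolonged_threshold)
  asm <- assemble_or_days(cases, config)
  structure(list(cases = asm$cases, or_days = asm$days, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic surgical cohort:", nrow(x$cases), "cases in",
      nrow(x$or_days), "OR days;",
      sum(x$cases$prolonged), sprintf("(%.2f%%)", 100 * mean(x$cases$prolonged)),
      "prolonged PACU stays\n")
  invisible(x)
}

#' Cohort CSV input/output
#'
#' One row per case; ISO-8601 dates, \code{HH:MM} clock times, logical
#' comorbidity flags. Column order is fixed so identical configurations
#' produce byte-identical files.
#'
#' @param cases data.frame of cases.
#' @param path file path.
#' @return \code{read_cohort_csv} returns the cases data.frame.
#' @export
write_cohort_csv <- function(cases, path) {
  cols <- c("case_id", "date", "surgeon_id", "scheduled_start",
            "scheduled_duration", "age", "sex", "bmi", "asa_ps", "procedure",
            comorbidity_names(), "pacu_los", "prolonged")
  cols <- intersect(cols, names(cases))
  utils::write.csv(cases[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c(comorbidity_names(), "prolonged"), names(df)))
    df[[nm]] <- as.logical(df[[nm]])
  df
}

#' @rdname write_cohort_csv
#' @param days OR-day index data.frame from \code{\link{assemble_or_days}}.
#' @export
write_or_day_csv <- function(days, path) {
  utils::write.csv(days, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_or_day_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$full_day <- as.logical(df$full_day)
  df
}
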