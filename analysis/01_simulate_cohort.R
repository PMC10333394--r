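#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic ambulatory-surgery cohort
# (10,928 cases) and summarize it against its configured targets.

suppressMessages(library(pacuseq))

dir.create("results", showWarnings = FALSE)
cfg <- cohort_config(n_cases = 10928, seed = 2023)
co <- generate_cohort(cfg)
print(co)

write_cohort_csv(co$cases, "results/cohort.csv")
write_or_day_csv(co$or_days, "results/or_days.csv")
write_cohort_config(cfg, "results/cohort_config.yaml")

cases <- co$cases
q <- function(x) sprintf("%g [%g, %g]", median(x),
                         quantile(x, 0.25), quantile(x, 0.75))
grp <- split(cases, cases$prolonged)
summary_tab <- data.frame(
  characteristic = c("n", "pacu_los_median_iqr", "age_median_iqr",
                     "male_sex_pct", "duration_median_iqr", "bmi_median_iqr",
                     "hypertension_pct", "osa_pct"),
  short_stay = c(nrow(grp$`FALSE`), q(grp$`FALSE`$pacu_los),
                 q(grp$`FALSE`$age),
                 sprintf("%.1f", 100 * mean(grp$`FALSE`$sex == "male")),
                 q(grp$`FALSE`$scheduled_duration), q(grp$`FALSE`$bmi),
                 sprintf("%.1f", 100 * mean(grp$`FALSE`$hypertension)),
                 sprintf("%.1f", 100 * mean(grp$`FALSE`$osa))),
  prolonged_stay = c(nrow(grp$`TRUE`), q(grp$`TRUE`$pacu_los),
                     q(grp$`TRUE`$age),
                     sprintf("%.1f", 100 * mean(grp$`TRUE`$sex == "male")),
                     q(grp$`TRUE`$scheduled_duration), q(grp$`TRUE`$bmi),
                     sprintf("%.1f", 100 * mean(grp$`TRUE`$hypertension)),
                     sprintf("%.1f", 100 * mean(grp$`TRUE`$osa)))
)
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)

cat("\nCohort characteristics by outcome (see results/cohort_summary.csv):\n")
print(summary_tab, row.names = FALSE)
cat(sprintf("\nOR days: %d total, %d (%.1f%%) full (scheduled past 15:00);",
            nrow(co$or_days), sum(co$or_days$full_day),
            100 * mean(co$or_days$full_day)),
    sprintf("cases per day median %g [%g, %g]\n",
            median(co$or_days$n_cases),
            quantile(co$or_days$n_cases, 0.25),
            quantile(co$or_days$n_cases, 0.75)))
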