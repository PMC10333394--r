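## Operating-room day reconstruction, sequential schedule simulation, and
## the historic-vs-resequenced after-hours comparison.
##
## Counterfactual assumption, stated explicitly: a case's PACU LOS (and its
## duration) are intrinsic to the case and travel with it when it is moved
## to a different slot in the day.

#' Reconstruct operating-room days from a case table
#'
#' Groups cases by (date, surgeon), orders each group by scheduled start,
#' and flags "full" days. By default a day is full when the scheduled end
#' of its last case (start + cumulative durations + turnover) reaches
#' \code{full_day_cutoff}; the alternative reading - last case *starts* at
#' or after the cutoff - is available via \code{rule}.
#'
#' @param cases data.frame with date, surgeon_id, scheduled_start,
#'   scheduled_duration (and case_id).
#' @param full_day_cutoff clock time, default \code{"15:00"}.
#' @param rule \code{"scheduled_end"} (default) or \code{"last_start"}.
#' @param turnover minutes between cases used for the scheduled-end check.
#' @param full_only if TRUE return only full days (non-full days are
#'   reported in the \code{n_partial} attribute).
#' @return list of \code{or_day} objects: \code{day_id}, \code{date},
#'   \code{surgeon_id}, \code{case_ids} (historic order), \code{day_start}
#'   (minutes), \code{full_day}.
#' @export
reconstruct_or_days <- function(cases, full_day_cutoff = "15:00",
                                rule = c("scheduled_end", "last_start"),
                                turnover = 0, full_only = FALSE) {
  rule <- match.arg(rule)
  cutoff <- parse_hm(full_day_cutoff)
  key <- paste(cases$date, cases$surgeon_id, sep = "|")
  days <- lapply(split(seq_len(nrow(cases)), key), function(ix) {
    start <- parse_hm(cases$scheduled_start[ix])
    o <- order(start)
    ix <- ix[o]; start <- start[o]
    dur <- cases$scheduled_duration[ix]
    end <- start + dur
    overlap <- which(start[-1] < end[-length(end)])
    if (length(overlap))
      stop("overlapping scheduled cases on ", cases$date[ix[1]], " / ",
           cases$surgeon_id[ix[1]], ": ",
           paste(cases$case_id[ix[overlap]], "overlaps",
                 cases$case_id[ix[overlap + 1L]], collapse = "; "))
    sched_end <- start[1] + sum(dur) + turnover * (length(dur) - 1L)
    full <- if (rule == "scheduled_end") sched_end >= cutoff
            else start[length(start)] >= cutoff
    structure(list(date = cases$date[ix[1]],
                   surgeon_id = cases$surgeon_id[ix[1]],
                   case_ids = cases$case_id[ix],
                   day_start = start[1],
                   full_day = full),
              class = "or_day")
  })
  days <- days[order(names(days))]
  for (i in seq_along(days)) days[[i]]$day_id <- sprintf("D%04d", i)
  n_partial <- sum(!vapply(days, `[[`, logical(1), "full_day"))
  if (full_only) days <- Filter(function(d) d$full_day, days)
  attr(days, "n_partial") <- n_partial
  days
}

#' Simulate surgery and PACU exit times for one case ordering
#'
#' Cases run sequentially from the day's first-case start time: each
#' surgery starts when the previous one ends (plus turnover), and each
#' patient leaves the PACU at surgery end + that case's PACU LOS. The LOS
#' moves with its case under reordering.
#'
#' @param day an \code{or_day}.
#' @param ordering permutation of \code{day$case_ids} (case ids, or
#'   integer positions relative to historic order).
#' @param durations named minutes per case id.
#' @param los named PACU LOS minutes per case id.
#' @param turnover minutes between consecutive cases.
#' @return object of class \code{schedule_result}: data.frame
#'   (\code{case_id}, \code{surgery_start}, \code{surgery_end},
#'   \code{pacu_exit}, in minutes) with attribute \code{latest_pacu_exit}.
#' @export
simulate_schedule <- function(day, ordering = day$case_ids, durations, los,
                              turnover = 0) {
  ids <- if (is.numeric(ordering)) day$case_ids[ordering] else ordering
  if (!setequal(ids, day$case_ids) || length(ids) != length(day$case_ids))
    stop("ordering is not a permutation of the day's cases")
  if (anyNA(los[ids]))
    stop("missing PACU LOS for case(s): ",
         paste(ids[is.na(los[ids])], collapse = ", "))
  dur <- unname(durations[ids])
  start <- day$day_start + cumsum(c(0, dur[-length(dur)] + turnover))
  end <- start + dur
  exit <- end + unname(los[ids])
  out <- data.frame(case_id = ids, surgery_start = start, surgery_end = end,
                    pacu_exit = exit, stringsAsFactors = FALSE)
  attr(out, "latest_pacu_exit") <- max(exit)
  class(out) <- c("schedule_result", "data.frame")
  out
}

#' Resequence a day's cases by predicted risk
#'
#' Sorts cases by predicted prolonged-stay risk, highest first; ties keep
#' their historic relative position (stable sort). A day counts as
#' "resequenced" only if the resulting order differs from the historic one
#' AND at least one of its cases is predicted prolonged at the
#' classification threshold.
#'
#' @param day an \code{or_day}.
#' @param risk named probability per case id.
#' @param threshold predicted-prolonged threshold, default 0.5.
#' @return integer permutation (positions into the historic order), with
#'   attribute \code{resequenced}.
#' @export
resequence_by_risk <- function(day, risk, threshold = 0.5) {
  r <- risk[day$case_ids]
  if (anyNA(r))
    stop("missing risk for case(s): ",
         paste(day$case_ids[is.na(r)], collapse = ", "))
  perm <- order(-r)  # stable: ties stay in historic order
  resequenced <- !identical(perm, seq_along(perm)) && any(r >= threshold)
  structure(perm, resequenced = resequenced)
}

#' After-hours occupancy flag
#'
#' TRUE iff any PACU exit in the schedule is strictly later than the
#' cutoff: an exit at exactly 19:00 does not count as after-hours.
#'
#' @param schedule a \code{schedule_result}.
#' @param cutoff clock time, default \code{"19:00"}.
#' @return logical.
#' @export
after_hours_flag <- function(schedule, cutoff = "19:00") {
  attr(schedule, "latest_pacu_exit") > parse_hm(cutoff)
}

#' Exhaustive-permutation scheduling oracle
#'
#' Evaluates every permutation of a (small) day and returns the minimum
#' achievable latest PACU exit with one optimal permutation. Scheduling
#' theory says ordering by PACU LOS descending (longest tail first) attains
#' this minimum; the oracle exists to verify that independently.
#'
#' @inheritParams simulate_schedule
#' @return list with \code{min_latest_exit} (minutes) and \code{ordering}
#'   (integer permutation).
#' @export
brute_force_min_latest_exit <- function(day, durations, los, turnover = 0) {
  k <- length(day$case_ids)
  if (k > 8L)
    stop("exhaustive search is guarded at 8 cases; ",
         "use the LOS-descending analytic ordering instead")
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- Inf; best_p <- seq_len(k)
  for (p in perms(seq_len(k))) {
    s <- simulate_schedule(day, p, durations, los, turnover)
    le <- attr(s, "latest_pacu_exit")
    if (le < best) { best <- le; best_p <- p }
  }
  list(min_latest_exit = best, ordering = best_p)
}

#' Chi-square comparison of after-hours frequencies
#'
#' Builds the 2x2 table (after-hours yes/no x historic/resequenced) from
#' per-arm counts over the same days and applies the chi-square test of
#' independence (1 df, no continuity correction by default; Yates available).
#'
#' @param historic_yes,resequenced_yes after-hours day counts per arm.
#' @param n_days total days per arm.
#' @param yates apply continuity correction.
#' @return list with \code{table}, \code{chi2_stat}, \code{p_value}.
#' @export
after_hours_test <- function(historic_yes, resequenced_yes, n_days,
                             yates = FALSE) {
  tab <- matrix(c(historic_yes, n_days - historic_yes,
                  resequenced_yes, n_days - resequenced_yes),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("historic", "resequenced"),
                                c("after_hours", "not_after_hours")))
  ht <- stats::chisq.test(tab, correct = yates)
  list(table = tab, chi2_stat = unname(ht$statistic),
       p_value = unname(ht$p.value))
}

#' Compare historic versus risk-resequenced schedules
#'
#' For each full OR day: simulate the historic order and the risk-descending
#' order (both rebuilt cumulatively from the day's first-case start with the
#' given turnover), flag after-hours PACU occupancy under each, and test the
#' frequency difference with \code{\link{after_hours_test}}.
#'
#' @param days list of \code{or_day} (typically
#'   \code{reconstruct_or_days(..., full_only = TRUE)}).
#' @param cases case table carrying case_id, scheduled_duration, pacu_los.
#' @param risk named probability per case id.
#' @param cutoff after-hours clock time, default \code{"19:00"}.
#' @param turnover minutes between cases.
#' @param threshold predicted-prolonged threshold for the resequenced-day
#'   count.
#' @param yates continuity correction for the chi-square test.
#' @return object of class \code{resequencing_report}.
#' @export
compare_schedules <- function(days, cases, risk, cutoff = "19:00",
                              turnover = 0, threshold = 0.5, yates = FALSE) {
  days <- Filter(function(d) d$full_day, days)
  if (length(days) == 0L) stop("no full OR days to compare")
  durations <- stats::setNames(cases$scheduled_duration, cases$case_id)
  los <- stats::setNames(cases$pacu_los, cases$case_id)
  per_day <- lapply(days, function(d) {
    hist_s <- simulate_schedule(d, d$case_ids, durations, los, turnover)
    perm <- resequence_by_risk(d, risk, threshold)
    rese_s <- simulate_schedule(d, perm, durations, los, turnover)
    data.frame(day_id = d$day_id, n_cases = length(d$case_ids),
               historic_after_hours = after_hours_flag(hist_s, cutoff),
               resequenced_after_hours = after_hours_flag(rese_s, cutoff),
               resequenced = attr(perm, "resequenced"),
               historic_latest_exit = attr(hist_s, "latest_pacu_exit"),
               resequenced_latest_exit = attr(rese_s, "latest_pacu_exit"),
               stringsAsFactors = FALSE)
  })
  per_day <- do.call(rbind, c(per_day, list(make.row.names = FALSE)))
  ht <- after_hours_test(sum(per_day$historic_after_hours),
                         sum(per_day$resequenced_after_hours),
                         nrow(per_day), yates = yates)
  structure(list(
    n_days = nrow(per_day),
    n_days_resequenced = sum(per_day$resequenced),
    n_cases_resequenced = sum(per_day$n_cases[per_day$resequenced]),
    per_day = per_day,
    table_2x2 = ht$table,
    chi2_stat = ht$chi2_stat,
    p_value = ht$p_value,
    cutoff = parse_hm(cutoff),
    threshold = threshold, yates = yates
  ), class = "resequencing_report")
}

#' @export
print.resequencing_report <- function(x, ...) {
  h <- sum(x$per_day$historic_after_hours)
  r <- sum(x$per_day$resequenced_after_hours)
  pct <- function(k) sprintf("%d (%.1f%%)", k, 100 * k / x$n_days)
  cat("Operating-room day resequencing summary\n")
  cat(sprintf("  %-46s %s\n", "Total number of OR days", x$n_days))
  cat(sprintf("  %-46s %s\n", "Cases per OR day, median [quartile]",
              sprintf("%g [%g, %g]",
                      stats::median(x$per_day$n_cases),
                      stats::quantile(x$per_day$n_cases, 0.25, type = 7),
                      stats::quantile(x$per_day$n_cases, 0.75, type = 7))))
  cat(sprintf("  %-46s %s (%d cases)\n", "OR days resequenced",
              pct(x$n_days_resequenced), x$n_cases_resequenced))
  cat(sprintf("  %-46s historic %s vs resequenced %s\n",
              paste0("Days with PACU occupancy past ", format_hm(x$cutoff)),
              pct(h), pct(r)))
  cat(sprintf("  Chi-square = %.2f, p %s\n", x$chi2_stat,
              if (x$p_value < 1e-4) "< 0.0001" else sprintf("= %.4f", x$p_value)))
  invisible(x)
}

#' Serialize a resequencing report as JSON
#' @param report a \code{resequencing_report}.
#' @param path file path.
#' @export
write_resequencing_report <- function(report, path) {
  x <- unclass(report)
  x$table_2x2 <- as.data.frame(as.table(x$table_2x2))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write per-day schedules as CSV
#'
#' One row per case per arm with surgery start/end and PACU exit as HH:MM.
#'
#' @inheritParams compare_schedules
#' @param path file path.
#' @export
write_schedule_csv <- function(days, cases, risk, path, cutoff = "19:00",
                               turnover = 0, threshold = 0.5) {
  durations <- stats::setNames(cases$scheduled_duration, cases$case_id)
  los <- stats::setNames(cases$pacu_los, cases$case_id)
  rows <- lapply(Filter(function(d) d$full_day, days), function(d) {
    out <- lapply(c(historic = FALSE, resequenced = TRUE), function(rs) {
      ord <- if (rs) resequence_by_risk(d, risk, threshold) else d$case_ids
      s <- simulate_schedule(d, ord, durations, los, turnover)
      data.frame(day_id = d$day_id, arm = if (rs) "resequenced" else "historic",
                 position = seq_len(nrow(s)), case_id = s$case_id,
                 surgery_start = format_hm(s$surgery_start),
                 surgery_end = format_hm(s$surgery_end),
                 pacu_exit = format_hm(s$pacu_exit),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
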