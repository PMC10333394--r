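# Independent oracles and tiny fixture builders used across the suite.

# AUC by exhaustive positive-negative pair counting (ties score 1/2).
auc_pairs <- function(scores, labels) {
  y <- as.integer(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Textbook chi-square statistic for a 2x2 table: sum (O-E)^2 / E.
chi2_textbook <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Hand-built case table with complete fields (deterministic).
make_toy_cases <- function(n = 6, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(
      case_id = sprintf("T%03d", seq_len(n)),
      date = rep("2023-05-01", n),
      surgeon_id = rep("S0001", n),
      scheduled_start = format_hm(450 + 130 * (seq_len(n) - 1)),
      scheduled_duration = sample(30:120, n, replace = TRUE),
      age = sample(20:80, n, replace = TRUE),
      sex = sample(c("female", "male"), n, replace = TRUE),
      bmi = round(runif(n, 19, 40), 1),
      asa_ps = sample(1:4, n, replace = TRUE),
      procedure = sample(c("ent", "general", "urology"), n, replace = TRUE),
      pacu_los = sample(40:250, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (nm in pacuseq:::comorbidity_names())
      df[[nm]] <- runif(n) < 0.2
    df$prolonged <- df$pacu_los >= 180
    df
  })
}

# Labeled feature matrix of two gaussian blobs with a configurable
# class imbalance; class 1 is shifted by `sep` along every coordinate.
make_toy_fm <- function(n0 = 100, n1 = 20, p = 3, sep = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n0 * p), n0, p),
               matrix(rnorm(n1 * p, mean = sep), n1, p))
    colnames(x) <- paste0("f", seq_len(p))
    feature_matrix(x, c(rep(0L, n0), rep(1L, n1)))
  })
}

# A single or_day object without going through the generator.
make_toy_day <- function(n_cases, day_start = 450, full_day = TRUE) {
  structure(list(day_id = "D0001", date = "2023-05-01", surgeon_id = "S0001",
                 case_ids = sprintf("T%03d", seq_len(n_cases)),
                 day_start = day_start, full_day = full_day),
            class = "or_day")
}
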