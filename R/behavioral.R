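#' Behavioural response metrics per trial
#'
#' Reading latency is the time from stimulus onset to speech onset;
#' C1/V/C2 articulation durations are copied through and the total response
#' duration is their sum. Trials with a missing speech onset are excluded
#' with a reason.
#'
#' @param trials data.frame of trial timings (as produced by
#'   [sample_behavior()] or a session event table)
#' @return a `behavior_table` data.frame: `trial_id`, `condition`,
#'   `latency_s`, `c1_dur_s`, `v_dur_s`, `c2_dur_s`, `total_response_s`;
#'   excluded trials listed in `attr(, "excluded")`
#' @export
response_metrics <- function(trials) {
  need <- c("trial_id", "condition", "stimulus_onset_s", "speech_onset_s",
            "c1_dur_s", "v_dur_s", "c2_dur_s")
  assert_that(all(need %in% names(trials)), "trial table missing columns: %s",
              paste(setdiff(need, names(trials)), collapse = ", "))
  bad <- is.na(trials$speech_onset_s)
  excluded <- data.frame(trial_id = trials$trial_id[bad],
                         reason = rep("missing speech onset", sum(bad)),
                         stringsAsFactors = FALSE)
  tr <- trials[!bad, , drop = FALSE]
  out <- data.frame(trial_id = tr$trial_id, condition = tr$condition,
                    latency_s = tr$speech_onset_s - tr$stimulus_onset_s,
                    c1_dur_s = tr$c1_dur_s, v_dur_s = tr$v_dur_s,
                    c2_dur_s = tr$c2_dur_s,
                    total_response_s = tr$c1_dur_s + tr$v_dur_s + tr$c2_dur_s,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("behavior_table", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' Condition-stratified summary of a behaviour table
#'
#' Mean and SEM (population-SD convention, see [mean_sem()]) per condition
#' and pooled, for each response measure; mirrors the descriptive-table
#' layout of the study paradigm.
#'
#' @param tbl a `behavior_table`
#' @return data.frame with one row per (condition, measure): mean and sem
#' @export
behavior_summary <- function(tbl) {
  measures <- c("latency_s", "c1_dur_s", "v_dur_s", "c2_dur_s", "total_response_s")
  groups <- c(setdiff(unique(tbl$condition), NA), "pooled")
  rows <- list()
  for (g in groups) {
    sub <- if (g == "pooled") tbl else tbl[tbl$condition == g, , drop = FALSE]
    for (m in measures) {
      ms <- mean_sem(sub[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = g, measure = m, n = nrow(sub),
        mean = ms[["mean"]], sem = ms[["sem"]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mean and standard error of the mean (population-SD convention)
#'
#' The SEM divides the population standard deviation (denominator n, not
#' n - 1) by sqrt(n). This is the convention that reproduces the study's
#' printed descriptives: ages (68, 82, 71, 60) give 70.25 +/- 3.94 under the
#' population-SD convention (the sample-SD convention would give 4.55).
#'
#' @param values numeric vector (at least one value)
#' @return named vector `c(mean = , sem = )`
#' @examples
#' mean_sem(c(68, 82, 71, 60))   # 70.25 +/- 3.94
#' mean_sem(c(8, 8, 8, 6))       # 7.50 +/- 0.43
#' @export
mean_sem <- function(values) {
  assert_that(length(values) >= 1 && !anyNA(values),
              "need at least one non-missing value")
  n <- length(values)
  m <- mean(values)
  sd_pop <- sqrt(mean((values - m)^2))
  c(mean = m, sem = sd_pop / sqrt(n))
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact two-sided p-value for n <= `exact_max` pairs via dynamic programming
#' over the (doubled, so tied midranks stay integral) signed-rank
#' distribution; normal approximation with tie and continuity corrections
#' above. Zero differences are dropped and reported. The statistic is the
#' rank sum of positive differences of `a - b`.
#'
#' @param a,b paired samples (equal length >= 5)
#' @param exact_max largest n for the exact distribution
#' @return list: `statistic` (V), `p`, `n_used`, `n_zero`, `degenerate`,
#'   `method`
#' @export
paired_wilcoxon <- function(a, b, exact_max = 25) {
  assert_that(length(a) == length(b), "samples must have equal length")
  assert_that(length(a) >= 5, "need at least 5 pairs")
  d <- a - b
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  if (length(d) == 0) {
    return(list(statistic = 0, p = 1, n_used = 0, n_zero = n_zero,
                degenerate = TRUE, method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  n <- length(d)
  if (n <= exact_max) {
    r2 <- round(2 * r)  # midranks doubled -> integers
    total <- sum(r2)
    # distribution of the doubled positive-rank sum over all 2^n sign
    # assignments: polynomial product of (1 + x^{r2_i})
    counts <- numeric(total + 1)
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- round(2 * V)
    p_le <- sum(probs[seq_len(v2 + 1)])
    p_ge <- sum(probs[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = V, p = p, n_used = n, n_zero = n_zero,
       degenerate = FALSE, method = method)
}
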