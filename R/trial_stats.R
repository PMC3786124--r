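#' @title Trial statistics
#' @description
#' The analysis stage of the trial: CONSORT flow accounting
#' (participation and retention rates), the pooled-variance baseline t
#' test, the 2 (arm) x 4 (timepoint) mixed repeated-measures ANOVA with
#' partial eta squared, and per-cell Bonferroni-adjusted confidence
#' intervals in the layout of the adherence-by-time summary table.
#' @name trial-stats
NULL

#' CONSORT flow counts
#'
#' @param approached Patients approached for recruitment.
#' @param consented Of those, patients consenting to participate.
#' @param completed_screening Patients completing the screening month.
#' @param continued Of those, patients willing to continue into the trial
#'   (the retention numerator).
#' @param randomized,completed_trial Optional downstream counts.
#' @return A list of class `"flow_counts"`.
#' @export
flow_counts <- function(approached, consented, completed_screening,
                        continued, randomized = NA_integer_,
                        completed_trial = NA_integer_) {
  stopifnot(approached >= 0, consented >= 0, completed_screening >= 0,
            continued >= 0, consented <= approached,
            continued <= completed_screening)
  structure(list(approached = approached, consented = consented,
                 completed_screening = completed_screening,
                 continued = continued, randomized = randomized,
                 completed_trial = completed_trial),
            class = "flow_counts")
}

#' Participation and retention rates
#'
#' Participation = consented / approached; retention = continued /
#' completed_screening (the subjects entering the retention-denominator
#' stage). Percentages are rounded to whole percent for display, matching
#' how trial reports print them.
#'
#' @param counts A [flow_counts()].
#' @return A tibble with one row per rate: `rate`, `numerator`,
#'   `denominator`, `proportion`, `percent` (display rounding).
#' @examples
#' flow_rates(flow_counts(approached = 55, consented = 41,
#'                        completed_screening = 34, continued = 31))
#' @export
flow_rates <- function(counts) {
  stopifnot(inherits(counts, "flow_counts"))
  if (counts$approached == 0 || counts$completed_screening == 0) {
    stop("zero denominator in flow counts", call. = FALSE)
  }
  p_part <- counts$consented / counts$approached
  p_ret <- counts$continued / counts$completed_screening
  tibble::tibble(
    rate = c("participation", "retention"),
    numerator = c(counts$consented, counts$continued),
    denominator = c(counts$approached, counts$completed_screening),
    proportion = c(p_part, p_ret),
    percent = round(100 * c(p_part, p_ret))
  )
}

#' Pooled-variance two-sample t test
#'
#' Independent-samples t test with the equal-variance (pooled) formulation
#' — `t = (mean_y - mean_x) / sqrt(s_p^2 (1/n_x + 1/n_y))` on
#' `n_x + n_y - 2` degrees of freedom — used to compare baseline age
#' between arms. Accepts raw values or `(mean, sd, n)` summaries, so
#' published summary tables can be re-tested directly.
#'
#' @param x,y Numeric vectors of observations, or lists
#'   `list(mean =, sd =, n =)`.
#' @return A list: `t`, `df`, `p` (two-sided), `mean_x`, `mean_y`. The
#'   statistic is antisymmetric under swapping `x` and `y`.
#' @examples
#' two_sample_t(list(mean = 42.44, sd = 12.04, n = 9),
#'              list(mean = 57.6, sd = 8.28, n = 10))
#' @export
two_sample_t <- function(x, y) {
  summarise_arg <- function(v) {
    if (is.list(v)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(v)), v$n >= 2)
      list(mean = v$mean, var = v$sd^2, n = v$n)
    } else {
      v <- v[!is.na(v)]
      if (length(v) < 2) stop("each group needs n >= 2", call. = FALSE)
      list(mean = mean(v), var = var(v), n = length(v))
    }
  }
  a <- summarise_arg(x)
  b <- summarise_arg(y)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  t <- (b$mean - a$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean_x = a$mean, mean_y = b$mean)
}

#' Partial eta squared from an F statistic
#'
#' The effect-size identity `partial eta^2 = F * df1 / (F * df1 + df2)`,
#' equivalently `SS_effect / (SS_effect + SS_error)`.
#'
#' @param f F ratio.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1]` (vectorised).
#' @examples
#' partial_eta_sq(11.74, 3, 48)
#' @export
partial_eta_sq <- function(f, df1, df2) {
  f * df1 / (f * df1 + df2)
}

# Complete-case restriction: keep patients with a non-missing outcome at
# every timepoint level present in the table.
complete_case_table <- function(table, outcome) {
  stopifnot(outcome %in% names(table))
  tp_levels <- if (is.factor(table$timepoint)) levels(factor(table$timepoint))
  else sort(unique(table$timepoint))
  table$timepoint <- factor(table$timepoint, tp_levels)
  y <- table[[outcome]]
  ok_pat <- tapply(!is.na(y), table$patient_id, sum)
  keep <- names(ok_pat)[ok_pat == length(tp_levels)]
  dropped <- setdiff(unique(table$patient_id), keep)
  if (length(dropped)) {
    warning(sprintf("excluding %d patient(s) without all %d timepoints for '%s': %s",
                    length(dropped), length(tp_levels), outcome,
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  out <- table[table$patient_id %in% keep & !is.na(y), ]
  out$arm <- factor(out$arm)
  out
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' Two-way ANOVA with a between-subjects factor (trial arm) and a
#' within-subjects factor (timepoint), the design used to analyse
#' adherence and resting BP across the four monthly evaluations. The
#' decomposition is the classical univariate split-plot one:
#' `SS_group` tested against `MS_subject(group)`; `SS_time` and
#' `SS_group_x_time` tested against the within-subject residual. Analyses
#' are complete-case — patients missing the outcome at any timepoint are
#' excluded with a warning — and, by default, no sphericity correction is
#' applied (integer dfs); set `sphericity_correction = TRUE` in the config
#' for Greenhouse-Geisser-adjusted p-values.
#'
#' @param table A long trial table ([read_trial_table()] layout): one row
#'   per (patient, timepoint), arm constant within patient.
#' @param outcome One of `"adherence"`, `"sbp"`, `"dbp"` (any numeric
#'   column).
#' @param config A [study_config()].
#' @return A tibble with rows `GROUP`, `TIME`, `GROUP_X_TIME`: `effect`,
#'   `ss`, `df1`, `df2`, `ms`, `F`, `p`, `partial_eta_sq` (the identity
#'   `F*df1/(F*df1 + df2)` holds exactly). Attributes: `"ss"` (full
#'   sums-of-squares decomposition including subject and residual strata),
#'   `"n_complete"` (complete cases per arm), and `"gg_epsilon"` when the
#'   correction is enabled.
#' @examples
#' sim <- simulate_trial(n_per_arm = 5, seed = 42)
#' rm_anova(sim$trial, "adherence")
#' @export
rm_anova <- function(table, outcome = c("adherence", "sbp", "dbp"),
                     config = study_config()) {
  outcome <- outcome[1]
  config <- as_study_config(config)
  tab <- complete_case_table(table, outcome)
  y <- tab[[outcome]]
  pid <- factor(tab$patient_id)
  arm <- tab$arm
  tp <- factor(tab$timepoint)

  a <- nlevels(arm)
  t_lv <- nlevels(tp)
  arm_of_pid <- tapply(as.character(arm), pid, `[`, 1)
  n_i <- table(factor(arm_of_pid, levels(arm)))
  N <- sum(n_i)
  if (a < 2 || any(n_i < 2)) {
    stop("need at least 2 patients per arm with complete data", call. = FALSE)
  }

  grand <- mean(y)
  subj_mean <- tapply(y, pid, mean)
  arm_mean <- tapply(y, arm, mean)
  time_mean <- tapply(y, tp, mean)
  cell_mean <- tapply(y, list(arm, tp), mean)

  ss_total <- sum((y - grand)^2)
  ss_between <- t_lv * sum((subj_mean - grand)^2)
  ss_group <- t_lv * sum(n_i * (arm_mean - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- N * sum((time_mean - grand)^2)
  ss_cells <- sum(matrix(n_i, a, t_lv) * (cell_mean - grand)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_resid <- ss_total - ss_between - ss_time - ss_int

  df_group <- a - 1
  df_subj <- N - a
  df_time <- t_lv - 1
  df_int <- df_group * df_time
  df_resid <- df_subj * df_time

  ms_group <- ss_group / df_group
  ms_subj <- ss_subj / df_subj
  ms_time <- ss_time / df_time
  ms_int <- ss_int / df_int
  ms_resid <- ss_resid / df_resid

  f <- c(GROUP = ms_group / ms_subj,
         TIME = ms_time / ms_resid,
         GROUP_X_TIME = ms_int / ms_resid)
  df1 <- c(df_group, df_time, df_int)
  df2 <- c(df_subj, df_resid, df_resid)

  eps <- NA_real_
  if (isTRUE(config$sphericity_correction)) {
    eps <- gg_epsilon(y, pid, arm, tp)
    p <- c(pf(f[1], df1[1], df2[1], lower.tail = FALSE),
           pf(f[2], df1[2] * eps, df2[2] * eps, lower.tail = FALSE),
           pf(f[3], df1[3] * eps, df2[3] * eps, lower.tail = FALSE))
  } else {
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }

  out <- tibble::tibble(
    effect = c("GROUP", "TIME", "GROUP_X_TIME"),
    ss = c(ss_group, ss_time, ss_int),
    df1 = df1, df2 = df2,
    ms = c(ms_group, ms_time, ms_int),
    F = unname(f), p = unname(p),
    partial_eta_sq = partial_eta_sq(unname(f), df1, df2)
  )
  attr(out, "ss") <- c(group = ss_group, subject = ss_subj, time = ss_time,
                       interaction = ss_int, residual = ss_resid,
                       total = ss_total)
  attr(out, "n_complete") <- as.integer(n_i)
  names(attr(out, "n_complete")) <- names(n_i)
  if (isTRUE(config$sphericity_correction)) attr(out, "gg_epsilon") <- eps
  out
}

# Greenhouse-Geisser epsilon from the pooled within-arm covariance of the
# timepoint profiles.
gg_epsilon <- function(y, pid, arm, tp) {
  wide <- tapply(y, list(pid, tp), mean)
  arm_of_pid <- tapply(as.character(arm), pid, `[`, 1)[rownames(wide)]
  centred <- do.call(rbind, lapply(split(as.data.frame(wide), arm_of_pid),
                                   function(m) scale(m, scale = FALSE)))
  S <- crossprod(as.matrix(centred)) / (nrow(wide) - length(unique(arm_of_pid)))
  t_lv <- ncol(S)
  C <- S - outer(rowMeans(S), rep(1, t_lv)) -
    outer(rep(1, t_lv), colMeans(S)) + mean(S)
  sum(diag(C))^2 / ((t_lv - 1) * sum(C^2))
}

#' Bonferroni-adjusted cell confidence intervals
#'
#' Per (arm, timepoint) cell: `mean +/- t(1 - alpha/(2k), n_cell - 1) * SE`
#' where `SE = sd / sqrt(n_cell)` and `k` is the number of post-hoc
#' comparisons (default the number of timepoints, 4, giving per-comparison
#' alpha 0.0125 at alpha = .05). Two cells are declared different when
#' their adjusted intervals are disjoint.
#'
#' @param table Long trial table.
#' @param outcome Outcome column name.
#' @param k Number of comparisons adjusted for; default
#'   `config$n_timepoints`.
#' @param config A [study_config()].
#' @param complete_cases Restrict to complete cases first (as the ANOVA
#'   does)? Default `TRUE`.
#' @return A tibble per cell: `arm`, `timepoint`, `n`, `mean`, `se`,
#'   `ci_lo`, `ci_hi` (interval `NA` when `n < 2`).
#' @export
bonferroni_cis <- function(table, outcome = c("adherence", "sbp", "dbp"),
                           k = NULL, config = study_config(),
                           complete_cases = TRUE) {
  outcome <- outcome[1]
  config <- as_study_config(config)
  k <- k %||% config$n_timepoints
  stopifnot(k >= 1)
  tab <- if (complete_cases) complete_case_table(table, outcome) else table
  cells <- dplyr::summarise(
    dplyr::group_by(tab, .data$arm, .data$timepoint),
    n = sum(!is.na(.data[[outcome]])),
    mean = mean(.data[[outcome]], na.rm = TRUE),
    se = stats::sd(.data[[outcome]], na.rm = TRUE) / sqrt(.data$n[1]),
    .groups = "drop")
  crit <- qt(1 - config$alpha / (2 * k), df = cells$n - 1)
  cells$ci_lo <- ifelse(cells$n >= 2, cells$mean - crit * cells$se, NA_real_)
  cells$ci_hi <- ifelse(cells$n >= 2, cells$mean + crit * cells$se, NA_real_)
  cells$se[cells$n < 2] <- NA_real_
  cells
}

#' Adherence-by-time summary grid
#'
#' The trial's summary-table layout: per arm x timepoint cell the mean,
#' standard error, and Bonferroni-adjusted 95% confidence interval of the
#' outcome, in wide format with one row per timepoint.
#'
#' @inheritParams bonferroni_cis
#' @return A tibble with one row per timepoint and, per arm, columns
#'   `<arm>_mean`, `<arm>_se`, `<arm>_ci_lo`, `<arm>_ci_hi`. The long cell
#'   table from [bonferroni_cis()] is attached as attribute `"cells"`.
#' @export
table2_summary <- function(table, outcome = c("adherence", "sbp", "dbp"),
                           k = NULL, config = study_config()) {
  outcome <- outcome[1]
  cells <- bonferroni_cis(table, outcome, k = k, config = config)
  long <- tidyr::pivot_longer(cells, c("mean", "se", "ci_lo", "ci_hi"),
                              names_to = "stat", values_to = "value")
  long$col <- paste(long$arm, long$stat, sep = "_")
  wide <- tidyr::pivot_wider(long[c("timepoint", "col", "value")],
                             names_from = "col", values_from = "value")
  attr(wide, "cells") <- cells
  wide
}
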