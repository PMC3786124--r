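# Independent oracles, deliberately implemented apart from the package
# code paths they check.

# Per-dose credit, direct restatement of the scoring rule.
oracle_credit <- function(delay, full = 90, half = 180) {
  if (is.na(delay)) return(0)
  d <- abs(delay)
  if (d <= full) 1 else if (d <= half) 0.5 else 0
}

# Exhaustive-search optimal assignment of openings to doses (injective,
# within the half window), maximizing the total credit. Times in minutes.
oracle_optimal_total <- function(sched_min, open_min, full = 90, half = 180) {
  n_o <- length(open_min)
  rec <- function(i, used) {
    if (i > length(sched_min)) return(0)
    best <- rec(i + 1, used) # leave dose i unmatched
    for (j in seq_len(n_o)) {
      if (!used[j]) {
        s <- oracle_credit(open_min[j] - sched_min[i], full, half)
        if (s > 0) {
          used[j] <- TRUE
          best <- max(best, s + rec(i + 1, used))
          used[j] <- FALSE
        }
      }
    }
    best
  }
  rec(1, rep(FALSE, n_o))
}

# Greedy total credit through the package, on minute offsets.
greedy_total <- function(sched_min, open_min, config = study_config()) {
  origin <- ts_utc("2013-02-01 00:00")
  de <- match_openings(origin + sched_min * 60, origin + open_min * 60, config)
  sum(score_dose(de$delay_min, config))
}

# A day is unambiguous when dose half-windows are pairwise disjoint and
# no dose window holds more than one opening: the regime in which each
# compartment sees at most one candidate opening.
unambiguous_day <- function(sched_min, open_min, half = 180) {
  if (length(sched_min) > 1 && min(diff(sort(sched_min))) <= 2 * half) {
    return(FALSE)
  }
  all(vapply(sched_min,
             function(s) sum(abs(open_min - s) <= half) <= 1, logical(1)))
}

# Split-plot ANOVA oracle via stats::aov with an Error() stratum.
aov_oracle <- function(tab, outcome) {
  d <- data.frame(y = tab[[outcome]], pid = factor(tab$patient_id),
                  arm = factor(tab$arm), tp = factor(tab$timepoint))
  fit <- summary(stats::aov(y ~ arm * tp + Error(pid), data = d))
  between <- fit[["Error: pid"]][[1]]
  within <- fit[["Error: Within"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  list(
    ss = c(group = between["arm", "Sum Sq"],
           subject = between["Residuals", "Sum Sq"],
           time = within["tp", "Sum Sq"],
           interaction = within["arm:tp", "Sum Sq"],
           residual = within["Residuals", "Sum Sq"]),
    f = c(GROUP = between["arm", "F value"],
          TIME = within["tp", "F value"],
          GROUP_X_TIME = within["arm:tp", "F value"]),
    df = c(group1 = between["arm", "Df"], group2 = between["Residuals", "Df"],
           within1 = within["tp", "Df"], resid = within["Residuals", "Df"])
  )
}
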