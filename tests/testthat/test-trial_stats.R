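test_that("flow rates divide the configured numerators and denominators", {
  fr <- flow_rates(flow_counts(approached = 55, consented = 41,
                               completed_screening = 34, continued = 31))
  expect_equal(fr$proportion, c(41 / 55, 31 / 34))
  expect_equal(fr$percent, c(75, 91))
  fr0 <- flow_rates(flow_counts(10, 0, 5, 0))
  expect_equal(fr0$percent, c(0, 0))
  expect_error(flow_rates(flow_counts(0, 0, 5, 5)), "denominator")
  expect_error(flow_counts(10, 11, 5, 5))  # stage exceeding its predecessor
})

test_that("the pooled t test matches stats::t.test and the summary formula", {
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
      y <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
      got <- two_sample_t(x, y)
      ref <- stats::t.test(y, x, var.equal = TRUE)
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$df, unname(ref$parameter))
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
      # summary input agrees with raw input
      gs <- two_sample_t(list(mean = mean(x), sd = sd(x), n = length(x)),
                         list(mean = mean(y), sd = sd(y), n = length(y)))
      expect_equal(gs$t, got$t, tolerance = 1e-12)
      # antisymmetry under group swap
      expect_equal(two_sample_t(y, x)$t, -got$t, tolerance = 1e-12)
    }
  })
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("rm_anova matches the split-plot aov oracle across shapes", {
  withr::with_seed(31, {
    for (na in 2:3) for (nb in 2:3) for (t_lv in 2:3) {
      for (rep in 1:5) {
        tab <- trial_table(matrix(rnorm(na * t_lv), na),
                           matrix(rnorm(nb * t_lv), nb))
        got <- rm_anova(tab, "adherence")
        ref <- aov_oracle(tab, "adherence")
        expect_equal(attr(got, "ss")[names(ref$ss)], ref$ss,
                     tolerance = 1e-9)
        expect_equal(got$F, unname(ref$f), tolerance = 1e-9)
        expect_equal(got$df1, unname(c(ref$df["group1"], ref$df["within1"],
                                       ref$df["group1"] * ref$df["within1"])))
        expect_equal(got$df2[1], unname(ref$df["group2"]))
        expect_equal(got$df2[2], unname(ref$df["resid"]))
      }
    }
  })
})

test_that("toy 2x2 sums of squares match the hand-computed decomposition", {
  # MHEALTH subjects (1,2),(1,2); SC subjects (2,4),(2,4): by hand,
  # SS_group = 4.5, SS_time = 4.5, SS_interaction = 0.5, residual 0
  tab <- trial_table(matrix(c(1, 2, 1, 2), 2, byrow = TRUE),
                     matrix(c(2, 4, 2, 4), 2, byrow = TRUE))
  ss <- attr(rm_anova(tab, "adherence"), "ss")
  expect_equal(unname(ss["group"]), 4.5)
  expect_equal(unname(ss["time"]), 4.5)
  expect_equal(unname(ss["interaction"]), 0.5)
  expect_equal(unname(ss["subject"]), 0)
  expect_equal(unname(ss["residual"]), 0)
})

test_that("sums of squares are additive and the effect-size identity holds", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      tab <- trial_table(matrix(rnorm(12), 3), matrix(rnorm(16), 4))
      res <- rm_anova(tab, "adherence")
      ss <- attr(res, "ss")
      expect_equal(unname(ss["total"]),
                   unname(sum(ss[c("group", "subject", "time",
                                   "interaction", "residual")])),
                   tolerance = 1e-9)
      expect_equal(res$partial_eta_sq,
                   res$F * res$df1 / (res$F * res$df1 + res$df2),
                   tolerance = 1e-12)
    }
  })
  # all cells equal -> every effect SS is 0
  flat <- trial_table(matrix(5, 3, 4), matrix(5, 3, 4))
  ss <- attr(rm_anova(flat, "adherence"), "ss")
  expect_equal(unname(ss[c("group", "time", "interaction")]), c(0, 0, 0))
})

test_that("incomplete patients are excluded with a warning; small arms error", {
  tab <- trial_table(matrix(rnorm(12), 3), matrix(rnorm(12), 3))
  tab$adherence[tab$patient_id == "MHEALTH01" & tab$timepoint == "M3"] <- NA
  expect_warning(res <- rm_anova(tab, "adherence"), "MHEALTH01")
  expect_equal(sum(attr(res, "n_complete")), 5)
  tiny <- trial_table(matrix(rnorm(4), 1), matrix(rnorm(12), 3))
  expect_error(suppressWarnings(rm_anova(tiny, "adherence")), "2 patients")
})

test_that("Bonferroni cells use alpha/k and contain the unadjusted interval", {
  withr::with_seed(51, {
    tab <- trial_table(matrix(rnorm(40, 0.8, 0.1), 10),
                       matrix(rnorm(40, 0.5, 0.1), 10))
  })
  adj <- bonferroni_cis(tab, "adherence", k = 4)
  una <- bonferroni_cis(tab, "adherence", k = 1)
  expect_true(all(adj$ci_lo < una$ci_lo & adj$ci_hi > una$ci_hi))
  # critical quantile uses alpha/(2k) = 0.00625 per tail
  cell <- adj[adj$arm == "MHEALTH" & adj$timepoint == "BASELINE", ]
  expect_equal(cell$ci_hi - cell$mean,
               qt(1 - 0.05 / 8, df = 9) * cell$se, tolerance = 1e-12)
  # degenerate: constant outcome gives SE 0 and a point interval
  const <- trial_table(matrix(1, 3, 4), matrix(1, 3, 4))
  cc <- bonferroni_cis(const, "adherence")
  expect_equal(cc$se, rep(0, 8))
  expect_equal(cc$ci_lo, cc$ci_hi)
})

test_that("table2_summary lays out mean, SE and adjusted CI per arm and time", {
  sim <- simulate_trial(n_per_arm = 5, seed = 8)
  grid <- table2_summary(sim$trial, "adherence")
  expect_equal(nrow(grid), 4)
  expect_setequal(setdiff(names(grid), "timepoint"),
                  as.vector(outer(c("MHEALTH", "SC"),
                                  c("mean", "se", "ci_lo", "ci_hi"),
                                  paste, sep = "_")))
  cells <- attr(grid, "cells")
  expect_equal(grid$MHEALTH_mean,
               cells$mean[cells$arm == "MHEALTH"])
  # single-arm input: half grid, no comparisons
  half <- table2_summary(sim$trial[sim$trial$arm == "SC", ], "adherence")
  expect_false(any(grepl("MHEALTH", names(half))))
})
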