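# Per-dyad transition tables, the closed-form saturated logit, aggregation,
# and group comparison.

test_that("transition_table counts transitions against the joint prior state", {
  # constant (1,1) pair: every transition lands in one cell
  p <- dyad_pair("c", rep(1, 5), rep(1, 5))
  tb <- transition_table(p, target = "b")
  expect_equal(unclass(tb)["a1_b1", "yes"], 4L)
  expect_equal(sum(tb), 4L)

  # hand-built 6-interval pair vs brute-force classification of transitions
  p2 <- dyad_pair("h", c(1, 0, 1, 1, 0, 0), c(0, 1, 1, 0, 0, 1))
  tb2 <- transition_table(p2, target = "b")
  brute <- matrix(0L, 4, 2)
  for (t in 2:6) {
    r <- if (p2$seq_a[t - 1] == 1 && p2$seq_b[t - 1] == 1) 1
         else if (p2$seq_a[t - 1] == 1) 2
         else if (p2$seq_b[t - 1] == 1) 3 else 4
    cl <- if (p2$seq_b[t] == 1) 1 else 2
    brute[r, cl] <- brute[r, cl] + 1L
  }
  expect_equal(matrix(unclass(tb2), 4, 2), brute)
  expect_equal(sum(tb2), 5L)

  # random pairs, exhaustive transition classification (T <= 8)
  set.seed(5)
  for (i in 1:15) {
    pr <- random_pair("r", sample(2:8, 1))
    for (tg in c("a", "b")) {
      tb3 <- transition_table(pr, target = tg)
      expect_equal(sum(tb3), length(pr$seq_a) - 1L)
      out <- if (tg == "b") pr$seq_b else pr$seq_a
      expect_equal(sum(unclass(tb3)[, "yes"]), sum(out[-1]))
    }
  }
})

test_that("the closed-form saturated logit reproduces the worked single case", {
  tb <- as_transition_table(couple129_counts, target = "b", dyad_id = "129")
  expect_equal(sum(tb), 47)   # 27 + 2 + 4 + 14 transitions of a 48-interval dyad
  fit <- fit_saturated_logit(tb, constant = 0.5)
  expect_equal(unname(round(coef(fit), 2)), c(0.33, 0.92, 0.50, -0.10))
  expect_equal(unname(round(exp(coef(fit)), 2)), c(1.39, 2.52, 1.65, 0.91))
})

test_that("saturated logit equals IRLS logistic regression on positive tables", {
  set.seed(11)
  for (i in 1:25) {
    counts <- matrix(sample(1:30, 8, replace = TRUE), 4, 2)
    for (tg in c("a", "b")) {
      tb <- as_transition_table(counts, target = tg)
      closed <- coef(fit_saturated_logit(tb, constant = 0))
      expect_equal(closed, irls_oracle(counts, tg), tolerance = 1e-8)
    }
  }
})

test_that("saturated logit symmetry, linearity and zero-cell handling", {
  # equal yes/no counts in every row: all contrasts zero
  tb <- as_transition_table(matrix(c(5, 5, 2, 2, 9, 9, 4, 4), 4, 2, byrow = TRUE))
  co <- coef(fit_saturated_logit(tb, 0))
  expect_equal(unname(co[2:4]), c(0, 0, 0))

  # adding delta to all row log-odds shifts b0 only: scale yes-counts by e^d
  tb1 <- as_transition_table(matrix(c(4, 8, 2, 6, 10, 2, 3, 3), 4, 2, byrow = TRUE))
  d <- 0.7
  counts2 <- cbind(unclass(tb1)[, 1] * exp(d), unclass(tb1)[, 2])
  tb2 <- as_transition_table(counts2)
  c1 <- coef(fit_saturated_logit(tb1, 0))
  c2 <- coef(fit_saturated_logit(tb2, 0))
  expect_equal(c2[1] - c1[1], c(b0 = d), tolerance = 1e-12)
  expect_equal(c2[2:4], c1[2:4], tolerance = 1e-12)

  # zero cell with constant 0 errors, with 0.5 it does not
  tbz <- as_transition_table(c(3, 0, 1, 1, 2, 2, 1, 1))
  expect_error(fit_saturated_logit(tbz, 0), "zero-frequency")
  expect_silent(fit_saturated_logit(tbz, 0.5))
})

test_that("aggregation averages, tests, and flags degenerate spread", {
  # identical dyads: mean equals the single-dyad fit, SD = 0 flagged
  p <- dyad_pair("1", c(1, 0, 1, 1, 0, 1), c(0, 1, 1, 0, 1, 1))
  ds <- dyad_dataset(list(p, dyad_pair("2", p$seq_a, p$seq_b),
                          dyad_pair("3", p$seq_a, p$seq_b)))
  expect_warning(agg <- aggregate_logit(ds, target = "b"), "zero between-dyad SD")
  single <- coef(fit_saturated_logit(transition_table(p, "b"), 0.5))
  expect_equal(agg$summary$mean, unname(single))
  expect_true(all(is.na(agg$summary$t)))

  # t statistic matches stats::t.test on the per-dyad coefficients
  ds2 <- random_dataset(12, 10, seed = 21)
  agg2 <- aggregate_logit(ds2, target = "b")
  ref <- t.test(agg2$per_dyad[, "b_actor"])
  expect_equal(agg2$summary$t[2], unname(ref$statistic))
  expect_equal(agg2$summary$p[2], ref$p.value)
  expect_equal(agg2$summary$odds_ratio, exp(agg2$summary$mean))

  # drop policy excludes dyads with empty cells (long sequences so that
  # complete tables exist)
  lp <- logit_params(0.2, 0.4, 0.3, 0)
  ds3 <- simulate_logit_apim(lp, lp, 12, 48, seed = 8)
  agg3 <- aggregate_logit(ds3, target = "b", policy = "drop")
  expect_equal(agg3$n_dyads + agg3$n_excluded, 12)
  expect_equal(agg3$constant, 0)
})

test_that("aggregation is consistent and conservatively attenuated", {
  # The across-dyad mean estimates the expectation of the per-dyad estimator;
  # relative to the generating coefficients that expectation is mildly
  # attenuated toward zero (the price of the 0.5 constant on short tables).
  truth <- c(0.2, 0.5, 0.3, 0)
  lp <- logit_params(truth[1], truth[2], truth[3], truth[4])
  ds <- simulate_logit_apim(lp, lp, 300, 48, seed = 42)
  agg <- aggregate_logit(ds, target = "b", constant = 0.5)
  big <- aggregate_logit(simulate_logit_apim(lp, lp, 2000, 48, seed = 43),
                         target = "b", constant = 0.5)
  estimand <- big$summary$mean
  half <- qt(0.975, agg$n_dyads - 1) * agg$summary$sd / sqrt(agg$n_dyads)
  mc <- 3 * big$summary$sd / sqrt(big$n_dyads)
  expect_true(all(abs(agg$summary$mean - estimand) <= half + mc))
  # attenuation stays small and never flips a sign
  expect_true(all(abs(agg$summary$mean - truth) <= 0.1))
  expect_lte(estimand[2], truth[2])
})

test_that("apim_summary runs both outcomes and is symmetric under relabeling", {
  ds <- random_dataset(10, 12, seed = 31)
  ap <- apim_summary(ds)
  expect_equal(nrow(ap$outcome_a$summary), 4)
  expect_equal(nrow(ap$outcome_b$summary), 4)

  # swapping the partners swaps the two outcome summaries exactly
  ds_sw <- dyad_dataset(lapply(ds$pairs, function(p)
    dyad_pair(p$dyad_id, p$seq_b, p$seq_a)))
  ap_sw <- apim_summary(ds_sw)
  expect_equal(ap_sw$outcome_a$summary, ap$outcome_b$summary)
  expect_equal(ap_sw$outcome_b$summary, ap$outcome_a$summary)
  expect_equal(ap_sw$difference$mean_diff, -ap$difference$mean_diff)

  # symmetric generating process: between-outcome differences within 3 SE of 0
  lp <- logit_params(0.2, 0.6, 0.3, 0)
  sym <- simulate_logit_apim(lp, lp, 200, 30, seed = 42)
  ap2 <- apim_summary(sym)
  se <- abs(ap2$difference$mean_diff / ap2$difference$t)
  expect_true(all(abs(ap2$difference$mean_diff) <= 3 * se))
})

test_that("group comparison: identity, exact shifts, and sign recovery", {
  ds <- random_dataset(8, 10, seed = 41)
  agg <- aggregate_logit(ds, "b")
  same <- compare_logit_groups(agg, agg)
  expect_equal(same$diff, rep(0, 4))
  expect_equal(same$p, rep(1, 4), tolerance = 1e-12)

  # constant shift in b0 recovered exactly
  shifted <- agg$per_dyad
  shifted[, "b0"] <- shifted[, "b0"] + 0.4
  cmp <- compare_logit_groups(shifted, agg$per_dyad)
  expect_equal(cmp$diff[1], 0.4, tolerance = 1e-12)

  # opposite-sign interactions detected across two simulated groups
  lp_neg <- logit_params(0.2, 0.6, 0.4, -0.1)
  lp_pos <- logit_params(0.2, 0.6, 0.4, 0.25)
  g1 <- aggregate_logit(simulate_logit_apim(lp_neg, lp_neg, 32, 48, seed = 42), "b")
  g2 <- aggregate_logit(simulate_logit_apim(lp_pos, lp_pos, 32, 48, seed = 43), "b")
  cmp2 <- compare_logit_groups(g1, g2)
  expect_lt(cmp2$diff[4], 0)
})
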