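test_that("donor aggregation averages inserts and demands complete data", {
  tab <- data.frame(donor = c(1, 1, 1, 2),
                    condition = "control",
                    Je0 = c(0.10, 0.12, 0.14, 0.2),
                    eta0 = c(100, 120, 140, 200))
  agg <- aggregate_donor(tab)
  expect_equal(agg$Je0[agg$donor == 1], 0.12)
  expect_equal(agg$n_inserts, c(3L, 1L))
  # a single-insert donor equals that insert
  expect_equal(agg$Je0[agg$donor == 2], 0.2)
  tab$Je0[1] <- -1
  expect_error(aggregate_donor(tab), "nonpositive")
})

test_that("pipeline aggregates inserts before forming donor ratios", {
  # fixture where aggregate-then-ratio and ratio-then-aggregate differ:
  # donor 1 insert values a = (1, 4), b = (2, 2)
  tab <- data.frame(donor = c(1, 1, 1, 1, 2, 2, 2, 2),
                    condition = rep(c("control", "il13"), each = 2, times = 2),
                    insert = rep(1:2, 4),
                    Je0 = c(1, 4, 2, 2, 1, 1, 1, 1),
                    eta0 = 1)
  mean_then_ratio <- 2 / 2.5          # mean(b)/mean(a) for donor 1
  ratio_then_mean <- mean(c(2 / 1, 2 / 4))
  expect_false(isTRUE(all.equal(mean_then_ratio, ratio_then_mean)))
  cmp <- suppressWarnings(compare_conditions(tab, plan = list(c("control", "il13"))))
  gm_expected <- exp(mean(log(c(mean_then_ratio, 1))))
  expect_equal(cmp[[1]]$Je0$gm_ratio, gm_expected, tolerance = 1e-12)
})

test_that("ratio paired t test reproduces the frozen worked example", {
  res <- ratio_paired_ttest(c(1, 1, 1, 1), c(2.0, 2.2, 1.8, 2.1))
  # hand computation of the paired t on logs: mean log ratio 0.70283,
  # sd 0.08601, t = 16.344
  expect_equal(res$t, 16.344, tolerance = 1e-3)
  expect_identical(res$df, 3L)
  expect_equal(res$gm_ratio, exp(mean(log(c(2.0, 2.2, 1.8, 2.1)))),
               tolerance = 1e-12)
})

test_that("ratio paired t test equals the log-paired oracle on random samples", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(3:8, 1)
    a <- rlnorm(n, 0, 0.5)
    b <- a * rlnorm(n, 0.2, 0.3)
    res <- ratio_paired_ttest(a, b)
    oracle <- t.test(log(b), log(a), paired = TRUE)
    expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("ratio paired t test is scale invariant and handles degeneracy", {
  a <- c(1.2, 0.8, 1.5, 1.1)
  b <- c(2.3, 1.9, 2.8, 2.4)
  r1 <- ratio_paired_ttest(a, b)
  r2 <- ratio_paired_ttest(17.3 * a, 17.3 * b)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p_value, r2$p_value)
  # a == b: zero mean, zero variance -> p = 1, degenerate flag
  same <- ratio_paired_ttest(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  # exact common ratio: zero variance, nonzero mean -> p = 0, flagged
  ex <- ratio_paired_ttest(a, 2 * a)
  expect_true(ex$degenerate)
  expect_equal(ex$p_value, 0)
  expect_equal(ex$gm_ratio, 2)
  expect_error(ratio_paired_ttest(c(1, -1), c(1, 1)), "positive")
  expect_error(ratio_paired_ttest(1, 1), "2 pairs")
})

test_that("strong condition effects are detected with the right directions", {
  spec <- cohort_spec(il13_effect = c(Je0 = 0.3, eta0 = 5), seed = 21)
  tab <- fit_cohort(simulate_cohort(spec), qc_cycles = FALSE)
  cmp <- compare_conditions(tab, plan = list(c("control", "il13")))[[1]]
  expect_lt(cmp$Je0$gm_ratio, 1)
  expect_gt(cmp$eta0$gm_ratio, 1)
  expect_lt(cmp$Je0$p_value, 0.05)
  expect_lt(cmp$eta0$p_value, 0.05)
  expect_identical(cmp$compliance_direction, "less compliant")
  expect_identical(cmp$viscosity_direction, "more viscous")
  # effect direction holds for every donor at this effect size and noise
  pd <- aggregate_donor(tab)
  ctrl <- pd[pd$condition == "control", ]
  il13 <- pd[pd$condition == "il13", ]
  il13 <- il13[match(ctrl$donor, il13$donor), ]
  expect_true(all(il13$Je0 < ctrl$Je0))
  expect_true(all(il13$eta0 > ctrl$eta0))
})

test_that("donor pairing is what carries the significance", {
  spec <- cohort_spec(il13_effect = c(Je0 = 0.3, eta0 = 5), seed = 22)
  tab <- fit_cohort(simulate_cohort(spec), qc_cycles = FALSE)
  pd <- aggregate_donor(tab)
  ctrl <- pd[pd$condition == "control", ]
  il13 <- pd[pd$condition == "il13", ]
  il13 <- il13[match(ctrl$donor, il13$donor), ]
  paired <- ratio_paired_ttest(ctrl$Je0, il13$Je0)
  expect_lt(paired$p_value, 0.05)
  # permuting donors jointly (same pairing) changes nothing
  perm <- c(3, 1, 5, 2, 4)
  joint <- ratio_paired_ttest(ctrl$Je0[perm], il13$Je0[perm])
  expect_equal(joint$t, paired$t, tolerance = 1e-12)
  expect_equal(joint$p_value, paired$p_value, tolerance = 1e-12)
  # permuting condition labels within donors (swapping a/b for half the
  # donors) destroys the coherent ratio
  a <- ctrl$Je0; b <- il13$Je0
  swap <- c(1, 3)
  a2 <- a; b2 <- b
  a2[swap] <- b[swap]; b2[swap] <- a[swap]
  broken <- ratio_paired_ttest(a2, b2)
  expect_gt(broken$p_value, paired$p_value)
})
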