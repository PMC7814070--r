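# Interval likelihood ratios, Bayes updating, effect bands, extreme mass

test_that("score binning is left-closed right-open with a closed last bin", {
  expect_equal(bin_scores(0.0005), 1)   # 0.05% -> first bin
  expect_equal(bin_scores(0.001), 2)    # exactly 0.1% -> upper bin
  expect_equal(bin_scores(0), 1)
  expect_equal(bin_scores(1), 8)        # closed upper edge
  expect_equal(bin_scores(0.99), 7)     # exactly 99% assigned upward
  expect_error(bin_scores(1.1), "\\[0, 1\\]")
  expect_error(bin_scores(0.5, c(0, 50, 40, 100)), "increasing")
})

test_that("interval LRs follow the per-bin probability ratio with flagged edges", {
  tab <- lr_table_from_counts(c(10, 10), c(10, 10), c(0, 50, 100))
  expect_equal(tab$lr, c(1, 1))

  tab <- lr_table_from_counts(c(5, 5), c(0, 10), c(0, 50, 100))
  expect_true(is.infinite(tab$lr[1]))
  expect_equal(tab$effect[1], "large")

  tab <- lr_table_from_counts(c(0, 5), c(0, 10), c(0, 50, 100))
  expect_true(is.nan(tab$lr[1]))   # 0/0 undefined, flagged as NaN

  # continuity correction resolves zero cells
  tab <- lr_table_from_counts(c(5, 5), c(0, 10), c(0, 50, 100), continuity = TRUE)
  expect_true(is.finite(tab$lr[1]))
})

test_that("interval_lr_table counts agree with direct binning", {
  set.seed(21)
  scores <- runif(500)
  case <- rep(c(TRUE, FALSE), 250)
  edges <- c(0, 25, 50, 75, 100) # coarse bins so every bin is populated
  tab <- interval_lr_table(scores, case, edges)
  expect_equal(sum(tab$n_diseased), 250)
  expect_equal(sum(tab$n_nondiseased), 250)
  expect_equal(tab$n_total, tab$n_diseased + tab$n_nondiseased)
  # conservation: per-group bin probabilities sum to one, and the
  # control-weighted mean of the LRs is one
  expect_equal(sum(tab$n_diseased / 250), 1)
  expect_true(all(is.finite(tab$lr)))
  expect_equal(sum((tab$n_nondiseased / 250) * tab$lr), 1)
})

test_that("LRs are non-decreasing over bins for a monotone score link", {
  sim <- simulate_cohort(sim_config(n_subjects = 500L, seed = 23L))
  ph <- merge(sim$photos, sim$truth, by = c("subject_id", "eye"))
  tab <- interval_lr_table(ph$score, ph$group == "glaucoma")
  # finite LRs must rise with the bin; infinite LRs may only sit above them
  fin <- which(is.finite(tab$lr))
  expect_true(all(diff(tab$lr[fin]) >= 0))
  inf_bins <- which(is.infinite(tab$lr))
  if (length(inf_bins) > 0) expect_true(min(inf_bins) > max(fin))
})

test_that("post-test probability follows Bayes on the odds scale", {
  expect_equal(posttest_probability(0.5, 0.06), 0.06 / 1.06)
  expect_equal(round(100 * posttest_probability(0.5, 0.06), 1), 5.7)
  expect_equal(round(100 * posttest_probability(0.5, 10.4)), 91)
  expect_equal(round(100 * posttest_probability(0.05, 38.2), 1), 66.8)
  expect_equal(posttest_probability(0.3, 1), 0.3)   # uninformative test
  expect_equal(posttest_probability(0, 5), 0)
  expect_equal(posttest_probability(1, 0.5), 1)
  expect_equal(posttest_probability(0.4, Inf), 1)
  expect_error(posttest_probability(0.5, 0), "positive")
  expect_error(posttest_probability(1.2, 2), "\\[0, 1\\]")
})

test_that("post-test probability is strictly increasing in both arguments", {
  p <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(posttest_probability(p, 3)) > 0))
  lrs <- c(0.1, 0.5, 1, 2, 10, 40)
  expect_true(all(diff(posttest_probability(0.3, lrs)) > 0))
})

test_that("averaging post-test probability over bins returns the pretest prevalence", {
  set.seed(22)
  scores <- runif(600)
  case <- runif(600) < 0.4
  prev <- mean(case)
  tab <- interval_lr_table(scores, case)
  # bins with LR = 0 hold no diseased mass and contribute zero post-test
  ok <- tab$n_total > 0 & tab$lr > 0
  post <- posttest_probability(prev, tab$lr[ok])
  expect_equal(sum((tab$n_total[ok] / sum(tab$n_total)) * post), prev)
})

test_that("effect bands follow the published interpretation thresholds", {
  expect_equal(lr_effect_category(38.2), "large")
  expect_equal(lr_effect_category(0.06), "large")
  expect_equal(lr_effect_category(3.90), "small")
  expect_equal(lr_effect_category(1.0), "insignificant")
  # boundaries: large iff > 10 or < 0.1; moderate (5,10] and [0.1,0.2);
  # small (2,5] and [0.2,0.5)
  expect_equal(lr_effect_category(c(10, 10.01, 0.1, 0.099)),
               c("moderate", "large", "moderate", "large"))
  expect_equal(lr_effect_category(c(5, 5.01, 0.2, 0.199)),
               c("small", "moderate", "small", "moderate"))
  expect_equal(lr_effect_category(c(2, 2.01, 0.5, 0.499)),
               c("insignificant", "small", "insignificant", "small"))
  expect_equal(lr_effect_category(Inf), "large")
})

test_that("printed rounding uses 2 decimals below 10 and 3 significant figures above", {
  expect_equal(format_lr(c(0.0627, 3.898, 10.39, 38.24)), c(0.06, 3.90, 10.4, 38.2))
})

test_that("extreme mass counts the conclusive bins", {
  expect_equal(extreme_mass(rep(0.5, 10)), 0)
  expect_equal(extreme_mass(rep(1, 10)), 1)
  expect_equal(extreme_mass(c(0.0005, 0.995, 0.5, 0.9995)), 0.75)
  expect_equal(extreme_mass_from_counts(c(642, 160, 512), extreme_bins = c(1, 3)),
               (642 + 512) / 1314)
})
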