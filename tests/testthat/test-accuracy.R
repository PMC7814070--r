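# ROC/AUC, age adjustment, sensitivity at fixed specificity, bootstrap

test_that("auc equals the Mann-Whitney concordance", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))$auc, 1)

  # hand-worked four-pair example
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)

  expect_error(auc(1:5, rep(TRUE, 5)), "both classes")

  # ties get half credit, matching the all-pairs oracle
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(case) || all(case)) next
    expect_equal(auc(scores, case)$auc, auc_oracle(scores, case))
  }
})

test_that("auc is invariant under strictly increasing transforms", {
  set.seed(7)
  scores <- runif(60)
  case <- rep(c(TRUE, FALSE), 30)
  a <- auc(scores, case)$auc
  expect_equal(auc(qlogis(scores), case)$auc, a)
  expect_equal(auc(scores^3, case)$auc, a)
})

test_that("roc_curve is monotone with the proper endpoints", {
  set.seed(8)
  r <- roc_curve(runif(80), rep(c(TRUE, FALSE), 40))
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(1 - r$specificity) >= 0))
  expect_equal(r$sensitivity[c(1, nrow(r))], c(0, 1))
  expect_equal(r$specificity[c(1, nrow(r))], c(1, 0))
})

test_that("age adjustment degenerates to the pooled AUC for constant ages", {
  set.seed(12)
  scores <- c(rnorm(40, 1), rnorm(40))
  case <- rep(c(TRUE, FALSE), each = 40)
  ages <- rep(60, 80)
  expect_equal(age_adjusted_auc(scores, case, ages)$auc, auc(scores, case)$auc)
  # and with ties in the scores
  scores_t <- round(scores)
  expect_equal(age_adjusted_auc(scores_t, case, ages)$auc, auc(scores_t, case)$auc)
})

test_that("age adjustment matches pooled under independence and deflates confounding", {
  set.seed(13)
  n <- 1000
  case <- rep(c(TRUE, FALSE), each = n)
  ages <- runif(2 * n, 40, 80)
  scores <- ifelse(case, rnorm(2 * n, 1.2), rnorm(2 * n))
  pooled <- auc(scores, case)$auc
  adj <- suppressWarnings(age_adjusted_auc(scores, case, ages)$auc)
  expect_lt(abs(adj - pooled), 0.02)

  # pure age confounding: the score is age plus a group shift
  m <- 4000
  case2 <- rep(c(TRUE, FALSE), each = m)
  shift <- 0.8
  ages_c <- c(rnorm(m, 60, 10), rnorm(m, 52, 10))
  scores_c <- 0.05 * ages_c + ifelse(case2, shift, 0) + rnorm(2 * m)
  pooled_c <- auc(scores_c, case2)$auc
  adj_c <- suppressWarnings(age_adjusted_auc(scores_c, case2, ages_c)$auc)
  expect_lt(adj_c, pooled_c)
  expect_lt(abs(adj_c - pnorm(shift / sqrt(2))), 0.03)
})

test_that("age adjustment guards its preconditions", {
  expect_error(age_adjusted_auc(1:20, rep(c(TRUE, FALSE), c(15, 5)), rep(50, 20)),
               "10 controls")
  case <- rep(c(TRUE, FALSE), each = 20)
  ages <- ifelse(case, 90, 45 + seq_len(40) %% 10)
  expect_warning(age_adjusted_auc(rnorm(40), case, ages), "extrapolating")
})

test_that("sensitivity at fixed specificity matches hand enumeration", {
  expect_equal(sensitivity_at_specificity(c(1:5 / 10, 6:10 / 10),
                                          rep(c(FALSE, TRUE), each = 5)), 1)

  # 20 controls at 1..20, threshold must sit above 19 of them
  controls <- 1:20
  cases <- c(10, 18, 19.5, 25, 30)
  scores <- c(controls, cases)
  labels <- rep(c(FALSE, TRUE), c(20, 5))
  got <- sensitivity_at_specificity(scores, labels, target_spec = 0.95)
  # smallest observed score with 19/20 controls strictly below is 19.5;
  # cases at/above 19.5: {19.5, 25, 30}
  expect_equal(got, 3 / 5)

  # distributionally identical classes: sensitivity ~ 1 - target
  set.seed(14)
  s <- rnorm(4000)
  l <- rep(c(TRUE, FALSE), 2000)
  expect_lt(abs(sensitivity_at_specificity(s, l, 0.95) - 0.05), 0.02)
})

test_that("adjusted sensitivity uses the placement-value tail", {
  set.seed(15)
  n <- 500
  case <- rep(c(TRUE, FALSE), each = n)
  ages <- rep(60, 2 * n)
  scores <- ifelse(case, rnorm(2 * n, 2), rnorm(2 * n))
  sens <- sensitivity_at_specificity(scores, case, 0.95, adjusted = TRUE, ages = ages)
  expect_lt(abs(sens - pnorm(qnorm(0.05) + 2)), 0.06)
})

test_that("cluster bootstrap is deterministic, degenerate on constants, and clustered", {
  d <- data.frame(x = rnorm(60), cl = rep(1:12, each = 5))
  ci <- cluster_bootstrap_ci(function(r) 7, d, d$cl, n_boot = 50, seed = 3L)
  expect_equal(ci$lower, 7)
  expect_equal(ci$upper, 7)

  a <- cluster_bootstrap_ci(function(r) mean(r$x), d, d$cl, n_boot = 200, seed = 4L)
  b <- cluster_bootstrap_ci(function(r) mean(r$x), d, d$cl, n_boot = 200, seed = 4L)
  expect_identical(a, b)
  expect_error(cluster_bootstrap_ci(function(r) mean(r$x), d, rep(1, 60)), "2 clusters")

  # strong within-cluster correlation: eye-level CIs wider than record-level
  set.seed(16)
  cl_eff <- rnorm(30, 0, 2)
  dd <- data.frame(x = rep(cl_eff, each = 8) + rnorm(240, 0, 0.1),
                   cl = rep(1:30, each = 8))
  eye <- cluster_bootstrap_ci(function(r) mean(r$x), dd, dd$cl, n_boot = 400, seed = 5L)
  rec <- cluster_bootstrap_ci(function(r) mean(r$x), dd, seq_len(240), n_boot = 400, seed = 5L)
  expect_gt(eye$upper - eye$lower, rec$upper - rec$lower)
})

test_that("bootstrap drops failing replicates and errors above 10%", {
  d <- data.frame(x = 1:20, cl = rep(1:4, each = 5))
  flaky <- function(r) if (length(unique(r$cl)) < 2) stop("degenerate") else mean(r$x)
  # 4 clusters: ~1.6% of resamples are single-cluster -> warning only
  expect_warning(
    ci <- cluster_bootstrap_ci(flaky, d, d$cl, n_boot = 400, seed = 6L),
    "dropped")
  expect_lt(ci$n_boot_used, 400)
  first_call <- TRUE
  fail_on_resamples <- function(r) {
    if (first_call) { first_call <<- FALSE; return(mean(r$x)) }
    stop("no")
  }
  expect_error(suppressWarnings(
    cluster_bootstrap_ci(fail_on_resamples, d, d$cl, n_boot = 50, seed = 7L)),
    "10%")
})

test_that("severity strata are evaluated against all controls", {
  set.seed(17)
  n <- 300
  case <- rep(c(TRUE, FALSE), each = n)
  scores <- ifelse(case, rnorm(2 * n, 1.5), rnorm(2 * n))
  stages <- ifelse(case, "severe", NA)
  tab <- evaluate_by_severity(scores, case, stages)
  expect_equal(tab$auc[tab$stratum == "severe"], tab$auc[tab$stratum == "overall"])
  expect_equal(tab$n_cases[tab$stratum == "early"], 0)
  expect_true(is.na(tab$auc[tab$stratum == "moderate"]))
  expect_equal(tab$n_controls, rep(n, 4))
})

test_that("suspect quartile contrast summarises top vs bottom quartile", {
  expect_error(
    suspect_quartile_contrast(data.frame(score = rep(0.5, 10), rnfl_global = 1:10,
                                         md = 1:10)),
    "degenerate")
  d <- data.frame(score = (1:8) / 10, rnfl_global = c(100, 98, 96, 94, 92, 90, 88, 86),
                  md = -(1:8))
  res <- suspect_quartile_contrast(d)
  expect_equal(res$summary$n, c(2, 2))
  expect_equal(res$summary$rnfl_mean, c(mean(c(100, 98)), mean(c(88, 86))))
  expect_equal(res$summary$md_median, c(-1.5, -7.5))
  expect_lt(res$summary$rnfl_mean[2], res$summary$rnfl_mean[1])
})
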