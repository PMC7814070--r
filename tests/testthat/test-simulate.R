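# Synthetic cohort generator: determinism, calibration, structure-function

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_subjects = 30L, seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c <- simulate_cohort(sim_config(n_subjects = 30L, seed = 100L))
  expect_false(identical(a$photos$score, c$photos$score))
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_subjects = 0L), "n_subjects")
  expect_error(sim_config(prevalence = 1.2), "prevalence")
  expect_error(sim_config(vf = list(point_sd = -1)), "SD")
  expect_error(sim_config(flags = list(thresholds = c(5, 1))), "thresholds")
  expect_error(sim_config(nonsense = 1), "unknown config field")
})

test_that("subject-level glaucoma fraction is binomially consistent with prevalence", {
  cfg <- sim_config(n_subjects = 400L, prevalence = 0.5, seed = 42L)
  sim <- simulate_cohort(cfg)
  first_eye <- sim$truth[sim$truth$eye == "OD", ]
  subj_frac <- mean(first_eye$group == "glaucoma")
  expect_lt(abs(subj_frac - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("healthy-only cohorts show ~1% outside flags per sector", {
  cfg <- sim_config(n_subjects = 800L, prevalence = 0, seed = 5L,
                    visits = list(n_visits = 1L))
  sim <- simulate_cohort(cfg)
  for (s in c("TS", "NS", "TI", "NI", "global")) {
    rate <- mean(sim$sdoct[[paste0("flag_", s)]] == "outside")
    expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / nrow(sim$sdoct)) + 0.003)
  }
})

test_that("device flags follow the percentile thresholds of the healthy model", {
  cfg <- sim_config()
  model <- gonref:::rnfl_normative_model(cfg)
  scan <- sdoct_frame()
  age <- cfg$rnfl$age_ref
  mu <- model$mean0
  # at the healthy mean -> within; 5 SD below -> outside; 3rd pctile -> borderline
  for (ch in c("global", "TS")) {
    scan[[paste0("rnfl_", ch)]] <- mu[[ch]]
  }
  got <- assign_device_flags(scan, age, model)
  expect_equal(got$flag_global, "within")
  expect_equal(got$flag_TS, "within")

  scan2 <- scan
  scan2$rnfl_global <- mu[["global"]] - 5 * model$sd[["global"]]
  scan2$rnfl_TS <- qnorm(0.03, mu[["TS"]], model$sd[["TS"]])
  got <- assign_device_flags(scan2, age, model)
  expect_equal(got$flag_global, "outside")
  expect_equal(got$flag_TS, "borderline")

  scan2$rnfl_TS <- Inf
  expect_error(assign_device_flags(scan2, age, model), "non-finite")
})

test_that("structure-function correspondence: superior RNFL defects depress the inferior field", {
  cfg <- sim_config(n_subjects = 600L, seed = 8L)
  sim <- simulate_cohort(cfg)
  s <- merge(sim$sap, sim$truth, by = c("subject_id", "eye"))
  h <- hemifield_md(s)
  sup_defect <- s$defect_type == "localized_superior_rnfl"
  inf_defect <- s$defect_type == "localized_inferior_rnfl"
  expect_lt(mean(h$inferior_md[sup_defect]), mean(h$superior_md[sup_defect]))
  expect_lt(mean(h$superior_md[inf_defect]), mean(h$inferior_md[inf_defect]))

  # and the corresponding structural side is the thinner one
  oct <- merge(sim$sdoct, sim$truth, by = c("subject_id", "eye"))
  sup_defect_o <- oct$defect_type == "localized_superior_rnfl"
  expect_lt(mean(oct$rnfl_TS[sup_defect_o]), mean(oct$rnfl_TI[sup_defect_o]))
})

test_that("generator recovers the configured cohort means", {
  sim <- simulate_cohort(sim_config(n_subjects = 800L, seed = 1L))
  m <- merge(sim$sdoct, sim$truth, by = c("subject_id", "eye"))
  normal <- m$group == "normal"; glauc <- m$group == "glaucoma"
  expect_gt(sum(normal), 500); expect_gt(sum(glauc), 500)
  expect_lt(abs(mean(m$rnfl_global[normal]) - 98.3), 2)
  expect_lt(abs(mean(m$rnfl_global[glauc]) - 67.0), 2)
})

test_that("empirical score AUC converges to the closed-form of the link", {
  # degenerate severity: binormal closed form pnorm(a * s / (sqrt(2) * sd))
  cfg <- sim_config(n_subjects = 1000L, seed = 6L,
                    rnfl = list(severity_shape = Inf),
                    visits = list(n_visits = 1L, photos_per_visit = 1L))
  sim <- simulate_cohort(cfg)
  ph <- merge(sim$photos, sim$truth, by = c("subject_id", "eye"))
  emp <- auc(ph$score, ph$group == "glaucoma")$auc
  expect_equal(emp, implied_score_auc(cfg), tolerance = 0.02)

  # gamma severity: numerically integrated implied AUC
  cfg2 <- sim_config(n_subjects = 1000L, seed = 7L,
                     visits = list(n_visits = 1L, photos_per_visit = 1L))
  sim2 <- simulate_cohort(cfg2)
  ph2 <- merge(sim2$photos, sim2$truth, by = c("subject_id", "eye"))
  emp2 <- auc(ph2$score, ph2$group == "glaucoma")$auc
  expect_equal(emp2, implied_score_auc(cfg2), tolerance = 0.02)
})

test_that("healthy reference sample has two eyes per subject and zero severity", {
  ref <- simulate_healthy_reference(231, sim_config(n_subjects = 5L), seed = 3L)
  expect_equal(nrow(ref), 462)
  expect_equal(sort(unique(table(ref$subject_id))), 2)
  expect_error(simulate_healthy_reference(1, sim_config()), "at least 2")

  # noiseless limit: every td value is exactly zero
  quiet <- sim_config(n_subjects = 5L,
                      vf = list(point_sd = 0, eye_sd = 0))
  ref0 <- simulate_healthy_reference(5, quiet, seed = 4L)
  expect_true(all(as.matrix(ref0[td_columns()]) == 0))
  expect_true(all(hemifield_md(ref0) == 0))
})
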