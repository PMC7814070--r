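## Synthetic cohort generator -------------------------------------------------
##
## A seeded generative model for subjects, eyes, RNFL scans, visual fields
## and photo scores carrying the statistical structure the analysis assumes:
## age differences between groups, structure-function correspondence (a
## superior RNFL defect depresses the inferior hemifield and vice versa),
## device normality flags from percentile thresholds on the healthy model,
## and a monotone latent-severity -> score link with configurable separation.

# Spectralis-style arc weights of the six peripapillary sectors.
sector_weights <- function() c(T = 0.25, TS = 0.125, NS = 0.125,
                               N = 0.25, NI = 0.125, TI = 0.125)

#' Simulation configuration
#'
#' Builds the configuration for [simulate_cohort()], with defaults
#' calibrated to the clinical registry the generator emulates: glaucoma
#' subjects older than normals (mean 62.8 vs 52.9 years), healthy global
#' RNFL around 98.3 um (SD ~11.5) declining ~2 um/decade, glaucomatous
#' global RNFL around 67 um, and a logistic severity-to-score link whose
#' separation is tunable.
#'
#' @param ... Named overrides of the defaults; nested lists are merged
#'   (e.g. `score = list(slope = 0.2)` replaces one field only).
#' @return An object of class `sim_config` (a nested list). Main blocks:
#' \describe{
#'   \item{n_subjects, prevalence, second_eye_concordance, seed}{cohort
#'     structure; the second eye of a glaucoma subject is glaucomatous with
#'     the given probability.}
#'   \item{age}{per-group normal age models (mean, sd) with truncation
#'     `bounds`, plus the healthy-reference age model.}
#'   \item{rnfl}{healthy sector means/SDs (um), shared eye-level SD, global
#'     measurement noise, age decline per decade, reference age, defect mix
#'     (`p_localized`, split evenly between superior and inferior; the rest
#'     diffuse), severity distribution (gamma via `severity_mean` and
#'     `severity_shape`, truncated at `severity_max`; `severity_shape = Inf`
#'     makes severity degenerate at the mean), and the loss-concentration
#'     factor of localized defects.}
#'   \item{vf}{total-deviation point noise SD (dB), eye-level shift SD, the
#'     structural-to-functional `transfer_slope` (dB of hemifield depression
#'     per um of global-equivalent loss), multipliers for the affected and
#'     spillover hemifields of a localized defect, and the GHT / PSD
#'     calibration rates.}
#'   \item{score}{the latent link `score = plogis(slope * severity +
#'     intercept + noise)`.}
#'   \item{flags}{percentile thresholds (percent) for outside/borderline
#'     device flags on the healthy model.}
#'   \item{visits}{visits per eye, spacing and date jitter (days), photos
#'     per visit.}
#'   \item{qc}{fractions of low-quality scans and unreliable fields, to
#'     exercise the exclusion rules.}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_subjects = 400L,
    prevalence = 0.5,
    second_eye_concordance = 0.6,
    seed = 1L,
    age = list(
      glaucoma = c(mean = 62.8, sd = 15.8),
      normal = c(mean = 52.9, sd = 15.7),
      reference = c(mean = 54.2, sd = 15.0),
      bounds = c(21, 95)
    ),
    rnfl = list(
      sector_mean = c(T = 72, TS = 135, NS = 103, N = 74, NI = 112, TI = 144),
      sector_sd = c(T = 8, TS = 14, NS = 13, N = 9, NI = 14, TI = 13),
      eye_sd = 10,
      global_noise_sd = 2,
      age_decline_per_decade = 2,
      age_ref = 54.2,
      p_localized = 0.5,
      severity_mean = 29.5,
      severity_shape = 2,
      severity_max = 85,
      localized_concentration = 0.7,
      floor = 25
    ),
    vf = list(
      point_sd = 1.5,
      eye_sd = 1.0,
      transfer_slope = 0.3,
      affected_mult = 2.0,
      spill_mult = 0.2,
      td_bounds = c(-35, 10),
      ght_fp_outside = 0.01,
      ght_fp_borderline = 0.05,
      ght_depression_db = -3
    ),
    score = list(slope = 0.35, intercept = -6, noise_sd = 1.8),
    flags = list(thresholds = c(1, 5)),
    visits = list(n_visits = 2L, spacing_days = 180, sap_jitter_days = 30,
                  photo_jitter_days = 30, photos_per_visit = 2L),
    qc = list(p_low_quality = 0.05, p_unreliable = 0.05)
  )
  cfg <- merge_config(cfg, list(...))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) stop(sprintf("unknown config field: %s", nm), call. = FALSE)
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) && length(base[[nm]]) > 0) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

validate_sim_config <- function(cfg) {
  err <- function(msg) stop(sprintf("invalid sim_config: %s", msg), call. = FALSE)
  if (cfg$n_subjects < 1) err("n_subjects must be >= 1")
  if (cfg$prevalence < 0 || cfg$prevalence > 1) err("prevalence must be in [0, 1]")
  sds <- c(cfg$age$glaucoma["sd"], cfg$age$normal["sd"], cfg$rnfl$sector_sd,
           cfg$rnfl$eye_sd, cfg$rnfl$global_noise_sd, cfg$vf$point_sd,
           cfg$vf$eye_sd, cfg$score$noise_sd)
  if (any(sds < 0)) err("all SDs must be >= 0")
  th <- cfg$flags$thresholds
  if (length(th) != 2 || any(th <= 0) || any(th >= 50) || th[1] >= th[2]) {
    err("flag thresholds must be two percentiles in (0, 50), increasing")
  }
  if (cfg$visits$n_visits < 1) err("n_visits must be >= 1")
  invisible(cfg)
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_severity <- function(n, rnfl) {
  if (is.infinite(rnfl$severity_shape)) return(rep(rnfl$severity_mean, n))
  s <- stats::rgamma(n, shape = rnfl$severity_shape,
                     scale = rnfl$severity_mean / rnfl$severity_shape)
  pmin(s, rnfl$severity_max)
}

# Healthy RNFL normative model implied by a configuration: age-conditional
# mean and total SD per sector and for the global average.
rnfl_normative_model <- function(config) {
  w <- sector_weights()
  m <- config$rnfl
  mean0 <- c(global = unname(sum(w * m$sector_mean[names(w)])), m$sector_mean)
  sd <- c(global = sqrt(m$eye_sd^2 + m$global_noise_sd^2),
          sqrt(m$eye_sd^2 + m$sector_sd^2))
  list(mean0 = mean0, sd = sd,
       decline_per_decade = m$age_decline_per_decade, age_ref = m$age_ref)
}

normative_mean_at_age <- function(model, age, channel) {
  model$mean0[[channel]] - model$decline_per_decade * (age - model$age_ref) / 10
}

#' Assign device normality flags from a healthy RNFL model
#'
#' Emulates the device's three-level colour classification: a thickness is
#' `outside` normal limits when it falls below the lower percentile
#' threshold (default 1st) of the age-matched healthy distribution,
#' `borderline` between the two thresholds (default 1st-5th), and `within`
#' otherwise. Applied to the global average and all six sectors.
#'
#' @param scans Data frame with the `rnfl_*` thickness columns.
#' @param ages Age (years) per scan row.
#' @param model Healthy normative model as produced internally from a
#'   [sim_config()] (age-conditional normal per channel); lists `mean0`,
#'   `sd`, `decline_per_decade`, `age_ref`.
#' @param percentile_thresholds Two percentiles in (0, 50), increasing.
#' @return `scans` with the seven `flag_*` columns filled.
#' @export
assign_device_flags <- function(scans, ages, model, percentile_thresholds = c(1, 5)) {
  stopifnot(length(ages) == nrow(scans),
            length(percentile_thresholds) == 2,
            all(percentile_thresholds > 0), all(percentile_thresholds < 50))
  p <- percentile_thresholds / 100
  for (ch in c("global", rnfl_sectors())) {
    x <- scans[[paste0("rnfl_", ch)]]
    if (any(!is.finite(x))) stop(sprintf("non-finite thickness in rnfl_%s", ch), call. = FALSE)
    mu <- normative_mean_at_age(model, ages, ch)
    lo <- stats::qnorm(p[1], mu, model$sd[[ch]])
    bo <- stats::qnorm(p[2], mu, model$sd[[ch]])
    scans[[paste0("flag_", ch)]] <-
      ifelse(x < lo, "outside", ifelse(x < bo, "borderline", "within"))
  }
  scans
}

# GHT surrogate: outside when the absolute hemifield-mean difference exceeds
# the threshold calibrated (closed form under the healthy point-noise model)
# to the configured false-positive rate, or when both hemifields are
# depressed below ght_depression_db; borderline at the looser calibration.
simulate_ght <- function(sup_md, inf_md, vf) {
  sd_diff <- vf$point_sd * sqrt(2 / 26)
  th_out <- stats::qnorm(1 - vf$ght_fp_outside / 2) * sd_diff
  th_bord <- stats::qnorm(1 - vf$ght_fp_borderline / 2) * sd_diff
  d <- abs(sup_md - inf_md)
  both_low <- sup_md < vf$ght_depression_db & inf_md < vf$ght_depression_db
  ifelse(d > th_out | both_low, "outside_normal_limits",
         ifelse(d > th_bord, "borderline", "within_normal_limits"))
}

# PSD p-category from the closed-form healthy sampling distribution of the
# SD of 52 iid normal deviations: sigma * sqrt(chisq_51 / 51).
simulate_psd_p <- function(psd, vf) {
  if (vf$point_sd == 0) return(rep("not_significant", length(psd)))
  qs <- vf$point_sd * sqrt(stats::qchisq(c(0.95, 0.98, 0.99, 0.995), df = 51) / 51)
  ifelse(psd >= qs[4], "lt0.5",
         ifelse(psd >= qs[3], "lt1",
                ifelse(psd >= qs[2], "lt2",
                       ifelse(psd >= qs[1], "lt5", "not_significant"))))
}

# Per-sector thickness loss (um) implied by a defect type and severity s
# (global-equivalent um): diffuse spreads s over all sectors; a localized
# defect keeps a (1 - c) diffuse share and concentrates the share c in the
# two affected sectors, scaled by their arc weight so the weighted total
# stays s.
sector_losses <- function(defect_type, severity, rnfl) {
  w <- sector_weights()
  n <- length(severity)
  loss <- matrix(0, n, 6, dimnames = list(NULL, names(w)))
  conc <- rnfl$localized_concentration
  for (i in seq_len(n)) {
    s <- severity[i]
    if (s == 0) next
    loss[i, ] <- switch(defect_type[i],
      diffuse = rep(s, 6),
      localized_superior_rnfl = {
        base <- stats::setNames(rep((1 - conc) * s, 6), names(w))
        base[c("TS", "NS")] <- base[c("TS", "NS")] + conc * s / (w["TS"] + w["NS"])
        base
      },
      localized_inferior_rnfl = {
        base <- stats::setNames(rep((1 - conc) * s, 6), names(w))
        base[c("TI", "NI")] <- base[c("TI", "NI")] + conc * s / (w["TI"] + w["NI"])
        base
      },
      none = rep(0, 6)
    )
  }
  loss
}

# Hemifield td depression (dB, positive = loss) implied by a defect.
hemifield_depression <- function(defect_type, severity, vf) {
  base <- vf$transfer_slope * severity
  sup <- ifelse(defect_type == "diffuse", base,
         ifelse(defect_type == "localized_inferior_rnfl", vf$affected_mult * base,
         ifelse(defect_type == "localized_superior_rnfl", vf$spill_mult * base, 0)))
  inf <- ifelse(defect_type == "diffuse", base,
         ifelse(defect_type == "localized_superior_rnfl", vf$affected_mult * base,
         ifelse(defect_type == "localized_inferior_rnfl", vf$spill_mult * base, 0)))
  cbind(superior = sup, inferior = inf)
}

#' Simulate a full synthetic cohort
#'
#' Generates subjects (with group-specific ages), two eyes per subject with
#' correlated disease status, and per eye a latent severity, defect type and
#' repeated visits carrying an SDOCT scan, a SAP test and fundus-photo
#' scores. Deterministic given `config$seed`; a single seeded stream first
#' draws per-table sub-seeds, so each table is reproducible.
#'
#' @param config A [sim_config()].
#' @return A list of data frames: `subjects`, `sdoct`, `sap`, `photos`
#'   (in the package's table schemas) and `truth` (one row per eye:
#'   `subject_id`, `eye`, `group`, `defect_type`, `severity`) — the
#'   simulation truth, for testing only.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  sub_seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 4L))

  truth <- with_seed(sub_seeds[1], draw_truth(config))
  sdoct <- with_seed(sub_seeds[2], draw_sdoct(truth, config))
  sap <- with_seed(sub_seeds[3], draw_sap(truth, config))
  photos <- with_seed(sub_seeds[4], draw_photos(truth, config))

  subjects <- unique(truth$eyes[c("subject_id", "age", "sex", "race")])
  rownames(subjects) <- NULL
  list(subjects = subjects, sdoct = sdoct, sap = sap, photos = photos,
       truth = resetrow(truth$eyes[c("subject_id", "eye", "group", "defect_type",
                                     "severity")]))
}

draw_truth <- function(config) {
  n <- config$n_subjects
  subject_id <- sprintf("S%05d", seq_len(n))
  grp_subj <- ifelse(stats::runif(n) < config$prevalence, "glaucoma", "normal")
  b <- config$age$bounds
  age <- ifelse(grp_subj == "glaucoma",
                rtruncnorm(n, config$age$glaucoma["mean"], config$age$glaucoma["sd"], b[1], b[2]),
                rtruncnorm(n, config$age$normal["mean"], config$age$normal["sd"], b[1], b[2]))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.58, 0.42))
  race <- sample(c("african_american", "caucasian", "other"), n,
                 replace = TRUE, prob = c(0.30, 0.60, 0.10))
  base_date <- as.Date("2020-01-01") + sample.int(365, n, replace = TRUE)

  # two eyes per subject; the fellow eye of a glaucoma subject is
  # glaucomatous with the configured concordance probability
  eyes <- data.frame(
    subject_id = rep(subject_id, each = 2),
    eye = rep(c("OD", "OS"), n),
    age = rep(age, each = 2),
    sex = rep(sex, each = 2),
    race = rep(race, each = 2),
    base_date = rep(base_date, each = 2)
  )
  first <- rep(c(TRUE, FALSE), n)
  grp_eye <- rep(grp_subj, each = 2)
  fellow_normal <- !first & grp_eye == "glaucoma" &
    stats::runif(2 * n) > config$second_eye_concordance
  grp_eye[fellow_normal] <- "normal"
  eyes$group <- grp_eye

  is_g <- eyes$group == "glaucoma"
  eyes$severity <- 0
  eyes$severity[is_g] <- draw_severity(sum(is_g), config$rnfl)
  eyes$defect_type <- "none"
  u <- stats::runif(nrow(eyes))
  pl <- config$rnfl$p_localized
  eyes$defect_type[is_g] <- ifelse(u[is_g] < pl / 2, "localized_superior_rnfl",
                            ifelse(u[is_g] < pl, "localized_inferior_rnfl", "diffuse"))
  eyes$oct_eye_factor <- stats::rnorm(nrow(eyes), 0, config$rnfl$eye_sd)
  eyes$vf_eye_shift <- stats::rnorm(nrow(eyes), 0, config$vf$eye_sd)
  list(eyes = eyes)
}

visit_frame <- function(eyes, config) {
  nv <- config$visits$n_visits
  v <- eyes[rep(seq_len(nrow(eyes)), each = nv), , drop = FALSE]
  v$visit <- rep(seq_len(nv), nrow(eyes))
  v$visit_date <- v$base_date + (v$visit - 1) * config$visits$spacing_days
  resetrow(v)
}

draw_sdoct <- function(truth, config) {
  v <- visit_frame(truth$eyes, config)
  m <- config$rnfl
  model <- rnfl_normative_model(config)
  loss <- sector_losses(v$defect_type, v$severity, m)
  out <- v[c("subject_id", "eye")]
  out$scan_date <- v$visit_date
  low_q <- stats::runif(nrow(v)) < config$qc$p_low_quality
  out$quality_score <- ifelse(low_q, sample(5:14, nrow(v), replace = TRUE),
                              sample(18:35, nrow(v), replace = TRUE))
  decade <- (v$age - m$age_ref) / 10
  out$rnfl_global <- pmax(20, pmin(249,
    normative_mean_at_age(model, v$age, "global") - v$severity +
      v$oct_eye_factor + stats::rnorm(nrow(v), 0, m$global_noise_sd)))
  for (sec in rnfl_sectors()) {
    out[[paste0("rnfl_", sec)]] <- pmax(m$floor, pmin(249,
      m$sector_mean[[sec]] - m$age_decline_per_decade * decade - loss[, sec] +
        v$oct_eye_factor + stats::rnorm(nrow(v), 0, m$sector_sd[[sec]])))
  }
  out <- assign_device_flags(out, v$age, model, config$flags$thresholds)
  out[sdoct_columns()]
}

draw_sap <- function(truth, config) {
  v <- visit_frame(truth$eyes, config)
  vf <- config$vf
  n <- nrow(v)
  jit <- config$visits$sap_jitter_days
  out <- v[c("subject_id", "eye")]
  out$test_date <- v$visit_date + sample(seq(-jit, jit), n, replace = TRUE)

  dep <- hemifield_depression(v$defect_type, v$severity, vf)
  g <- grid24_points()
  td <- matrix(0, n, 52, dimnames = list(NULL, g$col))
  for (j in seq_len(52)) {
    d <- if (g$y[j] > 0) dep[, "superior"] else dep[, "inferior"]
    td[, j] <- -d + v$vf_eye_shift + stats::rnorm(n, 0, vf$point_sd)
  }
  td[] <- pmax(vf$td_bounds[1], pmin(vf$td_bounds[2], td))
  out$md <- rowMeans(td)
  out$psd <- apply(td, 1, stats::sd)
  out$psd_p <- simulate_psd_p(out$psd, vf)
  sup_cols <- g$col[g$y > 0]; inf_cols <- g$col[g$y < 0]
  out$ght <- simulate_ght(rowMeans(td[, sup_cols, drop = FALSE]),
                          rowMeans(td[, inf_cols, drop = FALSE]), vf)
  unrel <- stats::runif(n) < config$qc$p_unreliable
  which_fl <- stats::runif(n) < 0.5
  out$fixation_loss_frac <- ifelse(unrel & which_fl, stats::runif(n, 0.34, 0.6),
                                   stats::runif(n, 0, 0.30))
  out$false_positive_frac <- ifelse(unrel & !which_fl, stats::runif(n, 0.16, 0.4),
                                    stats::runif(n, 0, 0.12))
  out <- cbind(out, as.data.frame(td))
  out[sap_columns()]
}

draw_photos <- function(truth, config) {
  v <- visit_frame(truth$eyes, config)
  np <- config$visits$photos_per_visit
  p <- v[rep(seq_len(nrow(v)), each = np), , drop = FALSE]
  n <- nrow(p)
  jit <- config$visits$photo_jitter_days
  sc <- config$score
  out <- p[c("subject_id", "eye")]
  out$photo_date <- p$visit_date + sample(seq(-jit, jit), n, replace = TRUE)
  latent <- sc$slope * p$severity + sc$intercept + stats::rnorm(n, 0, sc$noise_sd)
  out$score <- stats::plogis(latent)
  out$camera_id <- sample(c("cam_A", "cam_B"), n, replace = TRUE)
  resetrow(out[photo_columns()])
}

#' Closed-form AUC implied by the score link
#'
#' The score link is monotone in the latent variable
#' `slope * severity + intercept + noise`, so the population AUC of score
#' against group is `P(latent_case > latent_control)`. With degenerate
#' severity (`severity_shape = Inf`) this is the binormal form
#' `pnorm(slope * severity_mean / (sqrt(2) * noise_sd))`; for gamma-
#' distributed severity the severity is integrated out numerically.
#'
#' @param config A [sim_config()].
#' @return The implied AUC in (0, 1).
#' @export
implied_score_auc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  a <- config$score$slope
  s2 <- sqrt(2) * config$score$noise_sd
  r <- config$rnfl
  if (is.infinite(r$severity_shape)) {
    return(stats::pnorm(a * r$severity_mean / s2))
  }
  # truncated-gamma severity: mass above severity_max sits at the bound
  shape <- r$severity_shape
  scale <- r$severity_mean / shape
  p_tail <- stats::pgamma(r$severity_max, shape, scale = scale, lower.tail = FALSE)
  body <- stats::integrate(function(s) {
    stats::pnorm(a * s / s2) * stats::dgamma(s, shape, scale = scale)
  }, 0, r$severity_max)$value
  body + p_tail * stats::pnorm(a * r$severity_max / s2)
}

#' Simulate a healthy reference sample of visual fields
#'
#' Generates the SAP tests of a healthy normative sample — two eyes per
#' subject, severity fixed at zero — used only to derive the hemifield-MD
#' cutoffs.
#'
#' @param n_subjects Number of healthy subjects (>= 2); yields
#'   `2 * n_subjects` tests.
#' @param config A [sim_config()]; only the visual-field noise model and the
#'   reference age model are used.
#' @param seed Integer seed.
#' @return Data frame of SAP tests in the package schema.
#' @export
simulate_healthy_reference <- function(n_subjects, config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_subjects < 2) stop("healthy reference needs at least 2 subjects", call. = FALSE)
  ref_cfg <- config
  ref_cfg$n_subjects <- as.integer(n_subjects)
  ref_cfg$prevalence <- 0
  ref_cfg$seed <- as.integer(seed)
  ref_cfg$visits$n_visits <- 1L
  ref_cfg$qc$p_unreliable <- 0
  ref_cfg$age$normal <- ref_cfg$age$reference
  sim <- simulate_cohort(ref_cfg)
  sim$sap
}
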