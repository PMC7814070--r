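## End-to-end orchestration ---------------------------------------------------

#' Pipeline run configuration
#'
#' Defaults reproduce the study conditions of the analysis: 180-day pairing
#' windows, reliability exclusions above 33% fixation losses / 15% false
#' positives, quality scores below 15 excluded, 5th-percentile hemifield
#' cutoffs from a 231-subject healthy reference, the standard score binning,
#' eye-level bootstrap with 2000 replicates, and an 80/20 subject-level
#' split.
#'
#' @param ... Named overrides (nested lists merged), e.g.
#'   `simulate = list(n_subjects = 100)`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    pairing_window_days = 180,
    photo_window_days = 180,
    max_fixation_loss = 0.33,
    max_false_positive = 0.15,
    min_quality = 15,
    cutoff_percentile = 5,
    n_reference_subjects = 231L,
    bin_edges_percent = default_bin_edges(),
    n_boot = 2000L,
    ci_level = 0.95,
    train_fraction = 0.8,
    seed = 1L,
    simulate = list() # sim_config() overrides for the synthetic cohort
  )
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Key-value configuration mirroring [run_config()] fields; unknown keys are
#' an error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[gonref] ", fmt), ...))
}

#' Run the full evaluation pipeline
#'
#' Orchestrates simulate (or load) -> QC -> pair -> classify -> label photos
#' -> split -> evaluate: derives normative cutoffs from a simulated healthy
#' reference, labels every SDOCT-SAP pair with the objective GON standard,
#' attaches labels to photos, and evaluates the photo score on the test
#' split with pooled and age-adjusted ROC/AUC, sensitivity at 95%
#' specificity, eye-level bootstrap CIs, the severity-stratified table, the
#' interval likelihood-ratio table and the suspect-quartile contrast.
#' Suspects are excluded from ROC/LR evaluation and routed to the quartile
#' report. All stage counts are logged.
#'
#' @param config A [run_config()].
#' @param tables Optional named list of input tables (`subjects`, `sdoct`,
#'   `sap`, `photos`); when `NULL` a synthetic cohort is generated from
#'   `config$simulate` with `config$seed`.
#' @param outdir Optional directory; when given, all result tables are
#'   written there as CSV (`labels.csv`, `cutoffs.csv`, `auc.csv`,
#'   `severity_table.csv`, `lr_table.csv`, `suspect_quartiles.csv`,
#'   `descriptives.csv`, `score_histogram.csv`, `exclusions.csv`).
#' @param verbose Log stage-by-stage counts?
#' @return A list bundle with elements `cutoffs`, `pairs`, `labels`,
#'   `labeled_photos`, `split`, `auc` (data frame of pooled/adjusted
#'   estimates with CIs), `severity`, `lr_table`, `suspect_quartiles`,
#'   `descriptives`, `score_histogram`, `exclusions`, `counts`.
#' @export
run_pipeline <- function(config = run_config(), tables = NULL, outdir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(tables)) {
    sim_cfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    tables <- simulate_cohort(sim_cfg)
    log_stage(verbose, "simulated cohort: %d subjects, %d scans, %d fields, %d photos (seed %d)",
              nrow(tables$subjects), nrow(tables$sdoct), nrow(tables$sap),
              nrow(tables$photos), config$seed)
  } else {
    sim_cfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
  }

  qc_sap <- filter_reliable_sap(tables$sap, config$max_fixation_loss,
                                config$max_false_positive)
  qc_oct <- filter_quality_sdoct(tables$sdoct, config$min_quality)
  log_stage(verbose, "QC: %d/%d fields reliable, %d/%d scans adequate quality",
            nrow(qc_sap$kept), nrow(tables$sap), nrow(qc_oct$kept), nrow(tables$sdoct))

  paired <- pair_sdoct_sap(qc_oct$kept, qc_sap$kept, config$pairing_window_days)
  log_stage(verbose, "pairing: %d pairs, %d scans unpaired",
            nrow(paired$pairs), nrow(paired$unpaired))

  healthy_ref <- simulate_healthy_reference(config$n_reference_subjects, sim_cfg,
                                            seed = config$seed + 1L)
  cutoffs <- derive_hemifield_cutoffs(healthy_ref, config$cutoff_percentile)
  labels <- classify_gon(paired$pairs, cutoffs)
  log_stage(verbose, "classification: %d glaucoma, %d normal, %d suspect",
            sum(labels$label == "glaucoma"), sum(labels$label == "normal"),
            sum(labels$label == "suspect"))

  matched <- match_photos_to_pairs(tables$photos, labels, config$photo_window_days)
  lp <- matched$matched
  lp$eye_id <- paste(lp$subject_id, lp$eye, sep = ":")
  lp <- merge(lp, tables$subjects[c("subject_id", "age")], by = "subject_id")
  log_stage(verbose, "photo matching: %d labeled photos, %d unmatched",
            nrow(lp), nrow(matched$unmatched))

  split <- split_by_subject(lp, config$train_fraction, config$seed + 2L)
  test <- split$test
  eval_set <- test[test$label != "suspect", ]
  suspects <- test[test$label == "suspect", ]
  log_stage(verbose, "split: %d train photos, %d test photos (%d eval, %d suspect)",
            nrow(split$train), nrow(test), nrow(eval_set), nrow(suspects))

  auc_tab <- severity_tab <- lr_tab <- quartiles <- NULL
  if (nrow(eval_set) > 0 && length(unique(eval_set$label)) == 2) {
    pooled <- auc(eval_set$score, eval_set$label)
    adjusted <- age_adjusted_auc(eval_set$score, eval_set$label, eval_set$age)
    boot_pooled <- cluster_bootstrap_ci(
      function(d) auc(d$score, d$label)$auc,
      eval_set, eval_set$eye_id, config$n_boot, config$ci_level, config$seed + 3L)
    boot_adj <- cluster_bootstrap_ci(
      function(d) suppressWarnings(age_adjusted_auc(d$score, d$label, d$age)$auc),
      eval_set, eval_set$eye_id, config$n_boot, config$ci_level, config$seed + 4L)
    sens <- sensitivity_at_specificity(eval_set$score, eval_set$label, 0.95)
    sens_adj <- sensitivity_at_specificity(eval_set$score, eval_set$label, 0.95,
                                           adjusted = TRUE, ages = eval_set$age)
    auc_tab <- data.frame(
      adjustment = c("none", "age"),
      auc = c(pooled$auc, adjusted$auc),
      ci_lower = c(boot_pooled$lower, boot_adj$lower),
      ci_upper = c(boot_pooled$upper, boot_adj$upper),
      sensitivity_at_95_spec = c(sens, sens_adj),
      n_cases = pooled$n_cases, n_controls = pooled$n_controls
    )
    severity_tab <- evaluate_by_severity(eval_set$score, eval_set$label,
                                         eval_set$stage, ages = eval_set$age)
    lr_tab <- interval_lr_table(eval_set$score, eval_set$label,
                                config$bin_edges_percent)
  }
  if (nrow(suspects) >= 8 && stats::sd(suspects$score) > 0) {
    quartiles <- suspect_quartile_contrast(suspects)
  }

  descriptives <- describe_groups(test)
  hist_tab <- score_histogram(test)

  exclusions <- rbind(
    count_frame("sap_unreliable", qc_sap$excluded),
    count_frame("sdoct_low_quality", qc_oct$excluded),
    count_frame("scan_unpaired", paired$unpaired),
    count_frame("photo_unmatched", matched$unmatched)
  )
  counts <- list(
    photos_in = nrow(tables$photos), labeled_photos = nrow(lp),
    train = nrow(split$train), test = nrow(test),
    eval = nrow(eval_set), suspect = nrow(suspects)
  )

  bundle <- list(cutoffs = cutoffs, pairs = paired$pairs, labels = labels,
                 labeled_photos = lp, split = split, auc = auc_tab,
                 severity = severity_tab, lr_table = lr_tab,
                 suspect_quartiles = quartiles, descriptives = descriptives,
                 score_histogram = hist_tab, exclusions = exclusions,
                 counts = counts)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  invisible(bundle)
}

count_frame <- function(stage, df) {
  data.frame(stage = stage, n = nrow(df))
}

# Group descriptives in the layout of a cohort table: median/IQR MD and
# score, mean/SD global RNFL, per label group.
describe_groups <- function(lp) {
  if (nrow(lp) == 0) return(NULL)
  do.call(rbind, lapply(split(lp, lp$label), function(d) {
    data.frame(
      label = d$label[1], n_photos = nrow(d),
      n_eyes = length(unique(paste(d$subject_id, d$eye))),
      n_subjects = length(unique(d$subject_id)),
      age_mean = mean(d$age), age_sd = stats::sd(d$age),
      md_median = stats::median(d$md),
      md_q1 = unname(stats::quantile(d$md, 0.25)),
      md_q3 = unname(stats::quantile(d$md, 0.75)),
      superior_md_median = stats::median(d$superior_md),
      inferior_md_median = stats::median(d$inferior_md),
      psd_mean = mean(d$psd), psd_sd = stats::sd(d$psd),
      rnfl_global_mean = mean(d$rnfl_global), rnfl_global_sd = stats::sd(d$rnfl_global),
      score_median_pct = 100 * stats::median(d$score),
      score_q1_pct = 100 * unname(stats::quantile(d$score, 0.25)),
      score_q3_pct = 100 * unname(stats::quantile(d$score, 0.75))
    )
  }))
}

# Histogram of score mass per default bin, per label group (figure data).
score_histogram <- function(lp, edges = default_bin_edges()) {
  if (nrow(lp) == 0) return(NULL)
  b <- bin_scores(lp$score, edges)
  k <- length(edges) - 1
  out <- lapply(split(seq_len(nrow(lp)), lp$label), function(idx) {
    data.frame(label = lp$label[idx[1]], bin = seq_len(k),
               bin_label = bin_labels(edges),
               n = tabulate(b[idx], nbins = k))
  })
  resetrow(do.call(rbind, out))
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  wr(data.frame(superior_cutoff = bundle$cutoffs$superior_cutoff,
                inferior_cutoff = bundle$cutoffs$inferior_cutoff,
                percentile = bundle$cutoffs$percentile,
                n_reference_eyes = bundle$cutoffs$n_reference_eyes), "cutoffs.csv")
  keep <- c("subject_id", "eye", "scan_date", "test_date", "gap_days", "label",
            "stage", "superior_md", "inferior_md", "md", "psd", "rnfl_global",
            "crit_global_loss", "crit_superior_structural_inferior_functional",
            "crit_inferior_structural_superior_functional")
  wr(bundle$labels[intersect(keep, names(bundle$labels))], "labels.csv")
  wr(bundle$auc, "auc.csv")
  wr(bundle$severity, "severity_table.csv")
  wr(as.data.frame(bundle$lr_table), "lr_table.csv")
  if (!is.null(bundle$suspect_quartiles)) {
    sq <- bundle$suspect_quartiles
    tab <- sq$summary
    tab$p_rnfl <- sq$p_rnfl
    tab$p_md <- sq$p_md
    wr(tab, "suspect_quartiles.csv")
  }
  wr(bundle$descriptives, "descriptives.csv")
  wr(bundle$score_histogram, "score_histogram.csv")
  wr(bundle$exclusions, "exclusions.csv")
  invisible(outdir)
}
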