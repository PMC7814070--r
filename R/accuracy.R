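## Diagnostic accuracy: ROC / AUC, age adjustment, clustered bootstrap --------

as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- as.character(labels)
  bad <- !(lab %in% c("glaucoma", "normal"))
  if (any(bad)) {
    stop("labels must be logical or in {\"glaucoma\", \"normal\"}", call. = FALSE)
  }
  lab == "glaucoma"
}

check_two_classes <- function(case) {
  if (!any(case) || all(case)) {
    stop("both classes (cases and controls) must be present", call. = FALSE)
  }
}

#' Pooled empirical AUC
#'
#' Area under the empirical ROC curve, computed as the Mann-Whitney
#' concordance: the mean over all case/control pairs of 1 if the case scores
#' higher, 0.5 for a tie, 0 otherwise (midrank convention).
#'
#' @param scores Numeric diagnostic scores (higher = more disease-like).
#' @param labels Logical case indicator, or character labels
#'   `"glaucoma"` / `"normal"`.
#' @return An object of class `auc_estimate`: `auc`, `n_cases`,
#'   `n_controls`, `adjustment = "none"`; CI fields are `NA` until filled by
#'   a bootstrap.
#' @export
auc <- function(scores, labels) {
  case <- as_case(labels)
  stopifnot(length(scores) == length(case), all(is.finite(scores)))
  check_two_classes(case)
  r <- rank(scores) # midranks give the 0.5 tie credit
  n1 <- sum(case); n0 <- sum(!case)
  a <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  new_auc_estimate(a, n1, n0, "none")
}

new_auc_estimate <- function(a, n1, n0, adjustment, lower = NA_real_, upper = NA_real_) {
  structure(list(auc = unname(a), ci_lower = lower, ci_upper = upper,
                 n_cases = n1, n_controls = n0, adjustment = adjustment),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_lower)) "" else sprintf(" (95%% CI %.3f, %.3f)", x$ci_lower, x$ci_upper)
  cat(sprintf("AUC = %.3f%s [%s; %d cases, %d controls]\n",
              x$auc, ci, x$adjustment, x$n_cases, x$n_controls))
  invisible(x)
}

#' Empirical ROC curve
#'
#' @inheritParams auc
#' @param ages Optional ages; when supplied the curve is the age-adjusted
#'   (placement-value) ROC.
#' @return Data frame with `threshold` (for the pooled curve), `sensitivity`
#'   and `specificity`, including the (0,0) and (1,1) endpoints.
#' @export
roc_curve <- function(scores, labels, ages = NULL) {
  case <- as_case(labels)
  check_two_classes(case)
  if (!is.null(ages)) {
    pv <- placement_values(scores, case, ages)
    t <- sort(unique(c(0, pv$pv_case, 1)))
    sens <- vapply(t, function(u) mean(pv$pv_case <= u), 0)
    return(data.frame(threshold = NA_real_, sensitivity = sens, specificity = 1 - t))
  }
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(u) mean(scores[case] >= u), 0)
  spec <- vapply(th, function(u) mean(scores[!case] < u), 0)
  data.frame(
    threshold = c(Inf, th, -Inf),
    sensitivity = c(0, sens, 1),
    specificity = c(1, spec, 0)
  )
}

# Placement values of cases relative to the age-conditional control score
# distribution: a linear location model of control scores on age, with the
# empirical (mid-)CDF of control residuals. pv_case = 1 - F0(residual), so
# small placement values mean disease-like scores; F0 uses the mid-CDF to
# carry the Mann-Whitney 0.5 tie credit.
placement_values <- function(scores, case, ages) {
  stopifnot(length(ages) == length(scores), all(is.finite(ages)))
  if (sum(!case) < 10) stop("age adjustment needs at least 10 controls", call. = FALSE)
  fit <- stats::lm(scores[!case] ~ ages[!case])
  b <- stats::coef(fit)
  b[is.na(b)] <- 0 # constant covariate: intercept-only location model
  r0 <- scores[!case] - (b[1] + b[2] * ages[!case])
  case_age <- ages[case]
  rng <- range(ages[!case])
  if (any(case_age < rng[1] | case_age > rng[2])) {
    warning("case ages outside the control age range; extrapolating the location model",
            call. = FALSE)
  }
  pred <- b[1] + b[2] * case_age
  rc <- scores[case] - pred
  f0_mid <- vapply(rc, function(x) mean(r0 < x) + 0.5 * mean(r0 == x), 0)
  list(f0_case = f0_mid, pv_case = 1 - f0_mid)
}

#' Age-adjusted AUC via placement values
#'
#' Adjusts the ROC analysis for age by referring each case's score to the
#' age-matched control distribution: a linear location model of control
#' scores on age is fitted, each case residual is ranked against the control
#' residuals (empirical mid-CDF), and the covariate-adjusted AUC is the mean
#' of those ranks. With a constant covariate this reduces exactly to the
#' pooled Mann-Whitney AUC.
#'
#' @inheritParams auc
#' @param ages Numeric ages, one per record.
#' @return An `auc_estimate` with `adjustment = "age"`.
#' @export
age_adjusted_auc <- function(scores, labels, ages) {
  case <- as_case(labels)
  check_two_classes(case)
  pv <- placement_values(scores, case, ages)
  new_auc_estimate(mean(pv$f0_case), sum(case), sum(!case), "age")
}

#' Sensitivity at a fixed specificity
#'
#' Pooled: the operating threshold is the smallest score whose empirical
#' specificity (fraction of controls strictly below it) reaches the target;
#' sensitivity is the case fraction at or above that threshold. Age-adjusted:
#' the fraction of case placement values at or below `1 - target_spec`.
#'
#' @inheritParams auc
#' @param target_spec Target specificity, default 0.95.
#' @param adjusted Use the age-adjusted (placement value) version?
#' @param ages Required when `adjusted = TRUE`.
#' @return Sensitivity as a proportion in \[0, 1\].
#' @export
sensitivity_at_specificity <- function(scores, labels, target_spec = 0.95,
                                       adjusted = FALSE, ages = NULL) {
  case <- as_case(labels)
  check_two_classes(case)
  if (adjusted) {
    if (is.null(ages)) stop("ages are required for the adjusted version", call. = FALSE)
    pv <- placement_values(scores, case, ages)
    return(mean(pv$pv_case <= 1 - target_spec))
  }
  controls <- scores[!case]
  th_candidates <- sort(unique(scores))
  spec <- vapply(th_candidates, function(u) mean(controls < u), 0)
  ok <- spec >= target_spec
  if (!any(ok)) {
    th <- max(scores) + 1 # no attainable threshold: call nothing positive
  } else {
    th <- th_candidates[which(ok)[1]]
  }
  mean(scores[case] >= th)
}

#' Eye-level clustered bootstrap confidence interval
#'
#' Percentile bootstrap for an arbitrary statistic of a record set, with
#' resampling performed at the cluster (eye) level: whole clusters are drawn
#' with replacement and each drawn cluster contributes all of its records,
#' respecting within-eye correlation of repeated photos.
#'
#' @param statistic Function taking a data frame (a resampled record set)
#'   and returning a scalar.
#' @param records Data frame of records.
#' @param cluster_ids Cluster identifier per record (e.g. `subject_id:eye`).
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the CI is deterministic given the seed.
#' @return A list: `point` (statistic on the full data), `lower`, `upper`,
#'   `n_boot_used` (replicates where the statistic evaluated successfully;
#'   more than 10% failures is an error).
#' @export
cluster_bootstrap_ci <- function(statistic, records, cluster_ids,
                                 n_boot = 2000, level = 0.95, seed = 1L) {
  stopifnot(nrow(records) == length(cluster_ids))
  clusters <- unique(cluster_ids)
  if (length(clusters) < 2) stop("need at least 2 clusters", call. = FALSE)
  idx_by_cluster <- split(seq_len(nrow(records)), factor(cluster_ids, levels = clusters))
  point <- statistic(records)
  stopifnot(is.numeric(point), length(point) == 1)

  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      draw <- sample.int(length(clusters), replace = TRUE)
      rows <- unlist(idx_by_cluster[draw], use.names = FALSE)
      tryCatch(statistic(records[rows, , drop = FALSE]),
               error = function(e) NA_real_)
    }, 0)
  })
  failed <- sum(is.na(reps))
  if (failed > 0) {
    warning(sprintf("%d/%d bootstrap replicate(s) failed and were dropped", failed, n_boot),
            call. = FALSE)
    if (failed > 0.1 * n_boot) stop("more than 10% of bootstrap replicates failed", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps[!is.na(reps)], c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(point = point, lower = qs[1], upper = qs[2], n_boot_used = n_boot - failed)
}

#' Accuracy by disease severity
#'
#' Evaluates the score within Hodapp-Parrish-Anderson severity strata: each
#' stratum's cases are contrasted against all controls (normals appear once,
#' against every stratum). Strata with no cases yield an `NA` row.
#'
#' @inheritParams auc
#' @param stages Character severity stage per record (`NA` for controls).
#' @param ages Optional; when given, AUC and sensitivity are age-adjusted.
#' @param target_spec Specificity at which sensitivity is reported.
#' @return Data frame with rows overall / early / moderate / severe:
#'   `n_cases`, `n_controls`, `auc`, `sensitivity_at_spec`.
#' @export
evaluate_by_severity <- function(scores, labels, stages, ages = NULL,
                                 target_spec = 0.95) {
  case <- as_case(labels)
  check_two_classes(case)
  strata <- list(overall = case,
                 early = case & !is.na(stages) & stages == "early",
                 moderate = case & !is.na(stages) & stages == "moderate",
                 severe = case & !is.na(stages) & stages == "severe")
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]] | !case
    n1 <- sum(strata[[nm]])
    if (n1 == 0) {
      return(data.frame(stratum = nm, n_cases = 0L, n_controls = sum(!case),
                        auc = NA_real_, sensitivity_at_spec = NA_real_))
    }
    s <- scores[sel]; l <- case[sel]
    if (is.null(ages)) {
      a <- auc(s, l)$auc
      sens <- sensitivity_at_specificity(s, l, target_spec)
    } else {
      a <- age_adjusted_auc(s, l, ages[sel])$auc
      sens <- sensitivity_at_specificity(s, l, target_spec, adjusted = TRUE, ages = ages[sel])
    }
    data.frame(stratum = nm, n_cases = n1, n_controls = sum(!case),
               auc = a, sensitivity_at_spec = sens)
  })
  do.call(rbind, rows)
}

#' Suspect quartile contrast
#'
#' Divides suspect eyes into quartiles of the continuous score and contrasts
#' the highest against the lowest quartile on structural (global RNFL
#' thickness, mean and SD) and functional (SAP MD, median and IQR) damage,
#' with rank-sum (Wilcoxon) p-values. Repeated photos of an eye are treated
#' as records; the p-values carry the usual caveat that within-eye
#' correlation is ignored by the rank-sum test.
#'
#' @param suspects Data frame with columns `score`, `rnfl_global`, `md`.
#' @return A list: `summary` (two rows, lowest and highest quartile) and
#'   `p_rnfl`, `p_md` (rank-sum p-values), `n`.
#' @export
suspect_quartile_contrast <- function(suspects) {
  stopifnot(all(c("score", "rnfl_global", "md") %in% names(suspects)))
  if (nrow(suspects) < 8) stop("need at least 8 suspect records", call. = FALSE)
  q <- stats::quantile(suspects$score, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (q[1] == q[3]) stop("degenerate quartiles: scores carry no spread", call. = FALSE)
  s <- suspects$score
  bin <- 1L + (s > q[1]) + (s > q[2]) + (s > q[3]) # right-closed quartile bins

  lo <- suspects[bin == 1, ]; hi <- suspects[bin == 4, ]
  summarise_q <- function(d, which) {
    data.frame(
      quartile = which, n = nrow(d),
      score_median = stats::median(d$score),
      rnfl_mean = mean(d$rnfl_global), rnfl_sd = stats::sd(d$rnfl_global),
      md_median = stats::median(d$md),
      md_q1 = unname(stats::quantile(d$md, 0.25, type = 7)),
      md_q3 = unname(stats::quantile(d$md, 0.75, type = 7))
    )
  }
  list(
    summary = rbind(summarise_q(lo, "lowest"), summarise_q(hi, "highest")),
    p_rnfl = suppressWarnings(stats::wilcox.test(lo$rnfl_global, hi$rnfl_global)$p.value),
    p_md = suppressWarnings(stats::wilcox.test(lo$md, hi$md)$p.value),
    n = nrow(suspects)
  )
}
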