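## Quality control, temporal pairing and subject-level splitting --------------

#' Reliability and quality filters
#'
#' `filter_reliable_sap()` removes unreliable visual fields: tests with more
#' than 33% fixation losses or more than 15% false-positive errors are
#' excluded (strict "more than", so FL = 0.33 and FP = 0.15 are kept).
#' `filter_quality_sdoct()` removes RNFL scans with a device quality score
#' lower than 15 (so 15 is kept, 14 excluded).
#'
#' Both filters are conservative bookkeeping: `kept` plus `excluded` always
#' reconstitutes the input, and excluded rows carry a reason code.
#'
#' @param sap,scans Data frames in the SAP / SDOCT schema.
#' @param max_fl,max_fp Reliability thresholds (fractions).
#' @param min_quality Minimum acceptable quality score.
#' @return A list with `kept` and `excluded` (the latter with a `reason`
#'   column: `"fixation_loss"`, `"false_positive"` or `"low_quality"`).
#' @export
filter_reliable_sap <- function(sap, max_fl = 0.33, max_fp = 0.15) {
  bad_fl <- sap$fixation_loss_frac > max_fl
  bad_fp <- sap$false_positive_frac > max_fp
  reason <- ifelse(bad_fl, "fixation_loss", ifelse(bad_fp, "false_positive", NA))
  excluded <- sap[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(kept = resetrow(sap[is.na(reason), , drop = FALSE]), excluded = resetrow(excluded))
}

#' @rdname filter_reliable_sap
#' @export
filter_quality_sdoct <- function(scans, min_quality = 15) {
  bad <- scans$quality_score < min_quality
  excluded <- scans[bad, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- "low_quality"
  else excluded$reason <- character(0)
  list(kept = resetrow(scans[!bad, , drop = FALSE]), excluded = resetrow(excluded))
}

resetrow <- function(df) { rownames(df) <- NULL; df }

#' Pair SDOCT scans with SAP tests
#'
#' For each RNFL scan, selects the visual field of the same subject and eye
#' that minimises the absolute date gap, provided the gap is at most
#' `max_window_days` (default 180 days, the "within six months" window).
#' Each scan yields at most one pair; a single test may serve several scans.
#' Date ties break to the earlier test, and inputs are sorted internally so
#' the result is invariant to input row order.
#'
#' @param scans,tests QC-filtered data frames in the SDOCT / SAP schema.
#' @param max_window_days Maximum allowed |scan date - test date|, inclusive.
#' @return A list with `pairs` (one row per paired scan: all scan columns,
#'   all test columns, and `gap_days`) and `unpaired` (scans with no
#'   eligible test).
#' @export
pair_sdoct_sap <- function(scans, tests, max_window_days = 180) {
  scans <- sort_exams(scans, "scan_date")
  tests <- sort_exams(tests, "test_date")
  key_s <- paste(scans$subject_id, scans$eye, sep = "\r")
  key_t <- paste(tests$subject_id, tests$eye, sep = "\r")
  tests_by_key <- split(seq_len(nrow(tests)), key_t)

  pick <- rep(NA_integer_, nrow(scans))
  gap <- rep(NA_real_, nrow(scans))
  for (i in seq_len(nrow(scans))) {
    cand <- tests_by_key[[key_s[i]]]
    if (is.null(cand)) next
    g <- abs(as.numeric(tests$test_date[cand] - scans$scan_date[i]))
    ok <- g <= max_window_days
    if (!any(ok)) next
    cand <- cand[ok]; g <- g[ok]
    best <- which(g == min(g))
    # tie -> earlier test date (candidates are date-sorted)
    j <- cand[best[1]]
    pick[i] <- j
    gap[i] <- min(g)
  }
  paired <- !is.na(pick)
  pairs <- cbind(scans[paired, , drop = FALSE],
                 drop_cols(tests[pick[paired], , drop = FALSE], c("subject_id", "eye")))
  pairs$gap_days <- gap[paired]
  list(pairs = resetrow(pairs), unpaired = resetrow(scans[!paired, , drop = FALSE]))
}

drop_cols <- function(df, cols) resetrow(df[setdiff(names(df), cols)])

sort_exams <- function(df, date_col) {
  resetrow(df[order(df$subject_id, df$eye, df[[date_col]]), , drop = FALSE])
}

#' Match photos to SDOCT-SAP pairs
#'
#' Each photo is matched to the same-eye pair whose scan date is closest to
#' the photo date, within `max_window_days`. Several photos may share one
#' pair (photo counts exceed eye counts in practice); photos without an
#' eligible pair go to the `unmatched` side list. Ties break to the earlier
#' scan date.
#'
#' @param photos Data frame in the photo schema.
#' @param pairs The `pairs` element of [pair_sdoct_sap()].
#' @param max_window_days Maximum |photo date - scan date|, inclusive.
#' @return A list with `matched` (photo columns + the pair's columns +
#'   `photo_gap_days`) and `unmatched`.
#' @export
match_photos_to_pairs <- function(photos, pairs, max_window_days = 180) {
  photos <- sort_exams(photos, "photo_date")
  pairs <- sort_exams(pairs, "scan_date")
  key_p <- paste(photos$subject_id, photos$eye, sep = "\r")
  key_q <- paste(pairs$subject_id, pairs$eye, sep = "\r")
  pairs_by_key <- split(seq_len(nrow(pairs)), key_q)

  pick <- rep(NA_integer_, nrow(photos))
  gap <- rep(NA_real_, nrow(photos))
  for (i in seq_len(nrow(photos))) {
    cand <- pairs_by_key[[key_p[i]]]
    if (is.null(cand)) next
    g <- abs(as.numeric(pairs$scan_date[cand] - photos$photo_date[i]))
    ok <- g <= max_window_days
    if (!any(ok)) next
    cand <- cand[ok]; g <- g[ok]
    pick[i] <- cand[which(g == min(g))[1]]
    gap[i] <- min(g)
  }
  matched <- !is.na(pick)
  out <- cbind(photos[matched, , drop = FALSE],
               drop_cols(pairs[pick[matched], , drop = FALSE], c("subject_id", "eye")))
  out$photo_gap_days <- gap[matched]
  list(matched = resetrow(out), unmatched = resetrow(photos[!matched, , drop = FALSE]))
}

#' Subject-level train/test split
#'
#' Splits records into training and test sets by randomly partitioning the
#' distinct subject identifiers, so no subject contributes to both sets.
#' The number of training subjects is `round(train_fraction * n_subjects)`.
#'
#' @param records Data frame with a `subject_id` column.
#' @param train_fraction Fraction of subjects assigned to training, in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with `train` and `test` data frames.
#' @export
split_by_subject <- function(records, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  subjects <- sort(unique(records$subject_id))
  n_train <- round(train_fraction * length(subjects))
  train_ids <- with_seed(seed, sample(subjects, n_train))
  in_train <- records$subject_id %in% train_ids
  list(train = resetrow(records[in_train, , drop = FALSE]),
       test = resetrow(records[!in_train, , drop = FALSE]))
}

# Run expr under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
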