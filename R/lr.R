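## Interval likelihood ratios and post-test probability -----------------------

#' Default score bin edges (percent)
#'
#' The probability-scale binning used for the interval likelihood-ratio
#' table: 0-0.1, 0.1-1, 1-10, 10-50, 50-90, 90-99, 99-99.9, 99.9-100 (%).
#' @return Numeric vector of 9 edges from 0 to 100.
#' @export
default_bin_edges <- function() c(0, 0.1, 1, 10, 50, 90, 99, 99.9, 100)

#' Bin continuous scores on the percent scale
#'
#' Bins are left-closed and right-open except the last, which is closed:
#' \[0, 0.1), \[0.1, 1), ..., \[99.9, 100\]. A score of exactly an interior
#' edge therefore falls in the upper bin.
#'
#' @param scores Probabilities in \[0, 1\].
#' @param edges_percent Strictly increasing edges spanning 0 to 100.
#' @return Integer bin index per score (1-based).
#' @export
bin_scores <- function(scores, edges_percent = default_bin_edges()) {
  check_edges(edges_percent)
  if (any(!is.finite(scores) | scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  pct <- scores * 100
  b <- findInterval(pct, edges_percent, rightmost.closed = TRUE, left.open = FALSE)
  b
}

check_edges <- function(edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0) ||
      edges[1] != 0 || edges[length(edges)] != 100) {
    stop("edges_percent must be strictly increasing from 0 to 100", call. = FALSE)
  }
}

bin_labels <- function(edges) {
  k <- length(edges) - 1
  sprintf("%g-%g", edges[-(k + 1)], edges[-1])
}

#' Interval likelihood-ratio table
#'
#' For each score bin, the interval likelihood ratio is the probability of a
#' score in that bin among the diseased divided by the probability of the
#' same bin among the non-diseased:
#' `LR(bin) = [n_dis(bin) / N_dis] / [n_non(bin) / N_non]`.
#' Bins where only diseased eyes fall have infinite LR (flagged); empty bins
#' have undefined (NaN) LR. An optional Haldane-style +0.5 continuity
#' correction for zero cells is available and off by default.
#'
#' `lr_table_from_counts()` builds the same table directly from per-bin
#' counts (e.g. a published contingency table).
#'
#' @param scores,labels As in [auc()]; suspects must already be excluded.
#' @param edges_percent Bin edges on the percent scale.
#' @param continuity Add 0.5 to every cell before forming the ratios?
#' @return An object of class `lr_table` (a data frame): `bin`, `bin_label`,
#'   `n_diseased`, `n_nondiseased`, `n_total`, `lr` (raw), `lr_printed`
#'   (rounded for reporting: 2 decimals below 10, 3 significant figures at
#'   or above 10), `effect` (see [lr_effect_category()]).
#' @export
interval_lr_table <- function(scores, labels, edges_percent = default_bin_edges(),
                              continuity = FALSE) {
  case <- as_case(labels)
  check_two_classes(case)
  b <- bin_scores(scores, edges_percent)
  k <- length(edges_percent) - 1
  n_dis <- tabulate(b[case], nbins = k)
  n_non <- tabulate(b[!case], nbins = k)
  lr_table_from_counts(n_dis, n_non, edges_percent, continuity)
}

#' @rdname interval_lr_table
#' @param n_diseased,n_nondiseased Integer per-bin counts, one per bin.
#' @export
lr_table_from_counts <- function(n_diseased, n_nondiseased,
                                 edges_percent = default_bin_edges(),
                                 continuity = FALSE) {
  check_edges(edges_percent)
  k <- length(edges_percent) - 1
  stopifnot(length(n_diseased) == k, length(n_nondiseased) == k,
            all(n_diseased >= 0), all(n_nondiseased >= 0))
  d <- n_diseased; h <- n_nondiseased
  if (continuity) { d <- d + 0.5; h <- h + 0.5 }
  p_dis <- d / sum(d)
  p_non <- h / sum(h)
  lr <- p_dis / p_non # 0/0 -> NaN (undefined), x/0 -> Inf (flagged by is.infinite)
  out <- data.frame(
    bin = seq_len(k),
    bin_label = bin_labels(edges_percent),
    n_diseased = n_diseased,
    n_nondiseased = n_nondiseased,
    n_total = n_diseased + n_nondiseased,
    lr = lr,
    lr_printed = format_lr(lr),
    effect = lr_effect_category(lr)
  )
  structure(out, class = c("lr_table", "data.frame"),
            edges_percent = edges_percent)
}

#' Printed-precision rounding of a likelihood ratio
#'
#' Report convention: two decimals for LR below 10, three significant
#' figures at or above 10. Raw values are always retained alongside.
#'
#' @param lr Numeric likelihood ratio(s).
#' @return Numeric vector at printed precision.
#' @export
format_lr <- function(lr) {
  ifelse(is.nan(lr), NaN,
         ifelse(is.infinite(lr), Inf,
                ifelse(lr < 10, round(lr, 2), signif(lr, 3))))
}

#' Post-test probability from a likelihood ratio
#'
#' Bayes on the odds scale: post-test odds = LR x pre-test odds; returned as
#' a probability. Pre-test probabilities of exactly 0 or 1 are fixed points.
#'
#' @param pretest Pre-test probability in \[0, 1\] (vectorised).
#' @param lr Positive likelihood ratio (vectorised; `Inf` allowed).
#' @return Post-test probability in \[0, 1\].
#' @export
posttest_probability <- function(pretest, lr) {
  if (any(!is.finite(pretest) | pretest < 0 | pretest > 1)) {
    stop("pretest must be in [0, 1]", call. = FALSE)
  }
  if (any(is.nan(lr) | lr <= 0)) stop("lr must be positive", call. = FALSE)
  odds <- lr * pretest / (1 - pretest)
  out <- odds / (1 + odds)
  out[pretest == 0] <- 0
  out[pretest == 1] <- 1
  out[is.infinite(lr) & pretest > 0] <- 1
  out
}

#' Effect-size category of a likelihood ratio
#'
#' Interpretation bands: LRs above 10 or below 0.1 produce large changes in
#' post-test probability; 5-10 or 0.1-0.2 moderate; 2-5 or 0.2-0.5 small;
#' anything nearer one is insignificant.
#'
#' @param lr Positive likelihood ratio(s); `Inf` maps to `"large"`.
#' @return Character vector in
#'   `{"large", "moderate", "small", "insignificant"}` (`NA` for NaN input).
#' @export
lr_effect_category <- function(lr) {
  out <- rep(NA_character_, length(lr))
  known <- !is.nan(lr)
  x <- lr[known]
  out[known] <- ifelse(x > 10 | x < 0.1, "large",
                ifelse((x > 5 & x <= 10) | (x >= 0.1 & x < 0.2), "moderate",
                ifelse((x > 2 & x <= 5) | (x >= 0.2 & x < 0.5), "small",
                       "insignificant")))
  out
}

#' Mass of scores in the extreme bins
#'
#' Fraction of all scores falling in designated extreme bins; with the
#' default binning these are scores below 0.1% or at/above 99% (bins 1, 7
#' and 8), the region where the test gives conclusive evidence.
#'
#' @inheritParams bin_scores
#' @param extreme_bins Integer indices of the extreme bins.
#' @return Proportion in \[0, 1\].
#' @export
extreme_mass <- function(scores, edges_percent = default_bin_edges(),
                         extreme_bins = c(1L, 7L, 8L)) {
  b <- bin_scores(scores, edges_percent)
  mean(b %in% extreme_bins)
}

#' @rdname extreme_mass
#' @param bin_totals Per-bin totals (all groups combined).
#' @export
extreme_mass_from_counts <- function(bin_totals, extreme_bins = c(1L, 7L, 8L)) {
  stopifnot(all(bin_totals >= 0), sum(bin_totals) > 0,
            all(extreme_bins >= 1), all(extreme_bins <= length(bin_totals)))
  sum(bin_totals[extreme_bins]) / sum(bin_totals)
}
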