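## Agreement between objective and subjective classifications -----------------

#' Three-grader adjudication
#'
#' Consensus grade over the ordered vocabulary normal < suspect < glaucoma:
#' when the first two graders agree their grade stands; otherwise the third
#' grader's assessment resolves the disagreement.
#'
#' @param grade1,grade2 First two graders' labels (vectorised).
#' @param grade3 Third grader's labels; may be `NA` where the first two
#'   agree, but must be present wherever they disagree.
#' @return Character vector of consensus grades.
#' @export
adjudicate <- function(grade1, grade2, grade3 = NA_character_) {
  n <- length(grade1)
  grade3 <- rep_len(grade3, n)
  chk <- function(g, allow_na = FALSE) {
    ok <- g %in% gon_labels() | (allow_na & is.na(g))
    if (!all(ok)) stop("grades must be in {normal, suspect, glaucoma}", call. = FALSE)
  }
  chk(grade1); chk(grade2); chk(grade3, allow_na = TRUE)
  disagree <- grade1 != grade2
  if (any(disagree & is.na(grade3))) {
    stop("grade3 required where grade1 != grade2", call. = FALSE)
  }
  ifelse(disagree, grade3, grade1)
}

#' Confusion table of objective vs subjective labels
#'
#' @param objective,subjective Label vectors over the ordered categories
#'   normal < suspect < glaucoma.
#' @return A k x k contingency `table` (rows objective, columns subjective).
#' @export
gon_confusion <- function(objective, subjective) {
  lv <- gon_labels()
  stopifnot(all(objective %in% lv), all(subjective %in% lv))
  table(objective = factor(objective, levels = lv),
        subjective = factor(subjective, levels = lv))
}

kappa_weights <- function(k, weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  if (weighting == "linear") 1 - d / (k - 1) else 1 - d^2 / (k - 1)^2
}

#' Weighted kappa
#'
#' Chance-corrected agreement for ordered categories, with linear weights
#' `w_ij = 1 - |i - j| / (k - 1)` (default) or quadratic weights
#' `w_ij = 1 - (i - j)^2 / (k - 1)^2`. Kappa is
#' `(P_o(w) - P_e(w)) / (1 - P_e(w))` with the chance term from the marginal
#' products. On a 2x2 table both weightings reduce to unweighted Cohen's
#' kappa.
#'
#' @param tab A square contingency table or matrix of counts, categories in
#'   identical order on both axes.
#' @param weighting `"linear"` or `"quadratic"`.
#' @return Kappa in \[-1, 1\]; `NaN` with a warning when the chance-expected
#'   weighted agreement is 1 (degenerate single-category marginals).
#' @export
weighted_kappa <- function(tab, weighting = c("linear", "quadratic")) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0), sum(tab) > 0)
  w <- kappa_weights(nrow(tab), weighting)
  p <- tab / sum(tab)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (isTRUE(all.equal(pe, 1))) {
    warning("degenerate marginals: chance-expected weighted agreement is 1; kappa undefined",
            call. = FALSE)
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Weighted percent agreement
#'
#' Observed weighted proportion of agreement, `100 * sum(w_ij p_ij)`, using
#' the same weights as [weighted_kappa()]. Adjacent-category disagreements
#' receive partial credit.
#'
#' @inheritParams weighted_kappa
#' @return Percent in \[0, 100\].
#' @export
weighted_agreement <- function(tab, weighting = c("linear", "quadratic")) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0), sum(tab) > 0)
  w <- kappa_weights(nrow(tab), weighting)
  100 * sum(w * tab / sum(tab))
}
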