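## Objective GON reference standard -------------------------------------------
##
## The classification rests on correspondence between structural loss on the
## SDOCT RNFL scan and functional loss on SAP: global loss (global RNFL flag
## outside normal limits + abnormal field), or a localized superior RNFL
## defect with inferior-hemifield depression (and vice versa). Exam pairs
## meeting neither the glaucoma nor the normal criteria are suspects.

#' Hemifield mean deviation
#'
#' The superior (inferior) hemifield MD is the unweighted mean of the 26
#' total-deviation values with y > 0 (y < 0) on the 24-2 grid.
#'
#' @param sap Data frame in the SAP schema (or any frame carrying the 52
#'   canonical `td_*` columns).
#' @return Data frame with `superior_md` and `inferior_md` (dB), one row per
#'   input row.
#' @export
hemifield_md <- function(sap) {
  sup <- td_columns("superior")
  inf <- td_columns("inferior")
  missing <- setdiff(c(sup, inf), names(sap))
  if (length(missing) > 0) {
    stop(sprintf("hemifield_md: %d td column(s) missing (e.g. %s)",
                 length(missing), missing[1]), call. = FALSE)
  }
  data.frame(
    superior_md = rowMeans(as.matrix(sap[sup])),
    inferior_md = rowMeans(as.matrix(sap[inf]))
  )
}

#' Normative hemifield-MD cutoffs
#'
#' Derives the abnormality cutoffs for superior and inferior hemifield MD as
#' an empirical percentile (default 5th, i.e. "P < 5%") of the per-eye
#' hemifield MDs of a healthy reference sample, with linear interpolation
#' between order statistics. Two eyes per subject are treated as independent
#' observations for the percentile point estimate.
#'
#' @param healthy_sap Data frame of healthy reference SAP tests.
#' @param percentile Percentile in (0, 50); default 5.
#' @return An object of class `gon_cutoffs`: `superior_cutoff`,
#'   `inferior_cutoff` (dB), `percentile`, `n_reference_eyes`.
#' @export
derive_hemifield_cutoffs <- function(healthy_sap, percentile = 5) {
  if (is.null(healthy_sap) || nrow(healthy_sap) == 0) {
    stop("derive_hemifield_cutoffs: empty reference sample", call. = FALSE)
  }
  if (percentile <= 0 || percentile >= 50) {
    stop("percentile must be in (0, 50)", call. = FALSE)
  }
  if (nrow(healthy_sap) < 40) {
    warning(sprintf("only %d reference eyes (< 40); cutoffs will be unstable",
                    nrow(healthy_sap)), call. = FALSE)
  }
  h <- hemifield_md(healthy_sap)
  structure(
    list(
      superior_cutoff = unname(stats::quantile(h$superior_md, percentile / 100, type = 7)),
      inferior_cutoff = unname(stats::quantile(h$inferior_md, percentile / 100, type = 7)),
      percentile = percentile,
      n_reference_eyes = nrow(healthy_sap)
    ),
    class = "gon_cutoffs"
  )
}

#' @export
print.gon_cutoffs <- function(x, ...) {
  cat(sprintf("Hemifield MD cutoffs (%gth percentile of %d reference eyes):\n",
              x$percentile, x$n_reference_eyes))
  cat(sprintf("  superior: %.2f dB\n  inferior: %.2f dB\n",
              x$superior_cutoff, x$inferior_cutoff))
  invisible(x)
}

#' Classify exam pairs as glaucoma, normal or suspect
#'
#' Applies the objective GON definition to SDOCT-SAP pairs. A pair is
#' **glaucoma** if any criterion fires:
#' \enumerate{
#'   \item global loss: global RNFL flag `outside` AND (GHT
#'     `outside_normal_limits` OR PSD p-category significant, i.e. anything
#'     other than `not_significant`);
#'   \item localized superior loss: TS or NS flag `outside` AND inferior
#'     hemifield MD strictly below the inferior cutoff;
#'   \item localized inferior loss: TI or NI flag `outside` AND superior
#'     hemifield MD strictly below the superior cutoff.
#' }
#' A pair is **normal** only if the global flag and all six sector flags are
#' `within`, GHT is `within_normal_limits` and PSD is `not_significant`.
#' Everything else (including borderline findings and isolated structural or
#' functional abnormality) is **suspect**.
#'
#' @param pairs Data frame of exam pairs (see [pair_sdoct_sap()]): flag
#'   columns, `ght`, `psd_p`, and the 52 `td_*` columns (or precomputed
#'   `superior_md` / `inferior_md`).
#' @param cutoffs A `gon_cutoffs` object from [derive_hemifield_cutoffs()].
#' @return The input with columns `superior_md`, `inferior_md`, `label`
#'   (`"glaucoma"` / `"normal"` / `"suspect"`), the three per-criterion
#'   indicator columns `crit_global_loss`,
#'   `crit_superior_structural_inferior_functional`,
#'   `crit_inferior_structural_superior_functional`, and `stage`
#'   (Hodapp-Parrish-Anderson severity, `NA` for non-glaucoma rows).
#' @export
classify_gon <- function(pairs, cutoffs) {
  stopifnot(inherits(cutoffs, "gon_cutoffs"))
  flag_cols <- paste0("flag_", c("global", rnfl_sectors()))
  missing <- setdiff(c(flag_cols, "ght", "psd_p"), names(pairs))
  if (length(missing) > 0) {
    stop(sprintf("classify_gon: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (cc in flag_cols) {
    if (anyNA(pairs[[cc]]) || !all(pairs[[cc]] %in% flag_levels())) {
      stop(sprintf("classify_gon: invalid or missing flag in %s", cc), call. = FALSE)
    }
  }
  if (!all(c("superior_md", "inferior_md") %in% names(pairs))) {
    pairs <- cbind(pairs, hemifield_md(pairs))
  }

  out <- gon_decision(
    flag_global = pairs$flag_global,
    flag_TS = pairs$flag_TS, flag_NS = pairs$flag_NS,
    flag_TI = pairs$flag_TI, flag_NI = pairs$flag_NI,
    flag_T = pairs$flag_T, flag_N = pairs$flag_N,
    ght = pairs$ght, psd_p = pairs$psd_p,
    inferior_below = pairs$inferior_md < cutoffs$inferior_cutoff,
    superior_below = pairs$superior_md < cutoffs$superior_cutoff
  )
  pairs$label <- out$label
  pairs$crit_global_loss <- out$crit1
  pairs$crit_superior_structural_inferior_functional <- out$crit2
  pairs$crit_inferior_structural_superior_functional <- out$crit3
  if (!is.null(pairs$md)) {
    pairs$stage <- ifelse(pairs$label == "glaucoma", severity_stage(pairs$md), NA_character_)
  }
  pairs
}

# Vectorised decision core, shared by classify_gon and kept minimal so an
# independent predicate oracle can be compared against it exhaustively.
gon_decision <- function(flag_global, flag_TS, flag_NS, flag_TI, flag_NI,
                         flag_T, flag_N, ght, psd_p,
                         inferior_below, superior_below) {
  sap_abnormal <- ght == "outside_normal_limits" | psd_p != "not_significant"
  crit1 <- flag_global == "outside" & sap_abnormal
  crit2 <- (flag_TS == "outside" | flag_NS == "outside") & inferior_below
  crit3 <- (flag_TI == "outside" | flag_NI == "outside") & superior_below
  all_within <- flag_global == "within" & flag_T == "within" & flag_TS == "within" &
    flag_NS == "within" & flag_N == "within" & flag_NI == "within" & flag_TI == "within"
  normal <- all_within & ght == "within_normal_limits" & psd_p == "not_significant"
  glaucoma <- crit1 | crit2 | crit3
  label <- ifelse(glaucoma, "glaucoma", ifelse(normal, "normal", "suspect"))
  list(label = label, crit1 = crit1, crit2 = crit2, crit3 = crit3)
}

#' Hodapp-Parrish-Anderson severity stage
#'
#' Stages glaucomatous eyes by visual-field damage: early for MD above
#' -6 dB, moderate for MD in \[-12, -6\] dB (closed on both ends), severe
#' below -12 dB. Only meaningful for eyes labelled glaucoma.
#'
#' @param md SAP mean deviation (dB), vectorised.
#' @return Character vector in `{"early", "moderate", "severe"}`.
#' @export
severity_stage <- function(md) {
  ifelse(md > -6, "early", ifelse(md >= -12, "moderate", "severe"))
}
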