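# Fixture builders and independent oracles used across the test files.

# --- table builders ----------------------------------------------------------

# A SAP test row with every td value settable; td may be a scalar, a length-52
# vector (grid order), or a list(superior =, inferior =) of scalars/26-vectors.
sap_frame <- function(n = 1, td = 0, md = NULL, psd = 1, psd_p = "not_significant",
                      ght = "within_normal_limits", fl = 0.1, fp = 0.05,
                      subject_id = sprintf("S%03d", seq_len(n)), eye = "OD",
                      test_date = as.Date("2021-06-01")) {
  g <- grid24_points()
  tdm <- matrix(0, n, 52, dimnames = list(NULL, g$col))
  if (is.list(td)) {
    tdm[, g$col[g$y > 0]] <- matrix(td$superior, n, 26, byrow = TRUE)
    tdm[, g$col[g$y < 0]] <- matrix(td$inferior, n, 26, byrow = TRUE)
  } else {
    tdm[] <- matrix(td, n, 52, byrow = TRUE)
  }
  df <- data.frame(subject_id = rep_len(subject_id, n), eye = rep_len(eye, n),
                   test_date = rep_len(test_date, n),
                   md = if (is.null(md)) rowMeans(tdm) else rep_len(md, n),
                   psd = rep_len(psd, n), psd_p = rep_len(psd_p, n),
                   ght = rep_len(ght, n),
                   fixation_loss_frac = rep_len(fl, n),
                   false_positive_frac = rep_len(fp, n))
  cbind(df, as.data.frame(tdm))
}

sdoct_frame <- function(n = 1, quality = 25, global = 98, sectors = 100,
                        flags = "within", subject_id = sprintf("S%03d", seq_len(n)),
                        eye = "OD", scan_date = as.Date("2021-06-01")) {
  df <- data.frame(subject_id = rep_len(subject_id, n), eye = rep_len(eye, n),
                   scan_date = rep_len(scan_date, n),
                   quality_score = rep_len(quality, n),
                   rnfl_global = rep_len(global, n))
  for (s in rnfl_sectors()) df[[paste0("rnfl_", s)]] <- rep_len(sectors, n)
  df$flag_global <- rep_len(flags, n)
  for (s in rnfl_sectors()) df[[paste0("flag_", s)]] <- rep_len(flags, n)
  df
}

photo_frame <- function(n = 1, score = 0.5, subject_id = sprintf("S%03d", seq_len(n)),
                        eye = "OD", photo_date = as.Date("2021-06-01")) {
  data.frame(subject_id = rep_len(subject_id, n), eye = rep_len(eye, n),
             photo_date = rep_len(photo_date, n), score = rep_len(score, n),
             camera_id = "cam_A")
}

# Minimal exam-pair frame for classify_gon: flags + SAP categories +
# precomputed hemifield MDs.
pair_frame <- function(flag_global = "within", flag_T = "within", flag_TS = "within",
                       flag_NS = "within", flag_N = "within", flag_NI = "within",
                       flag_TI = "within", ght = "within_normal_limits",
                       psd_p = "not_significant", superior_md = 0, inferior_md = 0,
                       md = 0) {
  data.frame(flag_global = flag_global, flag_T = flag_T, flag_TS = flag_TS,
             flag_NS = flag_NS, flag_N = flag_N, flag_NI = flag_NI,
             flag_TI = flag_TI, ght = ght, psd_p = psd_p,
             superior_md = superior_md, inferior_md = inferior_md, md = md)
}

# Cutoffs object with known thresholds (bypasses derivation).
fixed_cutoffs <- function(superior = 0, inferior = 0, percentile = 5, n = 462) {
  structure(list(superior_cutoff = superior, inferior_cutoff = inferior,
                 percentile = percentile, n_reference_eyes = n),
            class = "gon_cutoffs")
}

# --- independent oracles -----------------------------------------------------

# All-pairs Mann-Whitney concordance, written as the literal double loop
# definition (0.5 credit for ties).
auc_oracle <- function(scores, case) {
  cs <- scores[case]; ct <- scores[!case]
  total <- 0
  for (a in cs) for (b in ct) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cs) * length(ct))
}

# Scalar re-statement of the objective GON definition as three independent
# predicates plus the normality rule, coded separately from the package's
# vectorised decision.
gon_oracle <- function(fg, ft, fts, fns, fn, fni, fti, ght, psd_p,
                       sup_below, inf_below) {
  sap_abn <- (ght == "outside_normal_limits") || (psd_p != "not_significant")
  c1 <- (fg == "outside") && sap_abn
  c2 <- (fts == "outside" || fns == "outside") && inf_below
  c3 <- (fti == "outside" || fni == "outside") && sup_below
  if (c1 || c2 || c3) return("glaucoma")
  all_flags_within <- all(c(fg, ft, fts, fns, fn, fni, fti) == "within")
  if (all_flags_within && ght == "within_normal_limits" && psd_p == "not_significant") {
    return("normal")
  }
  "suspect"
}

label_rank <- function(lab) match(lab, c("normal", "suspect", "glaucoma"))
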