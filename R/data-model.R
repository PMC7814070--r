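#' @keywords internal
"_PACKAGE"

## Controlled vocabularies ----------------------------------------------------

#' Controlled vocabularies of the data model
#'
#' Category levels used throughout the package. RNFL normality flags follow
#' the three-level device classification; GHT and PSD p-value categories
#' follow the perimeter's printout vocabulary.
#'
#' @name vocab
#' @return Character vectors of the admissible levels.
#' @export
rnfl_sectors <- function() c("T", "TS", "NS", "N", "NI", "TI")

#' @rdname vocab
#' @export
flag_levels <- function() c("within", "borderline", "outside")

#' @rdname vocab
#' @export
ght_levels <- function() {
  c("within_normal_limits", "borderline", "outside_normal_limits",
    "general_reduction", "abnormally_high")
}

#' @rdname vocab
#' @export
psd_p_levels <- function() c("not_significant", "lt5", "lt2", "lt1", "lt0.5")

#' @rdname vocab
#' @export
gon_labels <- function() c("normal", "suspect", "glaucoma")

eye_levels <- function() c("OD", "OS")

## Schemas --------------------------------------------------------------------

sdoct_columns <- function() {
  c("subject_id", "eye", "scan_date", "quality_score",
    paste0("rnfl_", c("global", rnfl_sectors())),
    paste0("flag_", c("global", rnfl_sectors())))
}

sap_columns <- function() {
  c("subject_id", "eye", "test_date", "md", "psd", "psd_p", "ght",
    "fixation_loss_frac", "false_positive_frac", td_columns())
}

photo_columns <- function() {
  c("subject_id", "eye", "photo_date", "score", "camera_id")
}

subject_columns <- function() c("subject_id", "age", "sex", "race")

## Validation report ----------------------------------------------------------

new_validation_report <- function(n_input, accepted, rejected) {
  stopifnot(nrow(accepted) + nrow(rejected) == n_input)
  structure(
    list(n_input = n_input, n_accepted = nrow(accepted),
         n_rejected = nrow(rejected), rejected = rejected),
    class = "gon_validation_report"
  )
}

#' @export
print.gon_validation_report <- function(x, ...) {
  cat(sprintf("Validation: %d rows in, %d accepted, %d rejected\n",
              x$n_input, x$n_accepted, x$n_rejected))
  if (x$n_rejected > 0) {
    tab <- table(x$rejected$reason)
    for (r in names(tab)) cat(sprintf("  %-20s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

## Row-level validators -------------------------------------------------------

# Each validator returns a character vector of reasons, one entry per row,
# NA_character_ where the row is acceptable. Validation is total: every row
# is either accepted or carries a reason.

parse_iso_date <- function(x) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
  d[is.na(x) | !grepl("^\\d{4}-\\d{2}-\\d{2}$", as.character(x))] <- NA
  d
}

num_ok <- function(x, lower = -Inf, upper = Inf, open = FALSE) {
  is.finite(x) & if (open) x > lower & x < upper else x >= lower & x <= upper
}

validate_sdoct_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag_cols <- paste0("flag_", c("global", rnfl_sectors()))
  thick_cols <- paste0("rnfl_", c("global", rnfl_sectors()))

  bad_date <- is.na(parse_iso_date(df$scan_date))
  bad_num <- !num_ok(df$quality_score)
  for (cc in thick_cols) bad_num <- bad_num | is.na(suppressWarnings(as.numeric(df[[cc]])))
  reason[is.na(reason) & (bad_date | bad_num)] <- "parse_error"

  unk <- rep(FALSE, nrow(df))
  for (cc in flag_cols) unk <- unk | !(as.character(df[[cc]]) %in% flag_levels())
  reason[is.na(reason) & unk] <- "unknown_flag"

  viol <- df$quality_score < 0
  for (cc in thick_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    viol <- viol | !num_ok(v, 0, 250, open = TRUE)
  }
  bad_eye <- !(as.character(df$eye) %in% eye_levels())
  reason[is.na(reason) & (viol | bad_eye)] <- "invariant_violation"
  reason
}

validate_sap_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad_date <- is.na(parse_iso_date(df$test_date))
  bad_num <- !num_ok(df$md) | !num_ok(df$psd)
  for (cc in td_columns()) bad_num <- bad_num | is.na(suppressWarnings(as.numeric(df[[cc]])))
  reason[is.na(reason) & (bad_date | bad_num)] <- "parse_error"

  unk <- !(as.character(df$psd_p) %in% psd_p_levels()) |
    !(as.character(df$ght) %in% ght_levels())
  reason[is.na(reason) & unk] <- "unknown_category"

  viol <- df$psd < 0 |
    !num_ok(df$fixation_loss_frac, 0, 1) |
    !num_ok(df$false_positive_frac, 0, 1) |
    !(as.character(df$eye) %in% eye_levels())
  reason[is.na(reason) & viol] <- "invariant_violation"
  reason
}

validate_photo_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad_date <- is.na(parse_iso_date(df$photo_date))
  bad_num <- is.na(suppressWarnings(as.numeric(df$score)))
  reason[is.na(reason) & (bad_date | bad_num)] <- "parse_error"
  viol <- !num_ok(df$score, 0, 1) | !(as.character(df$eye) %in% eye_levels())
  reason[is.na(reason) & viol] <- "invariant_violation"
  reason
}

validate_subject_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad_num <- is.na(suppressWarnings(as.numeric(df$age)))
  reason[is.na(reason) & bad_num] <- "parse_error"
  reason[is.na(reason) & !num_ok(df$age, 18, 110)] <- "invariant_violation"
  reason
}
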