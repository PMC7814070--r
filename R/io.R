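## CSV readers / writers ------------------------------------------------------
##
## All tables are comma-separated UTF-8 with "." decimal and ISO 8601 dates;
## no dialect sniffing. Readers are total: each input row is either returned
## in `$data` (typed) or listed in `$report$rejected` with a reason code.

read_table_impl <- function(path, required_cols, validator, typer, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  missing <- setdiff(required_cols, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  raw <- raw[required_cols]
  typed <- typer(raw) # numeric coercion; failures become NA -> parse_error

  reason <- validator(typed)
  accepted <- typed[is.na(reason), , drop = FALSE]
  rejected <- data.frame(row = which(!is.na(reason)),
                         reason = reason[!is.na(reason)])
  rownames(accepted) <- NULL
  list(data = accepted,
       report = new_validation_report(nrow(raw), accepted, rejected))
}

as_num_cols <- function(df, cols) {
  for (cc in cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df
}

#' Read the input tables
#'
#' Readers for the four delimited input tables: SDOCT peripapillary RNFL
#' scans, SAP 24-2 visual fields, per-photo continuous GON scores, and
#' subject demographics. Column schemas are fixed (see the README); a missing
#' mandatory column is a schema error, while rows that fail parsing, use an
#' unknown category token, or violate a type invariant are rejected with a
#' reason code into the validation report rather than silently dropped.
#'
#' @param path Path to a CSV file.
#' @return A list with `data` (a typed data frame of the accepted rows) and
#'   `report` (a `gon_validation_report`: row counts and the rejected rows
#'   with reasons; `accepted + rejected = input`).
#' @seealso [write_sdoct_table()] and friends for the inverse operation.
#' @export
read_sdoct_table <- function(path) {
  typer <- function(df) {
    df <- as_num_cols(df, c("quality_score", paste0("rnfl_", c("global", rnfl_sectors()))))
    df$scan_date_parsed <- parse_iso_date(df$scan_date)
    df
  }
  res <- read_table_impl(path, sdoct_columns(), validate_sdoct_rows, typer, "sdoct table")
  res$data$scan_date <- res$data$scan_date_parsed
  res$data$scan_date_parsed <- NULL
  res
}

#' @rdname read_sdoct_table
#' @export
read_sap_table <- function(path) {
  typer <- function(df) {
    df <- as_num_cols(df, c("md", "psd", "fixation_loss_frac",
                            "false_positive_frac", td_columns()))
    df$test_date_parsed <- parse_iso_date(df$test_date)
    df
  }
  res <- read_table_impl(path, sap_columns(), validate_sap_rows, typer, "sap table")
  res$data$test_date <- res$data$test_date_parsed
  res$data$test_date_parsed <- NULL
  res
}

#' @rdname read_sdoct_table
#' @export
read_photo_table <- function(path) {
  typer <- function(df) {
    df <- as_num_cols(df, "score")
    df$photo_date_parsed <- parse_iso_date(df$photo_date)
    df
  }
  res <- read_table_impl(path, photo_columns(), validate_photo_rows, typer, "photo table")
  res$data$photo_date <- res$data$photo_date_parsed
  res$data$photo_date_parsed <- NULL
  dup <- duplicated(res$data[c("subject_id", "eye", "photo_date", "score")])
  if (any(dup)) {
    warning(sprintf("%d duplicated photo row(s) retained (multiple photos per visit are legal)",
                    sum(dup)), call. = FALSE)
  }
  res
}

#' @rdname read_sdoct_table
#' @export
read_subject_table <- function(path) {
  typer <- function(df) as_num_cols(df, "age")
  read_table_impl(path, subject_columns(), validate_subject_rows, typer, "subject table")
}

#' Write the input tables
#'
#' Writers mirroring the readers; `write` then `read` is the identity on the
#' accepted records (dates serialised as ISO 8601).
#'
#' @param df A data frame in the corresponding table schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sdoct_table <- function(df, path) write_table_impl(df, sdoct_columns(), path)

#' @rdname write_sdoct_table
#' @export
write_sap_table <- function(df, path) write_table_impl(df, sap_columns(), path)

#' @rdname write_sdoct_table
#' @export
write_photo_table <- function(df, path) write_table_impl(df, photo_columns(), path)

#' @rdname write_sdoct_table
#' @export
write_subject_table <- function(df, path) write_table_impl(df, subject_columns(), path)

write_table_impl <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("cannot write table: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- df[cols]
  for (cc in names(out)) if (inherits(out[[cc]], "Date")) out[[cc]] <- format(out[[cc]], "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
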