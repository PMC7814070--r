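#' The 24-2 test point grid
#'
#' Coordinates (degrees of visual angle) of the 52 non-blind-spot points of
#' the 24-2 perimetry pattern, in mapped right-eye (OD) orientation: positive
#' `y` is the superior hemifield, the two blind-spot points at (15, +/-3) are
#' excluded and the 30-degree nasal column sits at x = -27. Left-eye (OS)
#' fields are expected in the same mapped orientation; all classification
#' rules in this package use only the vertical axis, so laterality never
#' enters the superior/inferior logic.
#'
#' @return A data frame with columns `x`, `y` (degrees) and `col` (the
#'   canonical column name used for total-deviation values in SAP tables,
#'   e.g. `"td_n27p03"`), 52 rows, 26 per hemifield.
#' @examples
#' g <- grid24_points()
#' table(sign(g$y))
#' @export
grid24_points <- function() {
  rows <- list(
    `21` = c(-9, -3, 3, 9),
    `15` = c(-15, -9, -3, 3, 9, 15),
    `9`  = c(-21, -15, -9, -3, 3, 9, 15, 21),
    `3`  = c(-27, -21, -15, -9, -3, 3, 9, 21) # (15, 3) is the blind spot
  )
  x <- y <- integer(0)
  for (yy in c(21, 15, 9, 3)) {
    xs <- rows[[as.character(yy)]]
    x <- c(x, xs, xs)
    y <- c(y, rep(yy, length(xs)), rep(-yy, length(xs)))
  }
  ord <- order(-y, x)
  g <- data.frame(x = x[ord], y = y[ord])
  g$col <- td_col_name(g$x, g$y)
  g
}

td_col_name <- function(x, y) {
  sprintf(
    "td_%s%02d%s%02d",
    ifelse(x < 0, "n", "p"), abs(x),
    ifelse(y < 0, "n", "p"), abs(y)
  )
}

#' Canonical total-deviation column names
#'
#' @param hemifield `"all"`, `"superior"` (y > 0) or `"inferior"` (y < 0).
#' @return Character vector of column names (52, or 26 per hemifield).
#' @export
td_columns <- function(hemifield = c("all", "superior", "inferior")) {
  hemifield <- match.arg(hemifield)
  g <- grid24_points()
  switch(hemifield,
    all = g$col,
    superior = g$col[g$y > 0],
    inferior = g$col[g$y < 0]
  )
}
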