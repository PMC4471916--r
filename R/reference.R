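#' Published per-population song-measure summary (reference table)
#'
#' The printed mean, SD and CV of the nine song measures for the 20-male
#' field population, shipped as a plain-text reference. Useful for
#' consistency checks of the CV computation and as calibration anchors for
#' the synthetic generator. Note the buzz repertoire row: its printed SD
#' (1, rounded from about 1.65) is inconsistent with its printed CV (0.33)
#' under rounding, so that row must not be used as a CV consistency check.
#'
#' @return Data frame: measure, mean, sd, cv_printed.
#' @export
reference_song_measures <- function() {
  path <- system.file("extdata", "table1_reference.csv", package = "nightsong")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' CV from reported moments, at presentation precision
#'
#' Sample-SD-over-mean coefficient of variation rounded to the conventional
#' two decimals, as used in published summary tables.
#'
#' @param mean,sd numeric vectors.
#' @param digits rounding (default 2).
#' @return Numeric vector.
#' @export
cv_from_moments <- function(mean, sd, digits = 2L) {
  if (any(mean == 0)) stop_input("CV undefined for zero mean")
  round(sd / mean, digits)
}
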