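# Packaged site-level summary table for the 17 Illinois River Basin
# monitoring sites.

#' Published IRB site-level metabolism summaries
#'
#' Site-level summary statistics for the 17 Illinois River Basin sites of
#' the USGS metabolism data release (doi:10.5066/P9TEBOUR): unflagged-day
#' counts and percentages, time-averaged discharge, GPP, ER and NEP (g O2
#' m-2 d-1), percent of days autotrophic (NEP > 0), the river group, the
#' preferred depth-estimation method, and the overall confidence rating.
#' Basin-level aggregates (e.g. via [basin_rollup()]) computed from this
#' table reproduce the release's reported basin means.
#'
#' @return tibble with one row per site
#' @export
irb_site_summaries <- function() {
  path <- system.file("extdata", "irb_site_summaries.csv",
                      package = "rivermet", mustWork = TRUE)
  .read_csv_quiet(path, col_types = readr::cols(
    nwis_no = readr::col_character()))
}
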