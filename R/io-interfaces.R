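# Readers/writers for the canonical CSV dialects of the data-release
# workflow, site configuration, and provenance headers.

.series_schemas <- list(
  do = list(cols = c("site_no", "dateTime", "do_mgl"), kind = "do"),
  temp = list(cols = c("site_no", "dateTime", "temp_c"), kind = "temp"),
  sal = list(cols = c("site_no", "dateTime", "salinity_psu"), kind = "sal"),
  barop = list(cols = c("site_no", "dateTime", "press_mb"),
               kind = "pressure"),
  disch_gage = list(cols = c("site_no", "dateTime", "discharge_cms",
                             "gage_height_m"), kind = "discharge"),
  field_meas = list(cols = c("site_no", "date", "width_m", "area_m2",
                             "gage_height_m", "discharge_cms", "rating"),
                    kind = "field_meas"),
  model_input = list(cols = c("solar.time", "DO.obs", "DO.sat", "depth",
                              "temp.water", "light", "discharge"),
                     kind = "model_input"),
  daily_output = list(cols = c("date", "GPP", "GPP.sd", "ER", "ER.sd",
                               "K600", "K600.sd", "NEP", "R2_det"),
                      kind = "daily_output")
)

.read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read a canonical time-series CSV
#'
#' Validates the expected header for the file kind (unknown extra columns
#' are preserved, never dropped), parses timestamps to UTC, and sorts
#' out-of-order rows with a warning.
#'
#' @param path file path
#' @param kind one of `"do"`, `"temp"`, `"sal"`, `"barop"`,
#'   `"disch_gage"`, `"field_meas"`, `"model_input"`, `"daily_output"`
#' @param col_map optional named character vector remapping canonical
#'   column names to the names actually present in the file
#' @return tibble; time-series kinds gain a POSIXct `datetime` column and
#'   a `value` column (plus `value2` = gage height for `disch_gage`)
#' @export
read_series <- function(path, kind, col_map = NULL) {
  kind <- match.arg(kind, names(.series_schemas))
  schema <- .series_schemas[[kind]]
  if (!file.exists(path)) stop("file not found: ", path)
  x <- .read_csv_quiet(path)
  want <- schema$cols
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      names(x)[names(x) == col_map[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(want, names(x))
  if (length(missing_cols)) {
    stop(sprintf("file '%s' does not match the '%s' schema: missing %s",
                 path, kind, paste(missing_cols, collapse = ", ")))
  }
  if (kind %in% c("do", "temp", "sal", "barop", "disch_gage")) {
    x$datetime <- as.POSIXct(x$dateTime, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                            "%Y-%m-%d %H:%M:%S",
                                            "%Y-%m-%dT%H:%M:%S"))
    if (is.unsorted(x$datetime, na.rm = TRUE)) {
      warning("out-of-order timestamps in ", basename(path), "; sorted")
      x <- x[order(x$datetime), , drop = FALSE]
    }
    vcol <- setdiff(want, c("site_no", "dateTime"))
    x$value <- x[[vcol[1]]]
    if (length(vcol) > 1) x$value2 <- x[[vcol[2]]]
  }
  if (kind == "model_input") {
    x$solar.time <- as.POSIXct(x$solar.time, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                              "%Y-%m-%d %H:%M:%S"))
  }
  if (kind == "daily_output") x$date <- as.Date(x$date)
  x
}

.provenance_header <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("rivermet"))
  hash <- if (is.null(config)) "none" else {
    s <- paste(utils::capture.output(utils::str(config)), collapse = "")
    sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %%
              .Machine$integer.max)
  }
  c(sprintf("# rivermet %s", ver),
    sprintf("# config_hash: %s", hash),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed))
}

#' Write a CSV with a provenance comment header
#'
#' Comment lines record the package version, a config hash, and the master
#' seed; identical inputs rewrite byte-identically.
#'
#' @param x data.frame
#' @param path destination
#' @param seed,config provenance fields
#' @return `path`, invisibly
#' @export
write_series <- function(x, path, seed = NULL, config = NULL) {
  x <- as.data.frame(x)
  for (nm in names(x)) {
    if (inherits(x[[nm]], "POSIXct")) {
      x[[nm]] <- format(x[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
  }
  con <- file(path, "wb")  # binary: stable newlines across platforms
  on.exit(close(con))
  writeLines(.provenance_header(seed, config), con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write flagged and censored daily output files
#'
#' Emits the two per-site CSVs following the data-release naming pattern
#' `flagged_GPP_ER_K600_<date>_depth-<fm|hgc>_<site>.csv` and
#' `censored_GPP_ER_K600_...csv`, plus a small metadata stub documenting
#' the columns.
#'
#' @param daily daily metabolism tibble
#' @param flags output of [apply_flags()]
#' @param dir output directory
#' @param site_no site identifier embedded in the filenames
#' @param depth_method `"rating"` (token `fm`) or `"hydraulic"` (`hgc`)
#' @param date_label date token for the filenames
#' @param seed,config provenance fields
#' @return named character vector of the paths written
#' @export
write_daily_outputs <- function(daily, flags, dir, site_no,
                                depth_method = c("rating", "hydraulic"),
                                date_label = format(Sys.Date()),
                                seed = NULL, config = NULL) {
  if (nrow(daily) == 0) stop("empty daily results; nothing to write")
  depth_method <- match.arg(depth_method)
  token <- if (depth_method == "rating") "fm" else "hgc"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flagged <- cbind(daily, flags)
  censored <- censor(daily, flags)
  fp <- file.path(dir, sprintf("flagged_GPP_ER_K600_%s_depth-%s_%s.csv",
                               date_label, token, site_no))
  cp <- file.path(dir, sprintf("censored_GPP_ER_K600_%s_depth-%s_%s.csv",
                               date_label, token, site_no))
  mp <- file.path(dir, sprintf("metadata_GPP_ER_K600_%s_depth-%s_%s.txt",
                               date_label, token, site_no))
  write_series(flagged, fp, seed = seed, config = config)
  write_series(censored, cp, seed = seed, config = config)
  writeLines(c(
    "Columns: date; GPP, ER, NEP and posterior sd in g O2 m-2 d-1;",
    "K600 and sd in 1/day; R2_det dimensionless; n_obs per day;",
    "flag1_low_snr, flag2_gpp, flag3_er, flag4_k600, any_flag logical.",
    "Censored file removes days with any flag."), mp)
  invisible(c(flagged = fp, censored = cp, metadata = mp))
}

#' Read a site configuration file
#'
#' YAML file holding the per-site facts the workflow needs: identifiers,
#' coordinates, preferred depth-estimation method, distance to the nearest
#' upstream flow-regulation structure, optional replacement-discharge
#' site, hydraulic-geometry coefficients, and input paths.
#'
#' @param path YAML file
#' @return a `site_config` list
#' @export
read_site_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("site_id", "latitude", "longitude", "depth_method")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) stop("site config missing fields: ",
                         paste(miss, collapse = ", "))
  if (!cfg$depth_method %in% c("rating", "hydraulic")) {
    stop("depth_method must be 'rating' or 'hydraulic'")
  }
  if (abs(cfg$latitude) > 90 || abs(cfg$longitude) > 180) {
    stop("coordinates out of range")
  }
  cfg$upstream_structure_distance_m <-
    cfg$upstream_structure_distance_m %||% NA_real_
  structure(cfg, class = "site_config")
}
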