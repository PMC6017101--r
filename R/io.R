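# comma-delimited UTF-8 with header; tab accepted on read; '.' decimal only
read_delimited <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    locale = readr::locale(decimal_mark = ".")
  )
}

#' Read dose-effect series from a delimited file
#'
#' Expects a header with columns `agent_id`, `dose_mg_per_ml`, and exactly
#' one of `fraction_affected` or `percent_inhibition` (percent is converted
#' to a fraction). Comma or tab delimited. Every problem is reported with
#' the data row number and field so it can be fixed at the source.
#'
#' @param path Path to the file.
#' @return A tibble with columns `agent_id`, `dose`, `fraction_affected`,
#'   one row per point, grouped order preserved from the file.
#' @export
read_dose_effect <- function(path) {
  data <- read_delimited(path)
  require_columns(data, c("agent_id", "dose_mg_per_ml"), "read_dose_effect")
  has_fa <- "fraction_affected" %in% names(data)
  has_pct <- "percent_inhibition" %in% names(data)
  if (has_fa == has_pct) {
    abort("read_dose_effect: need exactly one of columns `fraction_affected` or `percent_inhibition`")
  }

  dose <- suppressWarnings(as.numeric(data$dose_mg_per_ml))
  bad <- which(is.na(dose))
  if (length(bad) > 0) {
    abort(sprintf("read_dose_effect: row %d, field dose_mg_per_ml: non-numeric value '%s'",
      bad[1], as.character(data$dose_mg_per_ml[bad[1]])))
  }
  bad <- which(dose <= 0)
  if (length(bad) > 0) {
    abort(sprintf("read_dose_effect: row %d, field dose_mg_per_ml: dose must be > 0 (got %g)",
      bad[1], dose[bad[1]]))
  }

  raw <- if (has_fa) data$fraction_affected else data$percent_inhibition
  field <- if (has_fa) "fraction_affected" else "percent_inhibition"
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val))
  if (length(bad) > 0) {
    abort(sprintf("read_dose_effect: row %d, field %s: non-numeric value '%s'",
      bad[1], field, as.character(raw[bad[1]])))
  }
  fa <- if (has_fa) val else val / 100
  bad <- which(fa < 0 | fa > 1)
  if (length(bad) > 0) {
    abort(sprintf("read_dose_effect: row %d, field %s: value %g maps outside [0, 1]",
      bad[1], field, val[bad[1]]))
  }

  tibble::tibble(
    agent_id = as.character(data$agent_id),
    dose = dose,
    fraction_affected = fa
  )
}

#' Write dose-effect series to the standard CSV
#'
#' The on-disk schema is `agent_id`, `dose_mg_per_ml`, `fraction_affected`,
#' the format [read_dose_effect()] reads back; the round trip preserves
#' values exactly.
#'
#' @param data A tibble with `agent_id`, `dose` (or `dose_mg_per_ml`) and
#'   `fraction_affected`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_effect <- function(data, path) {
  if ("dose" %in% names(data) && !"dose_mg_per_ml" %in% names(data)) {
    data <- dplyr::rename(data, dose_mg_per_ml = "dose")
  }
  require_columns(data, c("agent_id", "dose_mg_per_ml", "fraction_affected"), "write_dose_effect")
  readr::write_csv(
    dplyr::select(data, "agent_id", "dose_mg_per_ml", "fraction_affected"),
    path
  )
  invisible(path)
}
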