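#' Read a cell field from CSV
#'
#' Comma-separated, header required, `.` decimal separator, UTF-8. Required
#' columns: `cell_id`, `area_m2`, `depth_m`, `velocity_ms`; optional:
#' `grain_d_m`, `hsi`. Missing required columns, non-numeric cells and
#' duplicate ids are reported with row/column context.
#'
#' @param path CSV file path.
#' @return a [cell_field()].
#' @export
read_cell_field <- function(path) {
  if (!file.exists(path)) .stopf("cell field file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("cell_id", "area_m2", "depth_m", "velocity_ms")
  miss <- setdiff(required, names(df))
  if (length(miss)) .stopf("%s: missing column(s): %s", path,
                           paste(miss, collapse = ", "))
  for (col in intersect(c("area_m2", "depth_m", "velocity_ms", "grain_d_m", "hsi"),
                        names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) .stopf("%s: non-numeric value '%s' in column %s, row %d",
                              path, v[bad[1]], col, bad[1])
      df[[col]] <- num
    }
  }
  cell_field(cell_id = df$cell_id, area_m2 = df$area_m2, depth_m = df$depth_m,
             velocity_ms = df$velocity_ms,
             grain_d_m = if ("grain_d_m" %in% names(df)) df$grain_d_m else NA_real_,
             hsi = if ("hsi" %in% names(df)) df$hsi else NA_real_)
}

#' Write a cell field to CSV
#'
#' Full precision (up to 15 significant digits) so that
#' `read_cell_field(write_cell_field(x))` round-trips numerically.
#'
#' @param field a [cell_field()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_field <- function(field, path) {
  stopifnot(inherits(field, "data.frame"))
  df <- as.data.frame(field)
  for (col in names(df)) if (is.numeric(df[[col]]))
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                        sprintf("%.15g", df[[col]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a period schedule from CSV
#'
#' Columns exactly: `period`, `discharge_m3s`, `water_level_m`, `manning`,
#' `temperature_C`.
#'
#' @param path CSV file path.
#' @return data.frame of class `period_schedule`.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) .stopf("schedule file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("period", "discharge_m3s", "water_level_m", "manning",
                "temperature_C")
  miss <- setdiff(required, names(df))
  if (length(miss)) .stopf("%s: missing column(s): %s", path,
                           paste(miss, collapse = ", "))
  if (anyDuplicated(df$period))
    .stopf("%s: duplicate period label '%s'", path,
           df$period[duplicated(df$period)][1])
  for (col in required[-1]) if (!is.numeric(df[[col]]))
    .stopf("%s: column %s must be numeric", path, col)
  if (any(df$discharge_m3s <= 0)) .stopf("%s: discharge must be positive", path)
  class(df) <- c("period_schedule", "data.frame")
  df
}

#' Write a habitat summary table as TSV
#'
#' Human-facing layout: `Period`, `WUA_1e5_m2` (2 decimals), `WUA_m2` (full
#' precision), `OSI` (2 decimals), `ISP`, `MSP`, `LSP` (percent, 2 decimals).
#'
#' @param rows a `habitat_summary` data.frame (rows from
#'   [summarize_habitat()] or [run_schedule()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  out <- data.frame(Period = rows$period,
                    WUA_1e5_m2 = sprintf("%.2f", rows$wua_m2 / 1e5),
                    WUA_m2 = sprintf("%.15g", rows$wua_m2),
                    OSI = sprintf("%.2f", rows$osi),
                    ISP = sprintf("%.2f", rows$isp),
                    MSP = sprintf("%.2f", rows$msp),
                    LSP = sprintf("%.2f", rows$lsp))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a model-comparison table as TSV
#'
#' Relative changes (%) of each metric after incorporating substrate;
#' undefined entries (baseline metric zero) are written as `NA`.
#'
#' @param rows a `comparison_table` data.frame from [compare_models()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(rows, path) {
  fmt <- function(x) ifelse(is.finite(x), sprintf("%.2f", x), "NA")
  out <- data.frame(Period = rows$period, WUA = fmt(rows$wua_change),
                    OSI = fmt(rows$osi_change), ISP = fmt(rows$isp_change),
                    MSP = fmt(rows$msp_change), LSP = fmt(rows$lsp_change))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
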