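#' Construct a cell field
#'
#' A cell field is the per-cell hydraulic table of one period: cell id, cell
#' area (m^2), water depth (m), depth-averaged velocity (m/s), and optionally
#' bed grain size (m) and HSI. Dry cells carry `NA` depth/velocity and are
#' excluded from the habitat metrics.
#'
#' @param cell_id unique cell identifiers.
#' @param area_m2 cell areas (m^2), positive.
#' @param depth_m water depths (m); `NA` marks a dry cell.
#' @param velocity_ms depth-averaged velocities (m/s); `NA` marks a dry cell.
#' @param grain_d_m optional bed grain sizes (m).
#' @param hsi optional habitat suitability indices in `[0, 1]`.
#' @return data.frame of class `cell_field`.
#' @export
cell_field <- function(cell_id, area_m2, depth_m, velocity_ms,
                       grain_d_m = NA_real_, hsi = NA_real_) {
  n <- length(cell_id)
  if (n < 1L) .stopf("cell field needs at least one cell")
  if (anyDuplicated(cell_id)) .stopf("duplicate cell id: %s",
                                     cell_id[duplicated(cell_id)][1])
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0))
    .stopf("cell areas must be finite and positive")
  df <- data.frame(cell_id = cell_id, area_m2 = as.numeric(area_m2),
                   depth_m = as.numeric(rep_len(depth_m, n)),
                   velocity_ms = as.numeric(rep_len(velocity_ms, n)),
                   grain_d_m = as.numeric(rep_len(grain_d_m, n)),
                   hsi = as.numeric(rep_len(hsi, n)))
  ok <- is.finite(df$hsi)
  if (any(df$hsi[ok] < 0 | df$hsi[ok] > 1)) .stopf("hsi must lie in [0, 1]")
  class(df) <- c("cell_field", "data.frame")
  df
}

# wetted cells: those with usable hydraulics
.wetted <- function(cells, require_hsi = FALSE) {
  stopifnot(inherits(cells, "data.frame"))
  wet <- is.finite(cells$depth_m) & is.finite(cells$velocity_ms)
  ndry <- sum(!wet)
  if (ndry > 0) .msg(sprintf("excluding %d dry cell(s)", ndry))
  cells <- cells[wet, , drop = FALSE]
  if (!nrow(cells)) .stopf("no wetted cells")
  if (require_hsi && any(!is.finite(cells$hsi)))
    .stopf("HSI missing for %d wetted cell(s)", sum(!is.finite(cells$hsi)))
  cells
}

#' Habitat metric thresholds
#'
#' @param ideal HSI cutoff of the ideal class (default 0.7, inclusive).
#' @param low HSI cutoff of the low-suitability class (default 0.3,
#'   exclusive from above).
#' @return an object of class `metric_thresholds`.
#' @export
metric_thresholds <- function(ideal = 0.7, low = 0.3) {
  stopifnot(is.numeric(ideal), is.numeric(low), 0 < low, low < ideal, ideal < 1)
  structure(list(ideal = ideal, low = low), class = "metric_thresholds")
}

#' Weighted usable area
#'
#' `WUA = sum(A_i * HSI_i)` over wetted cells (m^2).
#'
#' @param cells a [cell_field()] with HSI present.
#' @return WUA in m^2.
#' @export
wua <- function(cells) {
  cells <- .wetted(cells, require_hsi = TRUE)
  sum(cells$area_m2 * cells$hsi)
}

#' Overall suitability index
#'
#' `OSI = WUA / sum(A_i)`, the area-weighted mean HSI over wetted cells.
#'
#' @inheritParams wua
#' @return OSI, dimensionless in `[0, 1]`.
#' @export
osi <- function(cells) {
  cells <- .wetted(cells, require_hsi = TRUE)
  total <- sum(cells$area_m2)
  if (total <= 0) .stopf("zero total wetted area")
  sum(cells$area_m2 * cells$hsi) / total
}

#' Suitability class proportions
#'
#' Area percentages of wetted cells in the ideal (`HSI >= 0.7`), moderate
#' (`0.3 <= HSI < 0.7`) and low (`HSI < 0.3`) classes, with the half-open
#' boundaries exactly as published.
#'
#' @inheritParams wua
#' @param thresholds a [metric_thresholds()].
#' @return named numeric vector `c(ISP =, MSP =, LSP =)` in percent, summing
#'   to 100.
#' @export
suitability_proportions <- function(cells, thresholds = metric_thresholds()) {
  cells <- .wetted(cells, require_hsi = TRUE)
  total <- sum(cells$area_m2)
  isp <- sum(cells$area_m2[cells$hsi >= thresholds$ideal]) / total * 100
  msp <- sum(cells$area_m2[cells$hsi >= thresholds$low &
                           cells$hsi < thresholds$ideal]) / total * 100
  lsp <- sum(cells$area_m2[cells$hsi < thresholds$low]) / total * 100
  c(ISP = isp, MSP = msp, LSP = lsp)
}

#' Summarise a cell field into one reach-level row
#'
#' Bundles WUA, OSI and the three class proportions; values are kept at full
#' precision internally (rounding is a display concern of the writers).
#'
#' @inheritParams suitability_proportions
#' @param period period label for the row.
#' @return data.frame of class `habitat_summary` with columns `period`,
#'   `wua_m2`, `osi`, `isp`, `msp`, `lsp`.
#' @export
summarize_habitat <- function(cells, thresholds = metric_thresholds(),
                              period = NA_character_) {
  props <- suitability_proportions(cells, thresholds)
  out <- data.frame(period = period, wua_m2 = wua(cells), osi = osi(cells),
                    isp = props[["ISP"]], msp = props[["MSP"]],
                    lsp = props[["LSP"]])
  class(out) <- c("habitat_summary", "data.frame")
  out
}
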