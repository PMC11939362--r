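#' Evaluate one period: substrate, suitability, reach metrics
#'
#' Fills bed grain size by inverting the threshold-velocity formula per cell
#' (unless the field already carries `grain_d_m`), evaluates the fuzzy model
#' on every wetted cell with the period's scalar temperature, and aggregates
#' the reach-level summary.
#'
#' @param cells a [cell_field()] with depth and velocity.
#' @param cond a [period_conditions()] row (supplies temperature and label).
#' @param rb a [rule_base()].
#' @param vars fuzzy variables, see [default_fuzzy_variables()].
#' @param spec a [defuzzify_spec()].
#' @param thresholds a [metric_thresholds()].
#' @param params a [sediment_params()] for grain-size inversion.
#' @return list with `cells` (HSI and grain size filled) and `summary`
#'   (one [summarize_habitat()] row).
#' @export
run_period <- function(cells, cond, rb = default_rule_base(),
                       vars = default_fuzzy_variables(),
                       spec = defuzzify_spec(),
                       thresholds = metric_thresholds(),
                       params = sediment_params()) {
  stopifnot(inherits(cells, "data.frame"))
  cond <- as.list(cond)
  wet <- is.finite(cells$depth_m) & is.finite(cells$velocity_ms)
  if (!any(wet)) .stopf("period '%s': no wetted cells", cond$period)
  if (is.null(cells$grain_d_m)) cells$grain_d_m <- NA_real_
  need_d <- wet & !is.finite(cells$grain_d_m)
  if (any(need_d)) {
    inv <- tryCatch(
      invert_grain_size(cells$velocity_ms[need_d], cells$depth_m[need_d], params),
      error = function(e) .stopf("period '%s', cell %s: %s", cond$period,
                                 cells$cell_id[which(need_d)[1]],
                                 conditionMessage(e)))
    cells$grain_d_m[need_d] <- inv$d
  }
  hsi <- tryCatch(
    evaluate_hsi(rb, vars,
                 substrate = cells$grain_d_m[wet],
                 temperature = cond$temperature_C,
                 velocity = cells$velocity_ms[wet],
                 depth = cells$depth_m[wet], spec = spec),
    error = function(e) .stopf("period '%s', cell %s: %s", cond$period,
                               cells$cell_id[which(wet)[1]],
                               conditionMessage(e)))
  cells$hsi <- NA_real_
  cells$hsi[wet] <- hsi
  list(cells = cells,
       summary = summarize_habitat(cells, thresholds, period = cond$period))
}

#' Evaluate a full semi-monthly schedule
#'
#' Maps [run_period()] over the schedule rows and stacks the summaries into
#' a table shaped like the published per-period assessment.
#'
#' @param fields named list of [cell_field()]s, one per schedule row, with
#'   names matching the `period` labels (e.g. from [generate_fields()]).
#' @param schedule a period schedule, see [read_schedule()] /
#'   [default_schedule()].
#' @inheritParams run_period
#' @return `habitat_summary` data.frame, one row per period.
#' @export
run_schedule <- function(fields, schedule, rb = default_rule_base(),
                         vars = default_fuzzy_variables(),
                         spec = defuzzify_spec(),
                         thresholds = metric_thresholds(),
                         params = sediment_params()) {
  if (nrow(schedule) == 0L) {
    out <- data.frame(period = character(), wua_m2 = numeric(),
                      osi = numeric(), isp = numeric(), msp = numeric(),
                      lsp = numeric())
    class(out) <- c("habitat_summary", "data.frame")
    return(out)
  }
  miss <- setdiff(schedule$period, names(fields))
  if (length(miss)) .stopf("no cell field for period(s): %s",
                           paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(schedule)), function(i)
    run_period(fields[[schedule$period[i]]], schedule[i, ], rb = rb,
               vars = vars, spec = spec, thresholds = thresholds,
               params = params)$summary)
  out <- do.call(rbind, rows)
  class(out) <- c("habitat_summary", "data.frame")
  out
}

#' Derive the substrate-free baseline rule base
#'
#' Rebuilds the three-factor model the four-factor base was developed from:
#' substrate-blocking rows (antecedents confined to substrate `VL`/`VH`) are
#' dropped, every remaining substrate antecedent becomes `AC`, the rules are
#' expanded and de-duplicated, and where deleting the substrate clause makes
#' two rules disagree the lower consequent is kept — the published table
#' upgrades combinations where substrate is favourable, so removing the
#' substrate clause must recover the pre-upgrade grade.
#'
#' @param rb4 the four-factor [rule_base()].
#' @return a [rule_base()] with provenance `"3-factor-baseline"`.
#' @export
build_baseline <- function(rb4) {
  stopifnot(inherits(rb4, "rule_base"))
  keep <- Filter(function(r) any(r$antecedent$substrate %in% c("L", "M", "H")),
                 rb4$rules)
  if (!length(keep)) .stopf("no non-blocking rules to build a baseline from")
  ex <- do.call(rbind, lapply(keep, function(r) {
    g <- expand.grid(temperature = r$antecedent$temperature,
                     velocity = r$antecedent$velocity,
                     depth = r$antecedent$depth, stringsAsFactors = FALSE)
    g$consequent <- r$consequent
    g
  }))
  key <- do.call(paste, ex[c("temperature", "velocity", "depth")])
  resolved <- vapply(split(ex$consequent, key), function(cs)
    GRADES[min(.grade_rank(cs))], character(1))
  first <- !duplicated(key)
  ante <- ex[first, c("temperature", "velocity", "depth")]
  cons <- resolved[key[first]]
  rules <- lapply(seq_len(nrow(ante)), function(i)
    fuzzy_rule(substrate = GRADES, temperature = ante$temperature[i],
               velocity = ante$velocity[i], depth = ante$depth[i],
               consequent = cons[i]))
  rule_base(rules, provenance = "3-factor-baseline")
}

#' Compare the substrate-inclusive model against the baseline
#'
#' Runs the four-factor and three-factor models on identical inputs and
#' reports the per-period relative change `(with - without) / without * 100`
#' of each reach metric. Entries whose baseline value is zero are flagged
#' `NaN` rather than raising an error.
#'
#' @inheritParams run_schedule
#' @param rb4 the four-factor [rule_base()].
#' @param rb3 the baseline; defaults to [build_baseline()] of `rb4`.
#' @return data.frame of class `comparison_table` with the per-period
#'   relative changes (%) of WUA, OSI, ISP, MSP, LSP, plus both raw WUA
#'   columns for reference.
#' @export
compare_models <- function(fields, schedule, rb4 = default_rule_base(),
                           rb3 = build_baseline(rb4),
                           vars = default_fuzzy_variables(),
                           spec = defuzzify_spec(),
                           thresholds = metric_thresholds(),
                           params = sediment_params()) {
  with_s <- run_schedule(fields, schedule, rb = rb4, vars = vars, spec = spec,
                         thresholds = thresholds, params = params)
  without <- run_schedule(fields, schedule, rb = rb3, vars = vars, spec = spec,
                          thresholds = thresholds, params = params)
  rel <- function(a, b) ifelse(b == 0, ifelse(a == b, 0, NaN), (a - b) / b * 100)
  out <- data.frame(period = with_s$period,
                    wua_change = rel(with_s$wua_m2, without$wua_m2),
                    osi_change = rel(with_s$osi, without$osi),
                    isp_change = rel(with_s$isp, without$isp),
                    msp_change = rel(with_s$msp, without$msp),
                    lsp_change = rel(with_s$lsp, without$lsp),
                    wua_with_m2 = with_s$wua_m2,
                    wua_without_m2 = without$wua_m2)
  class(out) <- c("comparison_table", "data.frame")
  out
}
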