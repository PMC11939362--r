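#' Sediment parameters for the threshold-velocity formula
#'
#' Densities enter only through the relative submerged density
#' `(rho_s - rho) / rho`, so the customary g/cm^3 values are used as printed;
#' all lengths and velocities are SI.
#'
#' @param rho_s sediment density (g/cm^3, default 2.65).
#' @param rho water density (g/cm^3, default 1.0).
#' @param cohesive_coef coefficient of the cohesive/viscous term
#'   (default 6.05e-7, SI as used in the formula).
#' @param d_max upper solver bracket for grain diameter (m, default 2).
#' @return an object of class `sediment_params`.
#' @export
sediment_params <- function(rho_s = 2.65, rho = 1.0,
                            cohesive_coef = 6.05e-7, d_max = 2) {
  stopifnot(rho_s > rho, rho > 0, cohesive_coef >= 0, d_max > 0)
  structure(list(rho_s = rho_s, rho = rho, cohesive_coef = cohesive_coef,
                 d_max = d_max), class = "sediment_params")
}

#' Critical (incipient-motion) velocity of a bed grain
#'
#' Threshold depth-averaged velocity at which a grain of diameter `d` on the
#' bed of a flow of depth `h` begins to move:
#' `Ue = (h/d)^0.14 * (17.6 * (rho_s - rho)/rho * d
#'        + 6.05e-7 * (10 + h) / d^0.72)^0.5`.
#' The gravity term dominates for coarse grains; the second (cohesive) term
#' diverges as `d -> 0`, making `Ue` U-shaped in `d`.
#'
#' @param h water depth (m), positive; recycled against `d`.
#' @param d grain diameter (m), positive.
#' @param params a [sediment_params()].
#' @return critical velocity (m/s).
#' @export
critical_velocity <- function(h, d, params = sediment_params()) {
  if (any(!is.finite(h)) || any(!is.finite(d)) || any(h <= 0) || any(d <= 0))
    .stopf("critical_velocity: h and d must be finite and positive")
  rel <- (params$rho_s - params$rho) / params$rho
  (h / d)^0.14 * sqrt(17.6 * rel * d + params$cohesive_coef * (10 + h) / d^0.72)
}

#' Locate the minimum of the critical-velocity curve in grain size
#'
#' The threshold-velocity formula is U-shaped in `d`; grain-size inversion
#' uses the coarse (increasing) branch, which starts at this minimum.
#' Golden-section search ([stats::optimize()]) over `log d` on
#' `[1e-6, d_max]` m to relative tolerance 1e-8.
#'
#' @param h water depth (m), scalar or vector.
#' @param params a [sediment_params()].
#' @return data.frame with `d_min` (argmin, m) and `ue_min` (m/s), one row
#'   per element of `h`.
#' @export
ue_minimum <- function(h, params = sediment_params()) {
  if (any(!is.finite(h)) || any(h <= 0)) .stopf("ue_minimum: h must be positive")
  res <- vapply(h, function(hi) {
    opt <- stats::optimize(function(ld) critical_velocity(hi, exp(ld), params),
                           interval = log(c(1e-6, params$d_max)), tol = 1e-9)
    c(exp(opt$minimum), opt$objective)
  }, numeric(2))
  data.frame(d_min = res[1, ], ue_min = res[2, ])
}

#' Invert the threshold-velocity formula for bed grain size
#'
#' Estimates the bed-surface grain diameter whose critical velocity equals
#' the local velocity, i.e. reverse-calculates the substrate from the flow.
#' The solve is restricted to the coarse (monotone increasing) branch
#' `d in [d_min, d_max]` by bisection to relative tolerance 1e-6. Velocities
#' below the attainable minimum clamp to the branch point; velocities beyond
#' `Ue(h, d_max)` clamp to `d_max` — both flagged.
#'
#' @param velocity depth-averaged velocity (m/s), `>= 0`; recycled against
#'   `depth`.
#' @param depth water depth (m), positive.
#' @param params a [sediment_params()].
#' @return data.frame with `d` (grain diameter, m) and logical `clamped`.
#' @examples
#' p <- sediment_params()
#' ue <- critical_velocity(10, 0.25, p)
#' invert_grain_size(ue, 10, p)$d  # ~0.25
#' @export
invert_grain_size <- function(velocity, depth, params = sediment_params()) {
  if (any(!is.finite(velocity)) || any(!is.finite(depth)) ||
      any(velocity < 0) || any(depth <= 0))
    .stopf("invert_grain_size: velocity must be >= 0 and depth > 0, both finite")
  n <- max(length(velocity), length(depth))
  u <- rep_len(as.numeric(velocity), n)
  h <- rep_len(as.numeric(depth), n)
  mins <- ue_minimum(h, params)
  d <- numeric(n)
  clamped <- logical(n)

  lo_clamp <- u <= mins$ue_min
  d[lo_clamp] <- mins$d_min[lo_clamp]
  clamped[lo_clamp] <- TRUE

  ue_top <- critical_velocity(h, params$d_max, params)
  hi_clamp <- !lo_clamp & u >= ue_top
  d[hi_clamp] <- params$d_max
  clamped[hi_clamp] <- TRUE

  solve_idx <- which(!lo_clamp & !hi_clamp)
  if (length(solve_idx)) {
    # vectorised bisection on the monotone coarse branch
    lo <- mins$d_min[solve_idx]
    hi <- rep(params$d_max, length(solve_idx))
    ui <- u[solve_idx]; hi_h <- h[solve_idx]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      too_low <- critical_velocity(hi_h, mid, params) < ui
      lo[too_low] <- mid[too_low]
      hi[!too_low] <- mid[!too_low]
      if (max((hi - lo) / lo) < 1e-8) break
    }
    d[solve_idx] <- (lo + hi) / 2
  }
  if (any(clamped))
    .msg(sprintf("invert_grain_size: %d value(s) clamped to the solver bracket",
                 sum(clamped)))
  data.frame(d = d, clamped = clamped)
}
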