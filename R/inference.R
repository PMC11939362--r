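#' Defuzzification settings
#'
#' @param step integration step on the HSI universe `[0, 1]` (default 0.001,
#'   i.e. a 1001-point grid; centroid error is O(step^2)).
#' @param fallback crisp value returned when the aggregated membership is
#'   identically zero (cannot occur under a complete rule base and covering
#'   fuzzy sets, kept as a guard). Default 0, with a warning when used.
#' @return an object of class `defuzzify_spec`.
#' @export
defuzzify_spec <- function(step = 0.001, fallback = 0) {
  stopifnot(is.numeric(step), step > 0, is.numeric(fallback),
            fallback >= 0, fallback <= 1)
  structure(list(step = step, fallback = fallback), class = "defuzzify_spec")
}

#' Strength of one rule given factor memberships
#'
#' Mamdani min-AND: each factor contributes the maximum membership over the
#' rule's allowed grades (`AC` therefore contributes the factor's maximal
#' membership), and the four factor terms are combined with `min`.
#'
#' @param rule a [fuzzy_rule()].
#' @param memberships named list over the four factors, each a named numeric
#'   vector of the five grade memberships (one row of [fuzzify()] output).
#' @return rule activation strength in `[0, 1]`.
#' @export
rule_strength <- function(rule, memberships) {
  stopifnot(inherits(rule, "fuzzy_rule"))
  miss <- setdiff(FACTORS, names(memberships))
  if (length(miss)) .stopf("memberships missing factor(s): %s",
                           paste(miss, collapse = ", "))
  terms <- vapply(FACTORS, function(f)
    max(memberships[[f]][rule$antecedent[[f]]]), numeric(1))
  min(terms)
}

# membership of the hsi grid in each output set: 5 x n_grid matrix
.output_set_matrix <- function(hsi_var, z) {
  t(vapply(GRADES, function(g) {
    s <- hsi_var$sets[[g]]
    .pl_interp(z, s$x, s$mu)
  }, numeric(length(z))))
}

#' Run Mamdani inference for one input tuple
#'
#' Clips (min-implication) each rule's consequent set at the rule strength
#' and aggregates all clipped sets pointwise by max on a discretised HSI
#' universe.
#'
#' @param rb a [rule_base()].
#' @param vars named list of fuzzy variables (from
#'   [default_fuzzy_variables()] or [read_fuzzy_variables()]).
#' @param inputs named list or vector with `substrate` (grain size, m),
#'   `temperature` (degC), `velocity` (m/s), `depth` (m). Values outside a
#'   variable's universe are clamped.
#' @param spec a [defuzzify_spec()].
#' @return list with the grid `z`, the aggregated membership `mu`, and the
#'   per-grade clip levels `clip`.
#' @export
infer <- function(rb, vars, inputs, spec = defuzzify_spec()) {
  stopifnot(inherits(rb, "rule_base"))
  inputs <- as.list(inputs)
  memberships <- lapply(FACTORS, function(f) {
    x <- clamp_to_universe(vars[[f]], as.numeric(inputs[[f]]))
    drop(fuzzify(vars[[f]], x))
  })
  names(memberships) <- FACTORS
  strengths <- vapply(rb$rules, rule_strength, numeric(1),
                      memberships = memberships)
  clip <- vapply(GRADES, function(g) {
    s <- strengths[vapply(rb$rules, function(r) r$consequent == g, logical(1))]
    if (length(s)) max(s) else 0
  }, numeric(1))
  z <- seq(0, 1, by = spec$step)
  om <- .output_set_matrix(vars$hsi, z)
  mu <- rep(0, length(z))
  for (g in seq_along(GRADES))
    mu <- pmax(mu, pmin(om[g, ], clip[g]))
  list(z = z, mu = mu, clip = clip)
}

#' Centroid defuzzification
#'
#' Crisp output `integral(z mu(z) dz) / integral(mu(z) dz)` by trapezoidal
#' quadrature on the sampled aggregate; the configured fallback is returned
#' (with a warning) when the denominator is zero.
#'
#' @param z uniform grid over the HSI universe.
#' @param mu aggregated membership sampled on `z`.
#' @param spec a [defuzzify_spec()] (supplies the fallback).
#' @return crisp HSI in `[0, 1]`.
#' @export
defuzzify_centroid <- function(z, mu, spec = defuzzify_spec()) {
  stopifnot(length(z) == length(mu), length(z) >= 2L)
  w <- diff(z)
  den <- sum((mu[-1] + mu[-length(mu)]) / 2 * w)
  if (den <= 0) {
    warning("aggregated membership is identically zero; returning fallback HSI")
    return(spec$fallback)
  }
  zmu <- z * mu
  num <- sum((zmu[-1] + zmu[-length(zmu)]) / 2 * w)
  num / den
}

# ---- vectorised core ------------------------------------------------------

# per-grade clip levels for vectors of inputs: returns n x 5 matrix
.clip_levels <- function(rb, vars, substrate, temperature, velocity, depth) {
  n <- max(length(substrate), length(temperature), length(velocity),
           length(depth))
  vals <- list(substrate = rep_len(as.numeric(substrate), n),
               temperature = rep_len(as.numeric(temperature), n),
               velocity = rep_len(as.numeric(velocity), n),
               depth = rep_len(as.numeric(depth), n))
  mm <- lapply(FACTORS, function(f)
    fuzzify(vars[[f]], clamp_to_universe(vars[[f]], vals[[f]])))
  names(mm) <- FACTORS
  clip <- matrix(0, n, 5L, dimnames = list(NULL, GRADES))
  for (r in rb$rules) {
    strength <- NULL
    for (f in FACTORS) {
      cols <- mm[[f]][, r$antecedent[[f]], drop = FALSE]
      term <- do.call(pmax, as.data.frame(cols))
      strength <- if (is.null(strength)) term else pmin(strength, term)
    }
    k <- r$consequent
    clip[, k] <- pmax(clip[, k], strength)
  }
  clip
}

# centroid for each row of a clip-level matrix (chunked to bound memory)
.centroid_from_clips <- function(clip, hsi_var, spec) {
  z <- seq(0, 1, by = spec$step)
  nz <- length(z)
  om <- .output_set_matrix(hsi_var, z)
  w <- c(spec$step / 2, rep(spec$step, nz - 2L), spec$step / 2)
  n <- nrow(clip)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / nz))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    agg <- matrix(0, length(idx), nz)
    for (g in seq_along(GRADES)) {
      m <- matrix(om[g, ], length(idx), nz, byrow = TRUE)
      # pmin recycles the clip column down the rows (column-major)
      agg <- pmax(agg, pmin(m, clip[idx, g]))
    }
    den <- as.numeric(agg %*% w)
    num <- as.numeric(agg %*% (z * w))
    zero <- den <= 0
    if (any(zero)) {
      warning(sprintf("%d cell(s) activated no rule; using fallback HSI", sum(zero)))
      out[idx] <- ifelse(zero, spec$fallback, num / pmax(den, .Machine$double.xmin))
    } else out[idx] <- num / den
  }
  out
}

#' Evaluate crisp habitat suitability for input tuples
#'
#' Composition fuzzify -> rule activation -> Mamdani aggregation -> centroid
#' defuzzification. Vectorised over the inputs (shorter vectors recycle), so
#' a whole cell field evaluates in one call.
#'
#' @inheritParams infer
#' @param substrate bed grain size (m).
#' @param temperature water temperature (degC).
#' @param velocity depth-averaged flow velocity (m/s).
#' @param depth water depth (m).
#' @return numeric vector of HSI values in `[0, 1]`.
#' @examples
#' vars <- default_fuzzy_variables()
#' rb <- default_rule_base()
#' # a cold cell is blocked regardless of hydraulics:
#' evaluate_hsi(rb, vars, substrate = 0.1, temperature = 13.4,
#'              velocity = 0.5, depth = 5)
#' @export
evaluate_hsi <- function(rb, vars, substrate, temperature, velocity, depth,
                         spec = defuzzify_spec()) {
  stopifnot(inherits(rb, "rule_base"), inherits(spec, "defuzzify_spec"))
  clip <- .clip_levels(rb, vars, substrate, temperature, velocity, depth)
  .centroid_from_clips(clip, vars$hsi, spec)
}
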