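# shared fixtures and independent oracles

default_vars <- local({
  v <- NULL
  function() {
    if (is.null(v)) v <<- default_fuzzy_variables()
    v
  }
})

default_rb <- local({
  r <- NULL
  function() {
    if (is.null(r)) r <<- default_rule_base()
    r
  }
})

# calibration is deterministic; memoise it across test files
calibrated_spec <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- calibrate_reach_spec()
    s
  }
})

# three-cell hand example: WUA 170 m2, OSI 0.17; with the half-open class
# boundaries, HSI 0.25 falls below the 0.3 cutoff, so classes are (0, 10, 90) %
three_cell_field <- function() {
  cell_field(cell_id = c("a", "b", "c"), area_m2 = c(100, 200, 700),
             depth_m = c(2, 3, 4), velocity_ms = c(0.5, 0.6, 0.7),
             hsi = c(0.5, 0.25, 0.1))
}

random_hsi_field <- function(n, seed) {
  set.seed(seed)
  cell_field(cell_id = sprintf("c%04d", seq_len(n)),
             area_m2 = runif(n, 10, 500),
             depth_m = runif(n, 0.5, 20),
             velocity_ms = runif(n, 0.05, 2),
             hsi = runif(n))
}

# independent fine-grid centroid of the output sets clipped at `clip`
# (direct interpolation + Riemann/trapezoid sum, step 1e-5 by default)
centroid_fine_oracle <- function(clip, vars, step = 1e-5) {
  z <- seq(0, 1, by = step)
  mu <- rep(0, length(z))
  for (g in names(vars$hsi$sets)) {
    s <- vars$hsi$sets[[g]]
    m <- approx(s$x, s$mu, xout = z, rule = 2)$y
    mu <- pmax(mu, pmin(m, clip[[g]]))
  }
  den <- sum((mu[-1] + mu[-length(mu)]) / 2) * step
  if (den <= 0) return(NA_real_)
  zm <- z * mu
  num <- sum((zm[-1] + zm[-length(zm)]) / 2) * step
  num / den
}

# package-side centroid of output sets clipped at `clip`, default step
centroid_package <- function(clip, vars, spec = defuzzify_spec()) {
  z <- seq(0, 1, by = spec$step)
  om <- fuzzify(vars$hsi, z)
  mu <- rep(0, length(z))
  for (g in colnames(om)) mu <- pmax(mu, pmin(om[, g], clip[[g]]))
  defuzzify_centroid(z, mu, spec)
}
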