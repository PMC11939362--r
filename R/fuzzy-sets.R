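#' Construct a fuzzy set
#'
#' A fuzzy set is a linguistic grade (`VL`, `L`, `M`, `H`, `VH`) together with
#' a piecewise-linear membership function given as ordered breakpoints.
#' Outside the breakpoint range membership extends flat at the terminal value
#' (shoulder semantics), so `VL`/`VH` shoulders need no explicit plateau.
#'
#' @param label linguistic grade, one of `"VL"`, `"L"`, `"M"`, `"H"`, `"VH"`.
#' @param x numeric vector of strictly increasing breakpoint locations, in the
#'   variable's units.
#' @param mu membership at each breakpoint, in `[0, 1]`; at least one value
#'   must equal 1 (the set is normal).
#' @return an object of class `fuzzy_set`.
#' @examples
#' fs <- fuzzy_set("VL", c(17, 19), c(1, 0))
#' @export
fuzzy_set <- function(label, x, mu) {
  label <- match.arg(label, GRADES)
  x <- as.numeric(x); mu <- as.numeric(mu)
  if (length(x) < 2L || length(x) != length(mu))
    .stopf("fuzzy set '%s': need >= 2 matching breakpoints", label)
  if (any(!is.finite(x)) || any(diff(x) <= 0))
    .stopf("fuzzy set '%s': breakpoint x must be finite and strictly increasing", label)
  if (any(mu < 0 | mu > 1) || !any(mu == 1))
    .stopf("fuzzy set '%s': mu must lie in [0,1] with at least one mu == 1", label)
  structure(list(label = label, x = x, mu = mu), class = "fuzzy_set")
}

#' Construct a fuzzy variable
#'
#' A fuzzy variable bundles five fuzzy sets (one per grade) over a universe of
#' discourse. The five sets must jointly cover the universe (total membership
#' positive everywhere) and adjacent grades must overlap.
#'
#' @param name variable name; one of `"substrate"`, `"temperature"`,
#'   `"velocity"`, `"depth"`, `"hsi"`.
#' @param units unit string (m, degC, m/s, dimensionless).
#' @param universe numeric length-2 `[min, max]` range in the variable units.
#' @param sets list of five [fuzzy_set()] objects labelled `VL` through `VH`.
#' @return an object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, units, universe, sets) {
  name <- match.arg(name, c(FACTORS, "hsi"))
  universe <- as.numeric(universe)
  if (length(universe) != 2L || !all(is.finite(universe)) || diff(universe) <= 0)
    .stopf("variable '%s': universe must be a finite increasing [min, max]", name)
  labels <- vapply(sets, function(s) s$label, character(1))
  if (length(sets) != 5L || !identical(sort(labels), sort(GRADES)))
    .stopf("variable '%s': need exactly the five sets VL, L, M, H, VH", name)
  names(sets) <- labels
  sets <- sets[GRADES]
  obj <- structure(list(name = name, units = units, universe = universe,
                        sets = sets), class = "fuzzy_variable")
  # validation grid: all breakpoints plus interior subdivisions, so narrow
  # transitions are resolved regardless of the universe extent
  knots <- sort(unique(c(universe,
                         unlist(lapply(sets, function(s) s$x)))))
  knots <- knots[knots >= universe[1] & knots <= universe[2]]
  grid <- sort(unique(c(knots, vapply(seq_len(length(knots) - 1L), function(i)
    (knots[i] + knots[i + 1]) / 2, numeric(1)),
    as.vector(outer(seq(0.1, 0.9, by = 0.2), diff(knots))) +
      rep(knots[-length(knots)], each = 5L))))
  tot <- rowSums(fuzzify(obj, grid))
  if (any(tot <= 0))
    .stopf("variable '%s': fuzzy sets do not cover the universe (gap near %.4g)",
           name, grid[which(tot <= 0)[1]])
  # adjacent grades overlap somewhere
  for (i in 1:4) {
    m1 <- membership(obj, GRADES[i], grid)
    m2 <- membership(obj, GRADES[i + 1], grid)
    if (!any(m1 > 0 & m2 > 0))
      .stopf("variable '%s': grades %s and %s do not overlap",
             name, GRADES[i], GRADES[i + 1])
  }
  obj
}

#' @export
print.fuzzy_variable <- function(x, ...) {
  cat(sprintf("fuzzy variable '%s' (%s), universe [%g, %g]\n",
              x$name, x$units, x$universe[1], x$universe[2]))
  for (s in x$sets)
    cat(sprintf("  %-2s: %s\n", s$label,
                paste(sprintf("(%g, %g)", s$x, s$mu), collapse = " ")))
  invisible(x)
}

# piecewise-linear interpolation with flat extension beyond terminal points
.pl_interp <- function(x, bx, bmu) {
  stats::approx(bx, bmu, xout = x, method = "linear", rule = 2)$y
}

#' Membership of a value in one grade of a fuzzy variable
#'
#' @param var a [fuzzy_variable()].
#' @param grade one of `"VL"`, `"L"`, `"M"`, `"H"`, `"VH"`.
#' @param x numeric vector of factor values (variable units).
#' @return membership degrees in `[0, 1]`, same length as `x`.
#' @examples
#' vars <- default_fuzzy_variables()
#' membership(vars$temperature, "VL", c(17, 18, 19))  # 1.0 0.5 0.0
#' @export
membership <- function(var, grade, x) {
  stopifnot(inherits(var, "fuzzy_variable"))
  if (!grade %in% GRADES) .stopf("unknown grade '%s'", as.character(grade)[1])
  if (any(!is.finite(x))) .stopf("membership: x must be finite")
  s <- var$sets[[grade]]
  .pl_interp(x, s$x, s$mu)
}

#' Fuzzify a value against all five grades of a variable
#'
#' @inheritParams membership
#' @return a numeric matrix with one row per element of `x` and the five
#'   grade columns `VL`..`VH`.
#' @examples
#' vars <- default_fuzzy_variables()
#' fuzzify(vars$temperature, 18)  # VL = L = 0.5
#' @export
fuzzify <- function(var, x) {
  stopifnot(inherits(var, "fuzzy_variable"))
  if (any(!is.finite(x))) .stopf("fuzzify: x must be finite")
  m <- vapply(GRADES, function(g) {
    s <- var$sets[[g]]
    .pl_interp(x, s$x, s$mu)
  }, numeric(length(x)))
  if (length(x) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, GRADES))
  m
}

#' Clamp values to a variable's universe
#'
#' Inputs outside the universe are pulled to its bounds (the membership
#' shoulders are flat there, so this only formalises the extension) and the
#' number of clamped values is reported when verbose.
#'
#' @inheritParams membership
#' @return clamped numeric vector.
#' @export
clamp_to_universe <- function(var, x) {
  lo <- var$universe[1]; hi <- var$universe[2]
  n <- sum(x < lo | x > hi, na.rm = TRUE)
  if (n > 0) .msg(sprintf("clamped %d value(s) to the '%s' universe", n, var$name))
  pmin(pmax(x, lo), hi)
}

#' Read fuzzy variables from a YAML file
#'
#' The file maps each variable name to `units`, `universe` and a `sets` block
#' of `[x, mu]` breakpoint lists per grade; see the packaged default
#' `system.file("extdata", "fuzzy_variables.yaml", package = "spawnhab")`.
#'
#' @param path YAML file path.
#' @return named list of [fuzzy_variable()] objects, including `hsi`.
#' @export
read_fuzzy_variables <- function(path) {
  if (!file.exists(path)) .stopf("variable file not found: %s", path)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    v <- raw[[nm]]
    if (is.null(v$units) || is.null(v$universe) || is.null(v$sets))
      .stopf("variable '%s': needs units, universe and sets", nm)
    sets <- lapply(names(v$sets), function(g) {
      bp <- v$sets[[g]]
      xs <- vapply(bp, function(p) as.numeric(p[[1]]), numeric(1))
      mus <- vapply(bp, function(p) as.numeric(p[[2]]), numeric(1))
      fuzzy_set(g, xs, mus)
    })
    fuzzy_variable(nm, v$units, unlist(v$universe), sets)
  })
  names(out) <- names(raw)
  miss <- setdiff(c(FACTORS, "hsi"), names(out))
  if (length(miss)) .stopf("variable file lacks: %s", paste(miss, collapse = ", "))
  out
}

#' Default fuzzy variables of the spawning-habitat model
#'
#' Loads the packaged breakpoints: suitability thresholds at 18/20/25/27 degC,
#' 0.1/0.2/1.3/1.5 m/s, 0.6/1.2/11.5/15 m depth and 2 mm/2 cm/25 cm/40 cm
#' grain size, each a mu = 0.5 crossover between adjacent grades, plus the
#' five triangular output sets on `[0, 1]`.
#'
#' @return named list of [fuzzy_variable()] objects.
#' @export
default_fuzzy_variables <- function() {
  read_fuzzy_variables(system.file("extdata", "fuzzy_variables.yaml",
                                   package = "spawnhab", mustWork = TRUE))
}
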