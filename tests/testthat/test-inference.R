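test_that("rule strength is min over factors of max over allowed grades", {
  mk <- function(vl = 0, l = 0, m = 0, h = 0, vh = 0)
    c(VL = vl, L = l, M = m, H = h, VH = vh)
  memberships <- list(substrate = mk(m = 1), temperature = mk(vl = 1),
                      velocity = mk(l = 1), depth = mk(h = 1))
  # AC contributes the factor's maximal membership
  r_block <- fuzzy_rule(c("VL","L","M","H","VH"), "VL",
                        c("VL","L","M","H","VH"), c("VL","L","M","H","VH"), "L")
  expect_equal(rule_strength(r_block, memberships), 1.0)
  # ... which may itself be below 1 near a grade transition
  partial <- memberships; partial$velocity <- mk(l = 0.7, m = 0.4)
  expect_equal(rule_strength(r_block, partial), 0.7)
  r_all_m <- fuzzy_rule("M", "M", "M", "M", "VH")
  all_m <- list(substrate = mk(m = 1), temperature = mk(m = 1),
                velocity = mk(m = 1), depth = mk(m = 1))
  expect_equal(rule_strength(r_all_m, all_m), 1.0)
  half <- all_m; half$temperature <- mk(m = 0.5)
  expect_equal(rule_strength(r_all_m, half), 0.5)
  expect_error(rule_strength(r_all_m, all_m[-2]), "missing factor")
})

test_that("cold water fires only low-suitability rules, at full strength", {
  vars <- default_vars()
  res <- infer(default_rb(), vars,
               list(substrate = 0.1, temperature = 13.4, velocity = 0.5,
                    depth = 5))
  expect_equal(unname(res$clip),  c(0, 1, 0, 0, 0))
  # the aggregate is exactly the full L output set
  expect_equal(res$mu, fuzzify(vars$hsi, res$z)[, "L"])
})

test_that("all-optimal plateau inputs fire only the top rule", {
  res <- infer(default_rb(), default_vars(),
               list(substrate = 0.1, temperature = 22.5, velocity = 0.7,
                    depth = 5))
  expect_equal(unname(res$clip), c(0, 0, 0, 0, 1))
})

test_that("centroid defuzzification matches symmetry and the fine-grid oracle", {
  spec <- defuzzify_spec()
  z <- seq(0, 1, by = spec$step)
  tri <- pmax(0, 1 - abs(z - 0.5) / 0.25)
  expect_equal(defuzzify_centroid(z, tri, spec), 0.5, tolerance = 1e-9)
  expect_equal(defuzzify_centroid(z, rep(1, length(z)), spec), 0.5,
               tolerance = 1e-12)
  vars <- default_vars()
  clipL <- c(VL = 0, L = 1, M = 0, H = 0, VH = 0)
  expect_equal(centroid_package(clipL, vars), 0.2, tolerance = 1e-6)
  expect_equal(centroid_fine_oracle(clipL, vars), 0.2, tolerance = 1e-6)
  # zero aggregate falls back with a warning
  expect_warning(out <- defuzzify_centroid(z, rep(0, length(z)), spec),
                 "fallback")
  expect_equal(out, spec$fallback)
})

test_that("package centroid agrees with the independent fine-grid oracle on random clips", {
  vars <- default_vars()
  set.seed(7)
  for (i in 1:50) {
    clip <- as.list(setNames(runif(5), c("VL", "L", "M", "H", "VH")))
    expect_equal(centroid_package(clip, vars),
                 centroid_fine_oracle(clip, vars), tolerance = 1e-3)
  }
})

test_that("evaluate_hsi reproduces hand-derived reference points", {
  vars <- default_vars(); rb <- default_rb()
  # blocked by temperature: centroid of the full L set, below the 0.3 cutoff
  expect_equal(evaluate_hsi(rb, vars, 0.1, 13.4, 0.5, 5), 0.2,
               tolerance = 1e-6)
  # all-optimal: centroid of the full VH triangle (0.8, 1, 1)
  expect_equal(evaluate_hsi(rb, vars, 0.1, 22.5, 0.7, 5),
               centroid_fine_oracle(c(VL=0,L=0,M=0,H=0,VH=1), vars),
               tolerance = 1e-3)
  # M substrate/temperature/velocity with depth on its L plateau fires only
  # the H-consequent row: centroid of the full H triangle
  expect_equal(evaluate_hsi(rb, vars, 0.1, 22.5, 0.7, 0.9), 0.8,
               tolerance = 1e-6)
})

test_that("vectorised evaluation equals scalar infer + defuzzify", {
  vars <- default_vars(); rb <- default_rb()
  set.seed(11)
  d <- runif(8, 0.001, 0.6); te <- runif(8, 12, 30)
  u <- runif(8, 0, 2); h <- runif(8, 0.2, 20)
  vec <- evaluate_hsi(rb, vars, d, te, u, h)
  for (i in 1:8) {
    res <- infer(rb, vars, list(substrate = d[i], temperature = te[i],
                                velocity = u[i], depth = h[i]))
    expect_equal(vec[i], defuzzify_centroid(res$z, res$mu), tolerance = 1e-12)
  }
  expect_true(all(vec >= 0 & vec <= 1))
})

test_that("HSI is continuous along dense 1-D input sweeps", {
  vars <- default_vars(); rb <- default_rb()
  tt <- seq(12, 30, by = 0.05)
  hsi_t <- evaluate_hsi(rb, vars, 0.1, tt, 0.7, 5)
  expect_lt(max(abs(diff(hsi_t))), 0.05)
  # the velocity response is steep (slope ~10 across the narrow VL/L
  # transitions) but continuous: refining the step shrinks the increments
  uu <- seq(0, 2.5, by = 0.002)
  hsi_u <- evaluate_hsi(rb, vars, 0.1, 22.5, uu, 5)
  expect_lt(max(abs(diff(hsi_u))), 0.05)
})

test_that("fully very-low or very-high temperature blocks independently of other inputs", {
  vars <- default_vars(); rb <- default_rb()
  set.seed(3)
  d <- runif(20, 0.0002, 1); u <- runif(20, 0, 3); h <- runif(20, 0.1, 30)
  for (t_block in c(13.4, 29)) {
    hsi <- evaluate_hsi(rb, vars, d, t_block, u, h)
    expect_equal(hsi, rep(hsi[1], 20), tolerance = 1e-9)
    expect_lt(hsi[1], 0.3)
  }
})

test_that("warming from the L to the M temperature plateau never lowers HSI", {
  vars <- default_vars(); rb <- default_rb()
  h_l <- evaluate_hsi(rb, vars, 0.1, 19, 0.7, 5)   # L plateau
  h_m <- evaluate_hsi(rb, vars, 0.1, 22.5, 0.7, 5) # M plateau
  expect_gte(h_m, h_l)
  # and along the whole sweep between the plateaus
  tt <- seq(19, 22.5, by = 0.1)
  hsi <- evaluate_hsi(rb, vars, 0.1, tt, 0.7, 5)
  expect_true(all(diff(hsi) >= -1e-9))
})
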