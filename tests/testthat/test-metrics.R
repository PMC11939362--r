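test_that("WUA, OSI and class proportions reproduce the hand example", {
  f <- three_cell_field()
  expect_equal(wua(f), 170)
  expect_equal(osi(f), 0.17)
  # HSI 0.25 sits below the 0.3 cutoff, so only the 0.5 cell is moderate
  expect_equal(suitability_proportions(f),
               c(ISP = 0, MSP = 10, LSP = 90))
})

test_that("degenerate and factorised cases behave as defined", {
  f0 <- cell_field("a", 100, 2, 0.5, hsi = 0)
  expect_equal(wua(f0), 0)
  n <- 20
  fc <- cell_field(sprintf("c%d", 1:n), runif(n, 1, 50), 2, 0.5, hsi = 0.37)
  expect_equal(wua(fc), 0.37 * sum(fc$area_m2))
  expect_equal(osi(fc), 0.37)
  f1 <- cell_field("solo", 42, 3, 0.4, hsi = 0.61)
  expect_equal(osi(f1), 0.61)
  # uniform low HSI: OSI equals the constant
  fu <- cell_field(sprintf("u%d", 1:5), c(1, 2, 3, 4, 5), 2, 0.5, hsi = 0.06)
  expect_equal(osi(fu), 0.06)
})

test_that("class boundaries are half-open exactly as published", {
  f <- cell_field(c("a", "b"), c(100, 900), 2, 0.5, hsi = c(0.7, 0))
  p <- suitability_proportions(f)
  expect_equal(p[["ISP"]], 10)   # HSI == 0.7 counts as ideal
  expect_equal(p[["LSP"]], 90)
  f2 <- cell_field(c("a", "b"), c(100, 900), 2, 0.5, hsi = c(0.3, 0.299999))
  p2 <- suitability_proportions(f2)
  expect_equal(p2[["MSP"]], 10)  # HSI == 0.3 counts as moderate
  expect_equal(p2[["LSP"]], 90)
})

test_that("proportions conserve area and OSI*area equals WUA on random fields", {
  for (seed in 1:100) {
    f <- random_hsi_field(50, seed)
    p <- suitability_proportions(f)
    expect_equal(sum(p), 100, tolerance = 1e-9)
    expect_equal(osi(f) * sum(f$area_m2), wua(f), tolerance = 1e-12)
  }
})

test_that("metrics are scale invariant in area", {
  f <- random_hsi_field(200, 99)
  fk <- f; fk$area_m2 <- f$area_m2 * 7.3
  expect_equal(wua(fk), 7.3 * wua(f))
  expect_equal(osi(fk), osi(f), tolerance = 1e-12)
  expect_equal(suitability_proportions(fk), suitability_proportions(f),
               tolerance = 1e-12)
})

test_that("metrics match a naive per-cell loop", {
  f <- random_hsi_field(1000, 5)
  w <- 0; tot <- 0; a_i <- 0; a_m <- 0; a_l <- 0
  for (i in seq_len(nrow(f))) {
    w <- w + f$area_m2[i] * f$hsi[i]
    tot <- tot + f$area_m2[i]
    if (f$hsi[i] >= 0.7) a_i <- a_i + f$area_m2[i]
    else if (f$hsi[i] >= 0.3) a_m <- a_m + f$area_m2[i]
    else a_l <- a_l + f$area_m2[i]
  }
  expect_equal(wua(f), w)
  expect_equal(osi(f), w / tot)
  expect_equal(unname(suitability_proportions(f)),
               c(a_i, a_m, a_l) / tot * 100)
})

test_that("dry cells are excluded and missing HSI is an error", {
  f <- cell_field(c("a", "b", "c"), c(100, 200, 300),
                  depth_m = c(2, NA, 3), velocity_ms = c(0.5, NA, 0.6),
                  hsi = c(0.5, NA, 0.9))
  expect_equal(wua(f), 100 * 0.5 + 300 * 0.9)
  expect_equal(osi(f), (100 * 0.5 + 300 * 0.9) / 400)
  f_missing <- cell_field(c("a", "b"), c(100, 200), 2, 0.5,
                          hsi = c(0.5, NA))
  expect_error(wua(f_missing), "HSI missing")
  expect_error(cell_field(c("a", "a"), c(1, 1), 2, 0.5), "duplicate")
  expect_error(cell_field("a", -1, 2, 0.5), "positive")
  expect_error(metric_thresholds(ideal = 0.3, low = 0.7))
})

test_that("summaries bundle the metrics at full precision", {
  f <- three_cell_field()
  s <- summarize_habitat(f, period = "First half of May")
  expect_equal(s$wua_m2, 170)
  expect_equal(s$osi, 0.17)
  expect_equal(c(s$isp, s$msp, s$lsp), c(0, 10, 90))
  expect_equal(s$period, "First half of May")
  s1 <- summarize_habitat(cell_field("x", 10, 1, 0.1, hsi = 0.42))
  expect_equal(s1$osi, 0.42)
  expect_equal(s1$wua_m2, 4.2)
})
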