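test_that("the packaged schedule carries the ten semi-monthly rows", {
  sched <- default_schedule()
  expect_equal(nrow(sched), 10)
  expect_equal(sched$discharge_m3s[sched$period == "Second half of July"],
               9596.25)
  expect_equal(sched$temperature_C[sched$period == "First half of May"], 18.7)
  expect_true(all(diff(sched$temperature_C) >= 0))
  expect_true(all(sched$discharge_m3s > 0))
})

test_that("field generation is seed-reproducible and area-conserving", {
  sp <- reach_spec(seed = 101)
  cond <- default_schedule()[5, ]
  f1 <- generate_field(sp, cond)
  f2 <- generate_field(sp, cond)
  expect_identical(f1, f2)
  f3 <- generate_field(sp, cond, seed = 202)
  expect_false(isTRUE(all.equal(f1$depth_m, f3$depth_m)))
  expect_equal(sum(f3$area_m2), sum(f1$area_m2))
  total <- sp$length_m * (sp$channel_width_m + 2 * sp$floodplain_width_m)
  expect_equal(sum(f1$area_m2), total, tolerance = 1e-6)
})

test_that("cross-section fluxes reproduce the discharge", {
  sp <- calibrated_spec()
  cond <- default_schedule()[5, ]
  f <- generate_field(sp, cond)
  wet <- is.finite(f$depth_m)
  lane <- as.integer(sub("y(\\d+)_.*", "\\1", f$cell_id))
  station <- as.integer(sub(".*_x(\\d+)", "\\1", f$cell_id))
  # channel lanes share the station grid; floodplain is dry at this flow
  dx <- sp$length_m / max(station[wet])
  flux <- tapply((f$velocity_ms * f$depth_m * f$area_m2 / dx)[wet],
                 station[wet], sum)
  expect_equal(median(flux), cond$discharge_m3s, tolerance = 0.1)
  expect_equal(mean(flux), cond$discharge_m3s, tolerance = 0.05)
})

test_that("bank lanes are shallower and slower than the thalweg", {
  sp <- calibrated_spec()
  sp$sigma_depth <- 0; sp$sigma_velocity <- 0; sp$sigma_grain <- 0
  f <- generate_field(sp, default_schedule()[5, ])
  wet <- is.finite(f$depth_m)
  lane <- as.integer(sub("y(\\d+)_.*", "\\1", f$cell_id))
  prof_u <- tapply(f$velocity_ms[wet], lane[wet], mean)
  prof_h <- tapply(f$depth_m[wet], lane[wet], mean)
  mid <- which.max(prof_h)
  expect_lt(prof_u[1], prof_u[mid])
  expect_lt(prof_u[length(prof_u)], prof_u[mid])
  expect_true(all(diff(prof_h[1:mid]) > 0))
})

test_that("calibration is deterministic, seed-independent and idempotent", {
  sp <- calibrated_spec()
  again <- calibrate_reach_spec(sp)
  expect_equal(again$channel_width_m, sp$channel_width_m)
  expect_equal(again$slope, sp$slope)
  other_seed <- calibrate_reach_spec(reach_spec(seed = 777))
  expect_equal(other_seed$channel_width_m, sp$channel_width_m)
  expect_equal(other_seed$slope, sp$slope)
})

test_that("calibrated defaults reproduce the documented flow regimes", {
  sp <- calibrated_spec()
  sched <- default_schedule()
  low <- generate_field(sp, sched[sched$period == "First half of May", ])
  wet <- is.finite(low$depth_m)
  mh <- weighted.mean(low$depth_m[wet], low$area_m2[wet])
  mu <- weighted.mean(low$velocity_ms[wet], low$area_m2[wet])
  expect_gte(mh, 9); expect_lte(mh, 10)
  expect_gte(mu, 0.4); expect_lte(mu, 0.6)
  flood <- generate_field(sp, sched[sched$period == "Second half of July", ])
  wf <- is.finite(flood$depth_m)
  frac_fast <- sum(flood$area_m2[wf][flood$velocity_ms[wf] > 1.5]) /
    sum(flood$area_m2[wf])
  expect_gt(frac_fast, 0.5)
})

test_that("the generated bed coarsens from gravel/cobble to boulders with discharge", {
  sp <- calibrated_spec()
  sched <- default_schedule()
  low <- generate_field(sp, sched[5, ])
  wet <- is.finite(low$depth_m)
  frac_fine <- sum(low$area_m2[wet][low$grain_d_m[wet] < 0.25]) /
    sum(low$area_m2[wet])
  expect_gt(frac_fine, 0.7)   # mostly gravel/cobble at low flow
  flood <- generate_field(sp, sched[10, ])
  wf <- is.finite(flood$depth_m)
  frac_boulder <- sum(flood$area_m2[wf][flood$grain_d_m[wf] > 0.40]) /
    sum(flood$area_m2[wf])
  expect_gt(frac_boulder, 0.5)  # boulder-dominated under flood flows
})

test_that("impossible discharges are rejected", {
  sp <- reach_spec()
  cond <- period_conditions("impossible", 1e15, NA, 0.17, 20)
  expect_error(generate_field(sp, cond), "unreachable")
})
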