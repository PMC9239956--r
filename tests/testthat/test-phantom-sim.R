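geom <- machine_geometry()

test_that("phantom_spec validates the ring arithmetic", {
  expect_silent(phantom_spec())
  expect_error(phantom_spec(ring_count = 10), "360")
  expect_error(phantom_spec(central_bb_diameter_mm = 0), "positive")
})

test_that("a perfectly aligned central ballbearing images at the central pixel", {
  im <- render_mvi(angle_deg = 0, wobble = wobble_model(), geom = geom)
  loc <- locate_bb(im)
  expect_lt(abs(loc$u_px - im$central_px[1]), 0.1)
  expect_lt(abs(loc$v_px - im$central_px[2]), 0.1)
})

test_that("rendering is bit-identical for a fixed seed", {
  wob <- wobble_model(noise_sd = 3, seed = 42)
  a <- render_mvi(angle_deg = 30, wobble = wob, geom = geom)
  b <- render_mvi(angle_deg = 30, wobble = wob, geom = geom)
  expect_identical(a$pixels, b$pixels)
  c <- render_mvi(angle_deg = 30, wobble = wob, geom = geom, seed = 43L)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("fields larger than the panel extent are rejected", {
  expect_error(render_mvi(field_cm = c(25, 5), geom = geom), "panel extent")
  expect_error(render_mvi(field_cm = c(10, 10), geom = geom), "panel extent")
})

test_that("integrated ballbearing deficit scales with diameter squared", {
  deficit <- function(d_mm) {
    spec <- phantom_spec(central_bb_diameter_mm = d_mm)
    im <- render_mvi(spec, angle_deg = 0, wobble = wobble_model(), geom = geom)
    sum(1000 - im$pixels)
  }
  d4 <- deficit(4)
  d8 <- deficit(8)
  expect_equal(d8 / d4, 4, tolerance = 0.05)
})

test_that("gantry-angle offsets separate, then resolve, the eclipsed pairs", {
  mk <- function(err) {
    render_mvi(angle_deg = 0,
               wobble = wobble_model(gantry_angle_error_deg = err,
                                     noise_sd = 1, seed = 3),
               field_cm = c(10, 9.4), geom = geom, shift_y_cm = -3.5)
  }
  base <- mk(0)
  m01 <- gantry_reproducibility(mk(0.1), base)
  m03 <- gantry_reproducibility(mk(0.3), base)
  # a 0.3 degree offset perturbs the blobs well beyond a 0.1 degree one
  expect_gt(m03$rms_profile_diff, m01$rms_profile_diff)
  expect_gt(max(abs(m03$peripheral_width_diffs)),
            max(abs(m01$peripheral_width_diffs)))
  expect_lt(m03$eclipse_score, m01$eclipse_score)
  # a degree splits the eclipsed peripheral pairs into resolved doublets
  m10 <- gantry_reproducibility(mk(1.0), base)
  expect_gt(m10$n_blobs, m10$n_blobs_baseline)
})

test_that("projection series applies the default exclusions and carries truth", {
  ang <- default_isocentre_angles()
  expect_false(any(c(10, 20, 60, 300) %in% ang))
  expect_true(all(c(0, 30, 350) %in% ang))
  series <- render_projection_series(angles = c(0, 90, 180, 270),
                                     wobble = wobble_model(), geom = geom)
  expect_length(series, 4)
  truth <- attr(series, "truth")
  expect_equal(truth$angle_set_deg, c(0, 90, 180, 270))
  expect_equal(truth$axis_x_mm, rep(0, 4))
})

test_that("a pure translation of the beam axis leaves the axes concurrent", {
  wob <- wobble_model(fixed_offset_mm = c(0.2, 0))
  series <- render_projection_series(angles = seq(0, 330, by = 30),
                                     wobble = wob, geom = geom)
  fit <- run_isocentre_analysis(series, excluded_angles = numeric())
  expect_equal(unname(fit$center_mm[1]), 0.2, tolerance = 0.02)
  expect_equal(unname(fit$center_mm[2]), 0.0, tolerance = 0.02)
  expect_lt(fit$diameter_mm, 0.05)
})

test_that("dose pairs reproduce the stated perturbation exactly", {
  p0 <- make_dose_pair("multi_gaussian")
  expect_equal(p0$ref$values, p0$eval$values)
  p2 <- make_dose_pair("uniform", dose_scale_pct = 2)
  expect_equal(p2$eval$values, p2$ref$values * 1.02)
  # analytic shift: wedge slope 1 %/mm, so a 3 mm shift changes dose by 3 %
  pw <- make_dose_pair("wedge", shift_mm = c(3, 0))
  expect_equal(pw$eval$values, pw$ref$values - 0.03, tolerance = 1e-12)
  expect_error(make_dose_pair("uniform", spacing_mm = 0), "positive")
  # reproducible noise
  pn1 <- make_dose_pair("wedge", noise_pct = 1, seed = 5)
  pn2 <- make_dose_pair("wedge", noise_pct = 1, seed = 5)
  expect_identical(pn1$eval$values, pn2$eval$values)
})

test_that("chamber series round-trips exactly without noise and is seeded", {
  sim <- simulate_chamber_series(noise_cv = 0)
  res <- run_reference_dosimetry(sim$readings, sim$constants)
  expect_equal(res$tpr_20_10$tpr, 0.705, tolerance = 1e-12)
  expect_equal(res$tpr_10_5$tpr, 0.858, tolerance = 1e-12)
  expect_equal(res$output$d5_gy_per_100mu, 1.000, tolerance = 1e-9)
  a <- simulate_chamber_series(noise_cv = 0.003, seed = 9)
  b <- simulate_chamber_series(noise_cv = 0.003, seed = 9)
  expect_identical(a$readings$reading, b$readings$reading)
})
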