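geom <- machine_geometry()

test_that("profile extraction inverts dips and respects spans", {
  im <- portal_image(matrix(7, 20, 30), 0, geom)
  p <- extract_profile(im, "horizontal", 10)
  expect_equal(p$value, rep(0, 30))  # constant image -> flat zero profile
  expect_equal(diff(p$position_mm), rep(geom$pixel_pitch_mm, 29))
  p1 <- extract_profile(im, "horizontal", 10, span = c(4, 4))
  expect_equal(nrow(p1), 1)
  expect_error(extract_profile(im, "horizontal", 25), "outside")
  expect_error(extract_profile(im, "vertical", 3, span = c(0, 25)), "outside")
})

test_that("profile through a simulated ballbearing peaks at the known position", {
  wob <- wobble_model(fixed_offset_mm = c(0.8, 0))
  im <- render_mvi(angle_deg = 0, wobble = wob, geom = geom)
  p <- extract_profile(im, "horizontal", round(im$central_px[2]))
  u_peak <- p$position_mm[which.max(p$value)]
  # axis offset +0.8 mm -> image displaced by -M * 0.8 = -1.2 mm
  expect_equal(u_peak, -1.2, tolerance = 2 * geom$pixel_pitch_mm)
})

test_that("affine backgrounds cancel exactly under flanking-row subtraction", {
  # synthetic: peak + affine field sampled at rows v = -d, 0, +d
  x <- seq(-10, 10, by = 0.25)
  peak <- 50 * exp(-x^2 / 4)
  affine <- function(v) 3 + 0.7 * x + 1.9 * v
  bb <- mrlqa:::new_bb_profile(x, peak + affine(0))
  above <- mrlqa:::new_bb_profile(x, affine(-2.5))
  below <- mrlqa:::new_bb_profile(x, affine(2.5))
  res <- subtract_background(bb, above, below)
  expect_equal(res$value, peak, tolerance = 1e-12)
  # degenerate: subtracting a profile from itself yields zero
  z <- subtract_background(bb, bb, bb)
  expect_equal(z$value, rep(0, length(x)))
  bad <- mrlqa:::new_bb_profile(x + 0.1, peak)
  expect_error(subtract_background(bb, bad, below), "coordinates")
})

test_that("couch-edge ramps are suppressed by background subtraction", {
  # couch band edge outside the flanking rows, so the background is affine
  # over the three sampled rows
  wob <- wobble_model(background = list(
    const = 20, slope_u = 0.4, slope_v = 0.6,
    couch = list(v0_mm = -30, step = 60, ramp_per_mm = 1.2)),
    noise_sd = 1, seed = 5)
  im <- render_mvi(angle_deg = 90, wobble = wob, geom = geom)
  row <- round(im$central_px[2])
  span <- c(round(im$central_px[1]) - 60, round(im$central_px[1]) + 60)
  bb <- extract_profile(im, "horizontal", row, span)
  res <- subtract_background(bb,
                             extract_profile(im, "horizontal", row - 70, span),
                             extract_profile(im, "horizontal", row + 70, span))
  n_edge <- floor(0.1 * nrow(res))
  baseline <- mean(c(head(res$value, n_edge), tail(res$value, n_edge)))
  expect_lt(abs(baseline), 0.01 * max(res$value))
})

test_that("FWHM centre is exact on symmetric and plateau peaks", {
  # symmetric triangle peaking at 50
  x <- seq(40, 60, by = 0.5)
  tri <- pmax(0, 5 - abs(x - 50))
  f <- fwhm_center(mrlqa:::new_bb_profile(x, tri))
  expect_equal(f$center_mm, 50)
  expect_equal(f$width_mm, 5)  # half-max at 2.5 -> crossings at 47.5, 52.5
  # flat-top plateau: centre at the plateau midpoint
  plat <- as.numeric(x >= 47 & x <= 53)
  fp <- fwhm_center(mrlqa:::new_bb_profile(x, plat))
  expect_equal(fp$center_mm, 50, tolerance = 0.26)
})

test_that("Gaussian FWHM matches the closed form", {
  f <- fwhm_center(gaussian_profile(sigma_mm = 2, spacing_mm = 0.25))
  expect_equal(f$width_mm, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.02 * 4.71)
  expect_equal(f$center_mm, 0, tolerance = 1e-9)
})

test_that("FWHM centre is translation-equivariant", {
  set.seed(7)
  for (delta in c(-3.2, 0.45, 7.77)) {
    p0 <- gaussian_profile(sigma_mm = 1.5, center_mm = 0)
    p1 <- mrlqa:::new_bb_profile(p0$position_mm + delta, p0$value)
    expect_equal(fwhm_center(p1)$center_mm, fwhm_center(p0)$center_mm + delta)
  }
})

test_that("FWHM errors on truncated and ambiguous peaks", {
  x <- seq(0, 10, by = 0.5)
  expect_error(fwhm_center(mrlqa:::new_bb_profile(x, x)), "truncated")
  two <- exp(-(x - 2)^2) + exp(-(x - 8)^2)
  expect_error(fwhm_center(mrlqa:::new_bb_profile(x, two)), "ambiguous")
  expect_error(fwhm_center(mrlqa:::new_bb_profile(x, rep(1, length(x)))),
               "no peak")
})

test_that("ballbearing localization recovers known offsets within 0.1 mm", {
  # a beam-axis offset displaces the image by -M times its component
  # perpendicular to the beam: x shows up at gantry 0, z at gantry 90
  set.seed(21)
  m <- magnification(geom)
  errs <- c()
  for (i in 1:6) {
    off <- runif(2, -2, 2)
    wob <- wobble_model(fixed_offset_mm = off, noise_sd = 3.5, seed = 30 + i)
    u0 <- locate_bb(render_mvi(angle_deg = 0, wobble = wob, geom = geom))$u_mm
    u90 <- locate_bb(render_mvi(angle_deg = 90, wobble = wob, geom = geom))$u_mm
    errs <- c(errs, abs(u0 - (-m * off[1])) / m,
              abs(u90 - (m * off[2])) / m)
  }
  expect_lt(mean(errs), 0.1)
})

test_that("a two-ballbearing ROI is reported as ambiguous", {
  im <- render_mvi(angle_deg = 0, wobble = wobble_model(),
                   field_cm = c(10, 9.4), geom = geom, shift_y_cm = -3.5)
  # wide ROI spanning the eclipsed centre and a peripheral pair
  expect_error(locate_bb(im, roi = list(rows = c(0, nrow(im$pixels) - 1),
                                        cols = c(0, ncol(im$pixels) - 1)),
                         background = FALSE),
               "ambiguous")
})

test_that("gantry reproducibility is zero against itself and errors on missing peaks", {
  im <- render_mvi(angle_deg = 0, wobble = wobble_model(noise_sd = 1, seed = 2),
                   field_cm = c(10, 9.4), geom = geom, shift_y_cm = -3.5)
  m <- gantry_reproducibility(im, im)
  expect_equal(m$rms_profile_diff, 0)
  expect_equal(m$peripheral_separation_diffs,
               rep(0, length(m$peripheral_separation_diffs)))
  expect_equal(m$eclipse_score, 1)
  # single-ballbearing image lacks the peripheral blobs of the ring baseline
  solo <- render_mvi(angle_deg = 0, wobble = wobble_model(noise_sd = 1, seed = 2),
                     field_cm = c(10, 9.4), geom = geom)
  expect_error(gantry_reproducibility(solo, im), "missing peripheral peaks")
})
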