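geom <- machine_geometry()

test_that("displacement back-projects through the magnification", {
  l0 <- displacement_to_axis_line(0, 123, geom)
  expect_equal(abs(l0$c), 0)
  # u = 1.5 mm at M = 1.5, gantry 0: vertical line at x = 1.0 mm
  l <- displacement_to_axis_line(1.5, 0, geom)
  expect_equal(l$px, 1.0)
  expect_equal(c(l$dx, l$dz), c(0, -1))
})

test_that("four tangent lines recover the circle they touch", {
  for (r in c(0.2, 0.5, 1.3)) {
    lines <- dplyr::bind_rows(
      axis_line_through(c(r, 0), 0), axis_line_through(c(0, r), 90),
      axis_line_through(c(-r, 0), 180), axis_line_through(c(0, -r), 270))
    fit <- fit_isocentre(lines)
    expect_equal(unname(fit$center_mm), c(0, 0), tolerance = 1e-9)
    expect_equal(fit$diameter_mm, 2 * r, tolerance = 1e-9)
  }
})

test_that("concurrent lines give a zero-diameter isocentre at their crossing", {
  p <- c(0.31, -0.17)
  lines <- dplyr::bind_rows(lapply(c(0, 45, 110, 200, 275),
                                   function(a) axis_line_through(p, a)))
  fit <- fit_isocentre(lines)
  expect_equal(unname(fit$center_mm), p, tolerance = 1e-9)
  expect_lt(fit$diameter_mm, 1e-9)
})

test_that("degenerate line sets are rejected", {
  expect_error(fit_isocentre(axis_line_through(c(0, 0), 0)),
               "insufficient angular coverage")
  parallel <- dplyr::bind_rows(
    axis_line_through(c(0, 0), 0), axis_line_through(c(1, 0), 0),
    axis_line_through(c(2, 0), 180))
  expect_error(fit_isocentre(parallel), "insufficient angular coverage")
})

test_that("the fit is equivariant under translation and rotation", {
  set.seed(5)
  lines <- random_line_set(9)
  fit <- fit_isocentre(lines)
  # translation
  t <- c(0.7, -0.4)
  moved <- lines
  moved$px <- lines$px + t[1]; moved$pz <- lines$pz + t[2]
  moved$c <- moved$nx * moved$px + moved$nz * moved$pz
  fit_t <- fit_isocentre(moved)
  expect_equal(unname(fit_t$center_mm), unname(fit$center_mm) + t,
               tolerance = 1e-9)
  expect_equal(fit_t$diameter_mm, fit$diameter_mm, tolerance = 1e-9)
  # rotation about the origin by phi
  phi <- 33 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  rot <- lines
  pr <- t(R %*% rbind(lines$px, lines$pz))
  nr <- t(R %*% rbind(lines$nx, lines$nz))
  rot$px <- pr[, 1]; rot$pz <- pr[, 2]
  rot$nx <- nr[, 1]; rot$nz <- nr[, 2]
  rot$c <- rot$nx * rot$px + rot$nz * rot$pz
  fit_r <- fit_isocentre(rot)
  expect_equal(unname(fit_r$center_mm),
               as.numeric(R %*% unname(fit$center_mm)), tolerance = 1e-9)
  expect_equal(fit_r$diameter_mm, fit$diameter_mm, tolerance = 1e-9)
})

test_that("adding a line never shrinks the minimax radius", {
  set.seed(8)
  for (i in 1:10) {
    lines <- random_line_set(6)
    extra <- random_line_set(1)
    d0 <- fit_isocentre(lines)$diameter_mm
    d1 <- fit_isocentre(dplyr::bind_rows(lines, extra))$diameter_mm
    expect_gte(d1, d0 - 1e-12)
  }
})

test_that("the residual invariants hold on noisy simulated line sets", {
  set.seed(12)
  ang <- default_isocentre_angles()
  wobble_off <- function(a) 0.2 * c(cos(2 * a * pi / 180),
                                    sin(2 * a * pi / 180))
  lines <- dplyr::bind_rows(lapply(ang, function(a) {
    e_u <- c(cos(a * pi / 180), -sin(a * pi / 180))
    off <- sum(wobble_off(a) * e_u) + rnorm(1, sd = 0.02)
    axis_line_through(off * e_u, a)
  }))
  fit <- fit_isocentre(lines)
  expect_true(all(fit$residuals_mm <= fit$diameter_mm / 2 + 1e-9))
  expect_equal(max(fit$residuals_mm), fit$diameter_mm / 2)
  # oracle agreement and truth proximity for the 0.4 mm harmonic wobble
  oracle <- grid_search_isocentre(lines, resolution_mm = 0.005)
  expect_lt(abs(fit$diameter_mm - oracle$diameter), 0.05)
  expect_lt(abs(fit$diameter_mm - 0.4), 0.1)
})

test_that("tidy, glance and autoplot expose the fit", {
  set.seed(3)
  fit <- fit_isocentre(random_line_set(7))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 7)
  expect_true("residual_mm" %in% names(td))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$within_tolerance_1mm == (gl$diameter_mm <= 1))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the full image pipeline handles exclusions and failures", {
  series <- render_projection_series(angles = c(0, 10, 45, 90, 135, 225, 315),
                                     wobble = wobble_model(), geom = geom)
  fit <- run_isocentre_analysis(series)
  expect_lt(fit$diameter_mm, 0.02)       # concurrent axes
  per <- fit$per_image
  expect_equal(per$status[per$angle_deg == 10], "excluded")
  expect_equal(fit$n_projections, 6)
  # too few usable projections errors
  short <- series[1:3]  # angles 0, 10 (excluded), 45
  expect_error(run_isocentre_analysis(short), "insufficient usable")
})

test_that("background subtraction improves localization under couch artifacts", {
  bg <- list(const = 15, slope_u = 0.3, slope_v = 0.5,
             couch = list(v0_mm = -16, step = 50, ramp_per_mm = 1.0))
  angles <- c(60, 75, 90, 105, 120)  # inside the distortion arc
  err_for <- function(mode) {
    wob <- wobble_model(background = bg, noise_sd = 1, seed = 14)
    series <- render_projection_series(angles = angles, wobble = wob,
                                       geom = geom)
    fit <- run_isocentre_analysis(series, excluded_angles = numeric(),
                                  background = mode)
    # truth: all axes through the origin -> per-line offsets are pure error
    stats::median(abs(fit$lines$c))
  }
  expect_lt(err_for("always"), err_for("never"))
})
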