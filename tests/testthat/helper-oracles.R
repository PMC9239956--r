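# Independent oracles used to validate the analytic implementations.

# Exhaustive grid search for the minimax (Chebyshev) centre of a set of
# lines: evaluates max point-to-line distance on a dense grid and returns
# the best grid point. Independent of the LP solver in fit_isocentre().
grid_search_isocentre <- function(lines, resolution_mm = 0.005, span_mm = 1) {
  xs <- seq(-span_mm, span_mm, by = resolution_mm)
  n <- length(xs)
  P <- cbind(rep(xs, times = n), rep(xs, each = n))
  D <- abs(P %*% t(cbind(lines$nx, lines$nz)) -
             matrix(lines$c, nrow(P), nrow(lines), byrow = TRUE))
  f <- do.call(pmax, as.data.frame(D))
  i <- which.min(f)
  list(center = P[i, ], radius = f[i], diameter = 2 * f[i])
}

# Brute-force exhaustive gamma: for each reference point, scan every
# evaluated position on a fine grid (a tenth of the analysis interpolation
# step) within the search radius.
gamma_oracle <- function(ref, ev, crit, step_frac = 0.01) {
  xs <- mrlqa:::grid_x(ref)
  ys <- mrlqa:::grid_y(ref)
  dmax <- max(ref$values)
  thr <- crit$suppression_pct / 100 * dmax
  h <- step_frac * crit$dta_mm
  rmax <- 3 * crit$dta_mm
  ks <- seq(-rmax, rmax, by = h)
  offs <- expand.grid(dx = ks, dy = ks)
  offs <- offs[offs$dx^2 + offs$dy^2 <= rmax^2, ]
  r2 <- (offs$dx^2 + offs$dy^2) / crit$dta_mm^2
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  for (j in seq_along(ys)) {
    for (i in seq_along(xs)) {
      dr <- ref$values[j, i]
      if (dr < thr || dr <= 0) next
      dd <- if (crit$normalization == "global") {
        crit$dose_diff_pct / 100 * dmax
      } else {
        crit$dose_diff_pct / 100 * dr
      }
      de <- mrlqa:::bilinear_at(ev, xs[i] + offs$dx, ys[j] + offs$dy)
      g2 <- ((de - dr) / dd)^2 + r2
      out[j, i] <- sqrt(min(g2, na.rm = TRUE))
    }
  }
  out
}

# Random beam-axis line sets: m lines at random gantry angles with random
# perpendicular offsets.
random_line_set <- function(m, offset_range_mm = 0.5) {
  ang <- runif(m, 0, 360)
  off <- runif(m, -offset_range_mm, offset_range_mm)
  dplyr::bind_rows(lapply(seq_len(m), function(j) {
    e_u <- c(cos(ang[j] * pi / 180), -sin(ang[j] * pi / 180))
    axis_line_through(off[j] * e_u, ang[j])
  }))
}

# Sampled Gaussian peak profile (closed-form FWHM = sigma * 2 sqrt(2 ln 2)).
gaussian_profile <- function(sigma_mm = 2, center_mm = 0, spacing_mm = 0.25,
                             half_extent_mm = 12, amplitude = 100,
                             baseline = 0) {
  x <- seq(-half_extent_mm, half_extent_mm, by = spacing_mm) + center_mm
  mrlqa:::new_bb_profile(x, baseline +
                           amplitude * exp(-(x - center_mm)^2 / (2 * sigma_mm^2)))
}
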