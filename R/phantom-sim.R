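#' MV alignment phantom description
#'
#' Geometry of the cylindrical alignment phantom used for gantry-angle and
#' isocentre QA: one central 10.0 mm ballbearing plus two rings of twelve
#' 4.0 mm ballbearings, radially arranged at 30.0 degree intervals and offset
#' longitudinally by +/- 3.5 cm from the phantom centre. The ring radius is
#' not a published value; the 6.5 cm default fits the 22.0 cm imaged width.
#'
#' @param central_bb_diameter_mm Diameter of the central ballbearing, mm.
#' @param ring_bb_diameter_mm Diameter of the ring ballbearings, mm.
#' @param ring_count Ballbearings per ring.
#' @param ring_angular_spacing_deg Angular spacing within a ring, degrees;
#'   `ring_count * ring_angular_spacing_deg` must equal 360.
#' @param ring_longitudinal_offset_cm Longitudinal offset of each ring from
#'   the phantom centre, cm (applied as +/-).
#' @param ring_radius_cm Ring radius, cm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(central_bb_diameter_mm = 10.0,
                         ring_bb_diameter_mm = 4.0,
                         ring_count = 12L,
                         ring_angular_spacing_deg = 30.0,
                         ring_longitudinal_offset_cm = 3.5,
                         ring_radius_cm = 6.5) {
  if (central_bb_diameter_mm <= 0 || ring_bb_diameter_mm <= 0) {
    stop("ballbearing diameters must be positive", call. = FALSE)
  }
  if (abs(ring_count * ring_angular_spacing_deg - 360) > 1e-9) {
    stop("`ring_count` x `ring_angular_spacing_deg` must equal 360",
         call. = FALSE)
  }
  structure(
    list(central_bb_diameter_mm = central_bb_diameter_mm,
         ring_bb_diameter_mm = ring_bb_diameter_mm,
         ring_count = as.integer(ring_count),
         ring_angular_spacing_deg = ring_angular_spacing_deg,
         ring_longitudinal_offset_cm = ring_longitudinal_offset_cm,
         ring_radius_cm = ring_radius_cm),
    class = "phantom_spec"
  )
}

#' Beam-axis wobble and image-degradation model
#'
#' Describes how the simulated beam axis wanders with gantry angle and what
#' degrades the images. The axis offset in the isocentre plane at true gantry
#' angle theta is
#' `o(theta) = fixed_offset + sum_k amp * cos(k * theta + phase)` per
#' component. A `gantry_angle_error_deg` rotates the whole acquisition.
#' `background` adds an affine intensity field and, optionally, a couch-edge
#' step-plus-ramp band crossing the image. All randomness (pixel noise) is
#' reproducible for a fixed `seed`.
#'
#' @param fixed_offset_mm Constant axis offset c(x, z), mm.
#' @param harmonics Data frame with columns `k`, `amp_x_mm`, `phase_x_deg`,
#'   `amp_z_mm`, `phase_z_deg` (one row per harmonic of gantry angle), or
#'   `NULL`. Amplitudes must be non-negative.
#' @param gantry_angle_error_deg Offset between set and true gantry angle.
#' @param noise_sd Additive Gaussian pixel noise standard deviation, in
#'   pixel-value units.
#' @param background `NULL`, or a list with any of `const`, `slope_u`,
#'   `slope_v` (pixel-value units and units/mm) and `couch = list(v0_mm,
#'   step, ramp_per_mm)` for the couch-edge artifact (applies at v >= v0_mm).
#' @param seed Integer RNG seed.
#' @return An object of class `wobble_model`.
#' @export
wobble_model <- function(fixed_offset_mm = c(0, 0), harmonics = NULL,
                         gantry_angle_error_deg = 0, noise_sd = 0,
                         background = NULL, seed = 1L) {
  stopifnot(length(fixed_offset_mm) == 2L, is.numeric(fixed_offset_mm))
  if (!is.null(harmonics)) {
    harmonics <- tibble::as_tibble(harmonics)
    need <- c("k", "amp_x_mm", "phase_x_deg", "amp_z_mm", "phase_z_deg")
    if (!all(need %in% names(harmonics))) {
      stop("`harmonics` needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(harmonics$amp_x_mm < 0) || any(harmonics$amp_z_mm < 0)) {
      stop("harmonic amplitudes must be non-negative", call. = FALSE)
    }
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(
    list(fixed_offset_mm = as.numeric(fixed_offset_mm), harmonics = harmonics,
         gantry_angle_error_deg = gantry_angle_error_deg,
         noise_sd = noise_sd, background = background,
         seed = as.integer(seed)),
    class = "wobble_model"
  )
}

#' True beam-axis offset for a wobble model
#'
#' @param wobble A [wobble_model()].
#' @param angle_deg True gantry angle, degrees.
#' @return c(x, z) axis offset at the isocentre plane, mm.
#' @export
wobble_axis_offset <- function(wobble, angle_deg) {
  o <- wobble$fixed_offset_mm
  h <- wobble$harmonics
  if (!is.null(h) && nrow(h)) {
    th <- angle_deg * pi / 180
    o[1] <- o[1] + sum(h$amp_x_mm * cos(h$k * th + h$phase_x_deg * pi / 180))
    o[2] <- o[2] + sum(h$amp_z_mm * cos(h$k * th + h$phase_z_deg * pi / 180))
  }
  o
}

# Separable Gaussian blur with edge replication; preserves the image integral
# away from the borders.
gauss_blur_mat <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  conv_cols <- function(mm) {
    nc <- ncol(mm)
    pad <- mm[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
    out <- matrix(0, nrow(mm), nc)
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[, i:(i + nc - 1L), drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

# Positions (mm, isocentre frame) of every ballbearing in the phantom.
# shift_y_cm translates the whole phantom longitudinally; -3.5 puts the
# superior ring centre at the isocentre plane.
phantom_bb_positions <- function(spec, shift_y_cm = 0) {
  y0 <- shift_y_cm * 10
  rows <- list(tibble::tibble(name = "central", x = 0, y = y0, z = 0,
                              diameter_mm = spec$central_bb_diameter_mm))
  phi <- seq(0, 360 - spec$ring_angular_spacing_deg,
             by = spec$ring_angular_spacing_deg) * pi / 180
  r_mm <- spec$ring_radius_cm * 10
  for (s in c(1, -1)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = sprintf("ring%+d_phi%03.0f", s, phi * 180 / pi),
      x = r_mm * sin(phi),
      y = y0 + s * spec$ring_longitudinal_offset_cm * 10,
      z = r_mm * cos(phi),
      diameter_mm = spec$ring_bb_diameter_mm
    )
  }
  dplyr::bind_rows(rows)
}

#' Render a synthetic portal image of the alignment phantom
#'
#' Projects every ballbearing through the configured geometry onto the imager
#' panel and renders it as an attenuation dip: within the projected disk of
#' radius `r`, the transmitted intensity is multiplied by
#' `1 - contrast * sqrt(1 - (rho/r)^2)` (a normalized projected-chord model,
#' so the integrated deficit scales with the projected area, i.e. with the
#' ballbearing diameter squared). Edges are then softened with a Gaussian
#' blur, an optional affine/couch-edge background is added, and Gaussian
#' pixel noise applied last. Ground truth (true angle, axis offset, projected
#' ballbearing centres) is carried in the image's `truth` field.
#'
#' The gantry ring is rigid: the beam-axis wobble displaces source and panel
#' together, so an axis offset `+o` moves the ballbearing image by `-M * o`
#' relative to the central pixel.
#'
#' @param spec A [phantom_spec()].
#' @param angle_deg Set gantry angle, degrees.
#' @param wobble A [wobble_model()].
#' @param field_cm Imaged field at the isocentre plane, c(x, y) cm; must fit
#'   the panel extent.
#' @param geom A [machine_geometry()].
#' @param shift_y_cm Longitudinal shift of the phantom, cm.
#' @param base Open-field pixel value.
#' @param contrast Maximum fractional dip of a ballbearing centre, in (0, 1).
#' @param blur_sigma_mm Gaussian edge blur at the panel, mm.
#' @param seed Optional seed override (defaults to `wobble$seed`).
#' @return A [portal_image()] whose `truth` field is a list with
#'   `angle_set_deg`, `angle_true_deg`, `axis_offset_mm` and `bb_panel`
#'   (tibble of projected centres).
#' @export
render_mvi <- function(spec = phantom_spec(), angle_deg = 0,
                       wobble = wobble_model(), field_cm = c(5.0, 5.7),
                       geom = machine_geometry(), shift_y_cm = 0,
                       base = 1000, contrast = 0.35, blur_sigma_mm = 0.5,
                       seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(wobble, "wobble_model"))
  if (any(field_cm > geom$panel_extent_cm + 1e-9)) {
    stop(sprintf("field %.1f x %.1f cm exceeds the panel extent %.1f x %.1f cm at isocentre",
                 field_cm[1], field_cm[2],
                 geom$panel_extent_cm[1], geom$panel_extent_cm[2]),
         call. = FALSE)
  }
  pitch <- geom$pixel_pitch_mm
  m <- magnification(geom)
  half_u <- field_cm[1] * 10 * m / 2
  half_v <- field_cm[2] * 10 * m / 2
  nu <- 2L * floor(half_u / pitch) + 1L
  nv <- 2L * floor(half_v / pitch) + 1L
  cu <- (nu - 1) / 2
  cv <- (nv - 1) / 2
  u <- (seq_len(nu) - 1 - cu) * pitch
  v <- (seq_len(nv) - 1 - cv) * pitch

  angle_true <- angle_deg + wobble$gantry_angle_error_deg
  axis <- wobble_axis_offset(wobble, angle_true)

  bbs <- phantom_bb_positions(spec, shift_y_cm)
  proj <- purrr::pmap_dfr(bbs, function(name, x, y, z, diameter_mm) {
    p <- project_point_panel(c(x, y, z), angle_true, geom, axis_offset_mm = axis)
    tibble::tibble(name = name, u_mm = p[["u"]], v_mm = p[["v"]],
                   r_panel_mm = diameter_mm / 2 * p[["mag"]])
  })
  margin <- max(proj$r_panel_mm) + 4 * blur_sigma_mm
  vis <- proj[abs(proj$u_mm) <= half_u + margin &
                abs(proj$v_mm) <= half_v + margin, , drop = FALSE]

  trans <- matrix(1, nv, nu)
  for (i in seq_len(nrow(vis))) {
    du2 <- (u - vis$u_mm[i])^2
    dv2 <- (v - vis$v_mm[i])^2
    rho2 <- outer(dv2, du2, `+`)
    arg <- 1 - rho2 / vis$r_panel_mm[i]^2
    arg[arg < 0] <- 0
    trans <- trans * (1 - contrast * sqrt(arg))
  }
  img <- base * trans
  img <- gauss_blur_mat(img, blur_sigma_mm / pitch)

  bg <- wobble$background
  if (!is.null(bg)) {
    add <- matrix(bg$const %||% 0, nv, nu)
    if (!is.null(bg$slope_u)) add <- add + outer(rep(1, nv), bg$slope_u * u)
    if (!is.null(bg$slope_v)) add <- add + outer(bg$slope_v * v, rep(1, nu))
    if (!is.null(bg$couch)) {
      cc <- bg$couch
      band <- pmax(0, v - cc$v0_mm)
      add <- add + outer((v >= cc$v0_mm) * cc$step +
                           (cc$ramp_per_mm %||% 0) * band, rep(1, nu))
    }
    img <- img + add
  }
  if (wobble$noise_sd > 0) {
    withr::with_seed(seed %||% wobble$seed, {
      img <- img + matrix(rnorm(nv * nu, sd = wobble$noise_sd), nv, nu)
    })
  }
  portal_image(img, gantry_angle_deg = angle_deg, geom = geom,
               central_px = c(cu, cv),
               truth = list(angle_set_deg = normalize_gantry_angle(angle_deg),
                            angle_true_deg = angle_true,
                            axis_offset_mm = axis,
                            shift_y_cm = shift_y_cm,
                            bb_panel = vis))
}

#' Default gantry-angle list for an isocentre series
#'
#' Ten-degree steps over a full rotation, dropping the angles routinely
#' excluded on this machine type: 10 and 20 degrees (cryostat cross-over
#' pipe in the beam) and 60 and 300 degrees (couch edges across the
#' ballbearing image).
#'
#' @param step_deg Angular step, degrees.
#' @param exclude Angles to drop, degrees.
#' @return Numeric vector of gantry angles.
#' @export
default_isocentre_angles <- function(step_deg = 10,
                                     exclude = c(10, 20, 60, 300)) {
  a <- seq(0, 360 - step_deg, by = step_deg)
  a[!a %in% exclude]
}

#' Render a full projection series of the central ballbearing
#'
#' One portal image per requested angle (duplicates allowed: acquiring with
#' both rotation senses images some angles twice). Pixel noise is seeded per
#' image from `wobble$seed` so the series is reproducible as a whole.
#'
#' @inheritParams render_mvi
#' @param angles Gantry angles, degrees; default [default_isocentre_angles()].
#' @param ... Passed on to [render_mvi()].
#' @return List of [portal_image()]s, with an attribute `truth`: a tibble of
#'   per-image true angles and axis offsets.
#' @export
render_projection_series <- function(spec = phantom_spec(),
                                     angles = default_isocentre_angles(),
                                     wobble = wobble_model(),
                                     geom = machine_geometry(), ...) {
  imgs <- purrr::imap(angles, function(a, i) {
    render_mvi(spec, a, wobble, geom = geom, seed = wobble$seed + i, ...)
  })
  truth <- purrr::map_dfr(imgs, function(im) {
    tibble::tibble(angle_set_deg = im$truth$angle_set_deg,
                   angle_true_deg = im$truth$angle_true_deg,
                   axis_x_mm = im$truth$axis_offset_mm[1],
                   axis_z_mm = im$truth$axis_offset_mm[2])
  })
  attr(imgs, "truth") <- truth
  imgs
}

#' True beam-axis lines of a simulated series
#'
#' Converts the per-image ground-truth axis offsets of a
#' [render_projection_series()] result into beam-axis lines, for comparison
#' with the lines recovered by the image analysis.
#'
#' @param series Output of [render_projection_series()].
#' @return A tibble of axis lines (see [displacement_to_axis_line()]).
#' @export
true_axis_lines <- function(series) {
  truth <- attr(series, "truth")
  if (is.null(truth)) stop("series carries no ground truth", call. = FALSE)
  purrr::pmap_dfr(truth, function(angle_set_deg, angle_true_deg,
                                  axis_x_mm, axis_z_mm) {
    axis_line_through(c(axis_x_mm, axis_z_mm), angle_true_deg)
  })
}

#' Generate a reference/evaluated dose-map pair with known perturbation
#'
#' Builds an analytic reference pattern on a uniform grid and an evaluated
#' grid that differs from it by exactly the stated perturbation: a uniform
#' dose scaling, a rigid in-plane shift (applied analytically, so no
#' resampling error), and multiplicative Gaussian noise.
#'
#' Patterns: `"uniform"` (flat 1 Gy), `"wedge"` (linear 1 %/mm ramp along x),
#' `"peaked_fff"` (radially peaked flattening-filter-free-like field with a
#' sigmoid edge), `"multi_gaussian"` (three off-centre Gaussians on a low
#' base).
#'
#' @param pattern One of `"uniform"`, `"wedge"`, `"peaked_fff"`,
#'   `"multi_gaussian"`.
#' @param dose_scale_pct Uniform dose error of the evaluated map, percent.
#' @param shift_mm Rigid shift c(x, y) of the evaluated map, mm.
#' @param noise_pct Multiplicative Gaussian noise SD, percent of local dose.
#' @param spacing_mm Grid spacing, mm; > 0.
#' @param extent_mm Physical grid extent c(x, y), mm, centred on the origin.
#' @param seed RNG seed for the noise.
#' @return `list(ref = dose_grid, eval = dose_grid)`.
#' @export
make_dose_pair <- function(pattern = c("uniform", "wedge", "peaked_fff",
                                       "multi_gaussian"),
                           dose_scale_pct = 0, shift_mm = c(0, 0),
                           noise_pct = 0, spacing_mm = 2,
                           extent_mm = c(60, 60), seed = 1L) {
  pattern <- match.arg(pattern)
  if (spacing_mm <= 0) stop("`spacing_mm` must be positive", call. = FALSE)
  f <- switch(pattern,
    uniform = function(x, y) rep(1, length(x)),
    wedge = function(x, y) 1 + 0.01 * x,
    peaked_fff = function(x, y) {
      r <- sqrt(x^2 + y^2)
      (1 + 0.08 * exp(-(r / 40)^2)) / (1 + exp((r - 0.45 * min(extent_mm)) / 3))
    },
    multi_gaussian = function(x, y) {
      0.1 +
        1.0 * exp(-((x - 10)^2 + (y - 5)^2) / (2 * 8^2)) +
        0.7 * exp(-((x + 12)^2 + (y + 8)^2) / (2 * 6^2)) +
        0.5 * exp(-((x + 2)^2 + (y - 14)^2) / (2 * 10^2))
    })
  xs <- seq(-extent_mm[1] / 2, extent_mm[1] / 2, by = spacing_mm)
  ys <- seq(-extent_mm[2] / 2, extent_mm[2] / 2, by = spacing_mm)
  xy <- expand.grid(x = xs, y = ys)
  ref_v <- matrix(f(xy$x, xy$y), nrow = length(ys), byrow = TRUE)
  ev_v <- matrix(f(xy$x - shift_mm[1], xy$y - shift_mm[2]),
                 nrow = length(ys), byrow = TRUE)
  ev_v <- ev_v * (1 + dose_scale_pct / 100)
  if (noise_pct > 0) {
    withr::with_seed(seed, {
      ev_v <- ev_v * (1 + matrix(rnorm(length(ev_v), sd = noise_pct / 100),
                                 nrow(ev_v), ncol(ev_v)))
    })
  }
  ev_v[ev_v < 0] <- 0
  org <- c(xs[1], ys[1])
  list(ref = dose_grid(ref_v, spacing_mm, org),
       eval = dose_grid(ev_v, spacing_mm, org))
}

#' Simulate ionization-chamber reading series with known truth
#'
#' Produces the delimited-reading tables the reference-dosimetry chain
#' consumes, generated from a known beam-quality/output truth so the pipeline
#' can be checked by parameter recovery. Each session holds triplet readings
#' at the depths needed for TPR(20,10) and TPR(10,5), plus a corrected output
#' reading at 10 cm from the lateral (G90) beam, with influence-quantity
#' bookkeeping (temperature, pressure, polarity and two-voltage readings)
#' consistent with the stated correction factors.
#'
#' @param truth List with `tpr_20_10`, `tpr_10_5`, `output_gy_per_100mu`.
#' @param noise_cv Coefficient of variation of a single reading (fractional,
#'   e.g. 0.003 for 0.3 %).
#' @param n_sessions Number of measurement sessions.
#' @param n_repeats Readings per depth per session.
#' @param constants List of chamber constants: `n_dw` (Gy per reading unit),
#'   `k_bmq`, `c_b`, `k_pol_true`, `k_s_true`, `voltage_ratio`.
#' @param seed RNG seed.
#' @return List with `readings` (tibble: session, quantity, repeat, reading,
#'   mu, temperature_c, pressure_kpa, m_plus, m_minus, m_v1, m_v2,
#'   voltage_ratio) and `constants`.
#' @export
simulate_chamber_series <- function(truth = list(tpr_20_10 = 0.705,
                                                 tpr_10_5 = 0.858,
                                                 output_gy_per_100mu = 1.000),
                                    noise_cv = 0.003, n_sessions = 7,
                                    n_repeats = 3,
                                    constants = list(n_dw = 5.4e-2,
                                                     k_bmq = 0.995,
                                                     c_b = 0.995,
                                                     k_pol_true = 1.001,
                                                     k_s_true = 1.004,
                                                     voltage_ratio = 2),
                                    seed = 1L) {
  stopifnot(n_sessions >= 1, n_repeats >= 1, noise_cv >= 0)
  k_bq <- combine_kb(constants$k_bmq, constants$c_b)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(n_sessions), function(s) {
      temp <- round(rnorm(1, 21, 0.8), 2)
      pres <- round(rnorm(1, 100.8, 0.6), 2)
      ktp <- k_tp(temp, pres)
      noisy <- function(x, n = n_repeats) x * (1 + rnorm(n, sd = noise_cv))
      # Raw reading at 10 cm (G90) that the correction chain maps back to the
      # true output: D10 = D5 * tpr_10_5, M_raw = D10 / (all corrections).
      d10 <- truth$output_gy_per_100mu * truth$tpr_10_5
      m10 <- d10 / (ktp * constants$k_pol_true * constants$k_s_true *
                      k_bq * constants$n_dw)
      base5 <- m10 / truth$tpr_10_5 # shallow TPR(10,5) reading, same scale
      out <- tibble::tibble(
        session = s,
        quantity = rep(c("tpr20_shallow", "tpr20_deep", "tpr5", "tpr10",
                         "output_g90"), each = n_repeats),
        rep = rep(seq_len(n_repeats), times = 5),
        reading = c(noisy(base5), noisy(base5 * truth$tpr_20_10),
                    noisy(base5), noisy(base5 * truth$tpr_10_5),
                    noisy(m10)),
        mu = 100,
        temperature_c = temp,
        pressure_kpa = pres
      )
      out$m_plus <- out$reading
      out$m_minus <- -(2 * constants$k_pol_true - 1) * out$reading
      r <- solve_two_voltage_ratio(constants$k_s_true, constants$voltage_ratio)
      out$m_v1 <- out$reading
      out$m_v2 <- out$reading / r
      out$voltage_ratio <- constants$voltage_ratio
      out
    })
  })
  list(readings = rows, constants = constants)
}
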