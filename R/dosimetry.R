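# Half-away-from-zero rounding, the convention of reported physics values
# (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(x * p + sign(x) * 0.5 + sign(x) * 1e-12) / p
}

#' Temperature-pressure correction factor
#'
#' Air-density correction for a vented ionization chamber,
#' `k_tp = (273.2 + T) / (273.2 + T_ref) * P_ref / P` (TRS-398 convention).
#' Equals 1 at reference conditions (20.0 C, 101.325 kPa).
#'
#' @param temperature_c Air temperature, Celsius; physical range -10..50.
#' @param pressure_kpa Air pressure, kPa; > 0.
#' @param t_ref_c,p_ref_kpa Reference conditions.
#' @return Correction factor (vectorized).
#' @export
k_tp <- function(temperature_c, pressure_kpa, t_ref_c = 20.0,
                 p_ref_kpa = 101.325) {
  if (any(pressure_kpa <= 0)) stop("`pressure_kpa` must be positive", call. = FALSE)
  if (any(temperature_c < -10 | temperature_c > 50)) {
    stop("`temperature_c` outside the physical range -10..50 C", call. = FALSE)
  }
  (273.2 + temperature_c) / (273.2 + t_ref_c) * p_ref_kpa / pressure_kpa
}

#' Polarity correction factor
#'
#' Two-polarity correction `k_pol = (|M+| + |M-|) / (2 |M|)` with `M` the
#' reading at the routinely used polarity (taken to be `m_plus`).
#'
#' @param m_plus Reading at the routine polarity (non-zero).
#' @param m_minus Reading at the opposite polarity (non-zero; sign may be
#'   negative, magnitudes are used).
#' @return Correction factor (vectorized).
#' @export
k_pol <- function(m_plus, m_minus) {
  if (any(m_plus == 0) || any(m_minus == 0)) {
    stop("polarity readings must be non-zero", call. = FALSE)
  }
  (abs(m_plus) + abs(m_minus)) / (2 * abs(m_plus))
}

# TRS-398 two-voltage quadratic coefficients for pulsed beams,
# k_s = a0 + a1 (M1/M2) + a2 (M1/M2)^2, tabulated against V1/V2 and
# interpolated linearly in the voltage ratio.
ks_pulsed_coef <- data.frame(
  ratio = c(2.0, 2.5, 3.0, 3.5, 4.0, 5.0),
  a0 = c(2.337, 1.474, 1.198, 1.080, 1.022, 0.975),
  a1 = c(-3.636, -1.587, -0.875, -0.542, -0.363, -0.188),
  a2 = c(2.299, 1.114, 0.677, 0.463, 0.341, 0.214)
)

ks_coefs_at <- function(voltage_ratio) {
  if (voltage_ratio < min(ks_pulsed_coef$ratio) ||
      voltage_ratio > max(ks_pulsed_coef$ratio)) {
    stop("`voltage_ratio` must lie in [2, 5] for the pulsed-beam two-voltage ",
         "coefficients", call. = FALSE)
  }
  sapply(c("a0", "a1", "a2"), function(cn) {
    approx(ks_pulsed_coef$ratio, ks_pulsed_coef[[cn]], voltage_ratio)$y
  })
}

#' Recombination correction factor (two-voltage method, pulsed beam)
#'
#' `k_s = a0 + a1 (M1/M2) + a2 (M1/M2)^2` with the pulsed-beam coefficients
#' of the two-voltage method, interpolated in the voltage ratio `V1/V2`
#' (valid range 2..5). Equals 1 when the two readings are equal.
#'
#' @param m_v1 Reading at the normal (higher) voltage; non-zero.
#' @param m_v2 Reading at the reduced voltage; non-zero.
#' @param voltage_ratio `V1/V2`, > 1 (and within 2..5 for the tabulated
#'   coefficients).
#' @return Correction factor.
#' @export
k_s <- function(m_v1, m_v2, voltage_ratio = 2) {
  if (any(voltage_ratio <= 1)) {
    stop("`voltage_ratio` must exceed 1", call. = FALSE)
  }
  if (any(m_v1 == 0) || any(m_v2 == 0)) {
    stop("two-voltage readings must be non-zero", call. = FALSE)
  }
  a <- ks_coefs_at(voltage_ratio)
  r <- m_v1 / m_v2
  unname(a[1] + a[2] * r + a[3] * r^2)
}

# Invert the pulsed two-voltage quadratic: reading ratio M1/M2 (root >= 1)
# that yields a given k_s. Used by the simulator to construct consistent
# reduced-voltage readings.
solve_two_voltage_ratio <- function(ks_target, voltage_ratio = 2) {
  a <- ks_coefs_at(voltage_ratio)
  roots <- polyroot(c(a[1] - ks_target, a[2], a[3]))
  roots <- Re(roots[abs(Im(roots)) < 1e-8])
  r <- roots[roots >= 1 - 1e-9]
  if (!length(r)) stop("no physical reading ratio for k_s = ", ks_target,
                       call. = FALSE)
  min(r)
}

#' Combine detector and dose-conversion magnetic-field factors
#'
#' The combined magnetic-field correction for an ionization chamber with its
#' axis parallel to a 1.5 T field is the product of the detector-response
#' factor `k_B,M,Q` and the dose-to-water conversion factor `c_B`, reported
#' to three decimals.
#'
#' @param k_bmq Detector magnetic-field response factor, in (0.9, 1.1).
#' @param c_b Dose conversion factor, in (0.9, 1.1).
#' @return Combined factor `k_B,Q`, rounded to 3 decimals (vectorized).
#' @export
combine_kb <- function(k_bmq, c_b) {
  if (any(k_bmq <= 0.9 | k_bmq >= 1.1) || any(c_b <= 0.9 | c_b >= 1.1)) {
    stop("magnetic-field factors outside the plausible range (0.9, 1.1)",
         call. = FALSE)
  }
  round_half_up(k_bmq * c_b, 3)
}

#' Tissue-phantom ratio from reading sets
#'
#' Ratio of mean deep to mean shallow chamber readings at fixed
#' source-chamber distance. When readings are grouped by session, the ratio
#' is formed per session and the across-session mean and SD are reported.
#'
#' @param readings_deep,readings_shallow Numeric vectors of raw readings, or
#'   data frames with columns `session` and `reading`.
#' @return A tibble with `tpr`, `sd` (NA for a single session) and
#'   `n_sessions`.
#' @export
tpr <- function(readings_deep, readings_shallow) {
  as_sessions <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("session", "reading") %in% names(x)))
      split(x$reading, x$session)
    } else {
      list(`1` = as.numeric(x))
    }
  }
  deep <- as_sessions(readings_deep)
  shallow <- as_sessions(readings_shallow)
  if (!length(deep) || !length(shallow) ||
      !identical(sort(names(deep)), sort(names(shallow)))) {
    stop("deep and shallow readings must cover the same sessions", call. = FALSE)
  }
  ratios <- purrr::map_dbl(names(deep), function(s) {
    ms <- mean(shallow[[s]])
    if (ms == 0) stop("shallow reading mean is zero", call. = FALSE)
    mean(deep[[s]]) / ms
  })
  tibble::tibble(tpr = mean(ratios),
                 sd = if (length(ratios) > 1) sd(ratios) else NA_real_,
                 n_sessions = length(ratios))
}

#' Machine output from a lateral-beam reading at 10 cm depth
#'
#' Reference-output chain for a machine calibrated at 5.0 cm depth but
#' measured from the lateral (G90) direction at 10.0 cm depth, where the
#' water tank can reach the isocentre: the fully corrected dose at 10 cm is
#' transferred to 5 cm with the TPR(10,5) measured from the vertical beam,
#' `D(5) = D(10) / TPR(10,5)`.
#'
#' `D(10) = M_raw * k_tp * k_pol * k_s * k_BQ * N_DW * 100 / MU`.
#' Every correction must be supplied or derivable from the reading's
#' influence-quantity fields; anything missing raises an error naming it.
#'
#' @param reading A list or one-row data frame with `reading`, `mu`, and the
#'   influence-quantity fields `temperature_c`, `pressure_kpa`
#'   (or a precomputed `k_tp` in `corrections`), `m_plus`/`m_minus` (or
#'   `k_pol`), `m_v1`/`m_v2`/`voltage_ratio` (or `k_s`).
#' @param corrections List with `n_dw` (Gy per reading unit) and either
#'   `k_bq` or both `k_bmq` and `c_b`; may also carry precomputed `k_tp`,
#'   `k_pol`, `k_s`.
#' @param tpr_10_5 TPR(10,5) depth-transfer ratio, in (0, 1].
#' @return A tibble with `d10_gy_per_100mu`, `d5_gy_per_100mu` and the
#'   individual correction factors applied.
#' @export
output_from_g90 <- function(reading, corrections, tpr_10_5) {
  if (!is.numeric(tpr_10_5) || tpr_10_5 <= 0 || tpr_10_5 > 1) {
    stop("`tpr_10_5` must lie in (0, 1]", call. = FALSE)
  }
  r <- as.list(reading)
  co <- as.list(corrections)
  missing <- character()
  if (is.null(r$reading)) missing <- c(missing, "reading")
  if (is.null(r$mu)) missing <- c(missing, "mu")
  if (is.null(co$n_dw)) missing <- c(missing, "n_dw")
  ktp <- co$k_tp %||% if (!is.null(r$temperature_c) && !is.null(r$pressure_kpa)) {
    k_tp(r$temperature_c, r$pressure_kpa)
  }
  if (is.null(ktp)) missing <- c(missing, "k_tp (or temperature_c + pressure_kpa)")
  kpol <- co$k_pol %||% if (!is.null(r$m_plus) && !is.null(r$m_minus)) {
    k_pol(r$m_plus, r$m_minus)
  }
  if (is.null(kpol)) missing <- c(missing, "k_pol (or m_plus + m_minus)")
  ks <- co$k_s %||% if (!is.null(r$m_v1) && !is.null(r$m_v2)) {
    k_s(r$m_v1, r$m_v2, r$voltage_ratio %||% 2)
  }
  if (is.null(ks)) missing <- c(missing, "k_s (or m_v1 + m_v2)")
  kbq <- co$k_bq %||% if (!is.null(co$k_bmq) && !is.null(co$c_b)) {
    combine_kb(co$k_bmq, co$c_b)
  }
  if (is.null(kbq)) missing <- c(missing, "k_bq (or k_bmq + c_b)")
  if (length(missing)) {
    stop("missing corrections: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  d10 <- mean(r$reading) * ktp[1] * kpol[1] * ks[1] * kbq[1] * co$n_dw *
    100 / r$mu[1]
  tibble::tibble(d10_gy_per_100mu = d10,
                 d5_gy_per_100mu = d10 / tpr_10_5,
                 k_tp = ktp[1], k_pol = kpol[1], k_s = ks[1], k_bq = kbq[1],
                 n_dw = co$n_dw, tpr_10_5 = tpr_10_5)
}

#' Expected vertical-beam output from the lateral-beam output
#'
#' The cryostat transmits slightly more at gantry 0 than at gantry 90 on this
#' machine type; a machine calibrated to `g90_output` at G90 is therefore
#' expected to read `g90_output * (1 + diff/100)` from G0 (nominally
#' 1.005 Gy per 100 MU for a 1.000 Gy calibration and a 0.5 % difference).
#'
#' @param g90_output Output measured from G90, Gy per 100 MU; > 0.
#' @param cryostat_diff_pct Percent by which G0 exceeds G90.
#' @return Expected G0 output, rounded to 3 decimals.
#' @export
expected_g0_output <- function(g90_output, cryostat_diff_pct = 0.5) {
  if (any(g90_output <= 0)) stop("`g90_output` must be positive", call. = FALSE)
  round_half_up(g90_output * (1 + cryostat_diff_pct / 100), 3)
}

#' Beam attenuation from paired readings
#'
#' Percent attenuation `100 * (1 - with / without)` of a beam by an object
#' (here the anterior imaging coil), from chamber readings with and without
#' the object in the beam. Negative values (noise exceeding the effect) are
#' allowed.
#'
#' @param with_reading Reading with the attenuator present.
#' @param without_reading Reading without it; must be non-zero.
#' @param digits Decimals for reporting (default 1); `NULL` for unrounded.
#' @return Attenuation in percent (vectorized).
#' @export
attenuation_pct <- function(with_reading, without_reading, digits = 1) {
  if (any(without_reading == 0)) {
    stop("`without_reading` must be non-zero", call. = FALSE)
  }
  a <- 100 * (1 - with_reading / without_reading)
  if (is.null(digits)) a else round_half_up(a, digits)
}

#' Mean attenuation over gantry angles
#'
#' Average and SD of per-angle attenuation records. Angles at which the beam
#' misses the attenuator entirely (recorded as 0.0 %) are excluded by
#' default, so the mean describes the attenuation when the coil is actually
#' in the beam.
#'
#' @param records Data frame with a column `attenuation_pct` (and optionally
#'   `gantry_angle_deg`), or a numeric vector of attenuations.
#' @param exclude_zero Drop records with `attenuation_pct <= 0`?
#' @param digits Decimals for reporting (default 1).
#' @return A tibble with `mean_pct`, `sd_pct`, `n`.
#' @export
mean_attenuation <- function(records, exclude_zero = TRUE, digits = 1) {
  a <- if (is.data.frame(records)) {
    stopifnot("attenuation_pct" %in% names(records))
    records$attenuation_pct
  } else {
    as.numeric(records)
  }
  if (exclude_zero) a <- a[a > 0]
  if (!length(a)) {
    stop("no attenuation records left after exclusion", call. = FALSE)
  }
  tibble::tibble(mean_pct = round_half_up(mean(a), digits),
                 sd_pct = if (length(a) > 1) round_half_up(sd(a), digits) else NA_real_,
                 n = length(a))
}

#' Run the full reference-dosimetry chain on a reading table
#'
#' Consumes the long reading table produced by [simulate_chamber_series()]
#' (or read from delimited text with the same columns) and recovers the
#' beam-quality ratios and the machine output at 5 cm: TPR(20,10) and
#' TPR(10,5) from the per-session reading ratios, then [output_from_g90()]
#' per session.
#'
#' @param readings Tibble with columns `session`, `quantity`
#'   (`tpr20_shallow`, `tpr20_deep`, `tpr5`, `tpr10`, `output_g90`),
#'   `reading`, `mu`, `temperature_c`, `pressure_kpa`, `m_plus`, `m_minus`,
#'   `m_v1`, `m_v2`, `voltage_ratio`.
#' @param constants List with `n_dw` and `k_bmq` + `c_b` (or `k_bq`).
#' @return A list with `tpr_20_10`, `tpr_10_5` (tibbles from [tpr()]),
#'   `per_session` (tibble of outputs) and `output` (tibble with mean, sd,
#'   cv_pct, n).
#' @export
run_reference_dosimetry <- function(readings, constants) {
  q <- function(qq) readings[readings$quantity == qq, , drop = FALSE]
  tpr2010 <- tpr(q("tpr20_deep"), q("tpr20_shallow"))
  tpr105 <- tpr(q("tpr10"), q("tpr5"))
  out_rows <- q("output_g90")
  per_session <- purrr::map_dfr(split(out_rows, out_rows$session), function(ss) {
    res <- output_from_g90(
      list(reading = ss$reading, mu = ss$mu[1],
           temperature_c = ss$temperature_c[1], pressure_kpa = ss$pressure_kpa[1],
           m_plus = ss$m_plus[1], m_minus = ss$m_minus[1],
           m_v1 = ss$m_v1[1], m_v2 = ss$m_v2[1],
           voltage_ratio = ss$voltage_ratio[1]),
      constants, tpr_10_5 = tpr105$tpr)
    dplyr::bind_cols(tibble::tibble(session = ss$session[1]), res)
  })
  out <- per_session$d5_gy_per_100mu
  list(
    tpr_20_10 = tpr2010,
    tpr_10_5 = tpr105,
    per_session = per_session,
    output = tibble::tibble(
      d5_gy_per_100mu = mean(out),
      sd = if (length(out) > 1) sd(out) else NA_real_,
      cv_pct = if (length(out) > 1) 100 * sd(out) / mean(out) else NA_real_,
      n = length(out))
  )
}

#' Bundled anterior-coil attenuation example
#'
#' Per-gantry-angle attenuation of the anterior imaging coil on one
#' commissioned MR-linac: chamber measurements with/without the coil and the
#' matching Monte Carlo TPS calculation, in percent, for 15-degree steps over
#' the arc where the couch does not shadow the chamber. At 75 and 285 degrees
#' the beam misses the coil (0.0 %).
#'
#' @return A tibble with `gantry_angle_deg`, `measured_pct`, `calculated_pct`.
#' @export
coil_attenuation_table <- function() {
  tibble::tibble(
    gantry_angle_deg = c(75, 60, 45, 30, 0, 345, 330, 315, 300, 285),
    measured_pct = c(0.0, 0.6, 0.6, 0.5, 0.5, 0.4, 0.7, 0.6, 0.6, 0.0),
    calculated_pct = c(0.0, 0.8, 0.9, 1.0, 0.7, 0.8, 0.9, 0.8, 0.7, 0.0)
  )
}

#' Bundled chamber magnetic-field factors
#'
#' Detector-specific magnetic-field response factors `k_B,M,Q` measured for
#' two Farmer-type chambers at the two candidate calibration depths in a
#' 1.5 T parallel field, plus the published dose conversion factor `c_B`.
#'
#' @return A list with `factors` (tibble: `serial`, `depth_cm`, `k_bmq`) and
#'   `c_b`.
#' @export
chamber_field_factors <- function() {
  list(
    factors = tibble::tibble(
      serial = c("10765", "11298", "10765", "11298"),
      depth_cm = c(5, 5, 10, 10),
      k_bmq = c(0.995, 0.996, 0.999, 0.999)
    ),
    c_b = 0.995
  )
}
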