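test_that("k_tp follows the air-density closed form", {
  expect_equal(k_tp(20.0, 101.325), 1.0000, tolerance = 1e-9)
  expect_equal(k_tp(22.93, 101.325), 1.0100, tolerance = 1e-4)
  expect_equal(k_tp(20.0, 100.32), 1.0100, tolerance = 1e-4)
  expect_error(k_tp(20, -1), "positive")
  expect_error(k_tp(80, 101), "physical")
})

test_that("k_pol and k_s are unity in the degenerate cases and invert exactly", {
  expect_equal(k_pol(12.3, -12.3), 1.000)
  expect_equal(k_s(5, 5), 1.000, tolerance = 1e-9)
  expect_error(k_pol(0, 1), "non-zero")
  expect_error(k_s(1, 1, voltage_ratio = 1), "exceed")
  # synthetic readings built from an assumed k_s recover it to 4 decimals
  for (ks_true in c(1.002, 1.004, 1.008)) {
    r <- mrlqa:::solve_two_voltage_ratio(ks_true, 2)
    expect_equal(k_s(100, 100 / r, 2), ks_true, tolerance = 5e-5)
  }
  # and an assumed k_pol likewise
  kp <- 1.003
  expect_equal(k_pol(50, -(2 * kp - 1) * 50), kp)
})

test_that("magnetic-field factors combine to the reported 3-decimal products", {
  expect_equal(combine_kb(0.995, 0.995), 0.990)
  expect_equal(combine_kb(0.996, 0.995), 0.991)
  expect_equal(combine_kb(0.999, 0.995), 0.994)
  expect_equal(combine_kb(1.000, 1.000), 1.000)
  expect_error(combine_kb(0.5, 0.995), "plausible")
})

test_that("tpr handles vectors, sessions and degenerate input", {
  expect_equal(tpr(c(7.05), c(10.00))$tpr, 0.705)
  expect_equal(tpr(rep(5, 3), rep(5, 3))$tpr, 1.000)
  expect_error(tpr(1, 0), "zero")
  df_deep <- data.frame(session = rep(1:4, each = 3), reading = rep(7.05, 12))
  df_shal <- data.frame(session = rep(1:4, each = 3), reading = rep(10, 12))
  res <- tpr(df_deep, df_shal)
  expect_equal(res$n_sessions, 4)
  expect_equal(res$sd, 0)
  expect_error(tpr(df_deep, data.frame(session = 1, reading = 1)), "sessions")
})

test_that("tpr recovers a simulated truth within sampling error", {
  sim <- simulate_chamber_series(truth = list(tpr_20_10 = 0.705,
                                              tpr_10_5 = 0.858,
                                              output_gy_per_100mu = 1),
                                 noise_cv = 0.001, n_sessions = 6, seed = 4)
  r <- sim$readings
  res <- tpr(r[r$quantity == "tpr20_deep", ], r[r$quantity == "tpr20_shallow", ])
  expect_lt(abs(res$tpr - 0.705), 0.002)
})

test_that("the output chain is consistent arithmetic and linear in its inputs", {
  reading <- list(reading = 0.858 / 5.4e-2, mu = 100)
  corr <- list(n_dw = 5.4e-2, k_tp = 1, k_pol = 1, k_s = 1, k_bq = 1)
  out <- output_from_g90(reading, corr, tpr_10_5 = 0.858)
  expect_equal(out$d10_gy_per_100mu, 0.858, tolerance = 1e-12)
  expect_equal(out$d5_gy_per_100mu, 1.000, tolerance = 1e-12)
  # tpr_10_5 = 1 leaves the dose unchanged
  expect_equal(output_from_g90(reading, corr, 1)$d5_gy_per_100mu,
               out$d10_gy_per_100mu)
  # linearity in n_dw and the raw reading
  out2 <- output_from_g90(reading, modifyList(corr, list(n_dw = 2 * 5.4e-2)),
                          0.858)
  expect_equal(out2$d5_gy_per_100mu, 2 * out$d5_gy_per_100mu)
  reading2 <- list(reading = 2 * 0.858 / 5.4e-2, mu = 100)
  expect_equal(output_from_g90(reading2, corr, 0.858)$d5_gy_per_100mu,
               2 * out$d5_gy_per_100mu)
})

test_that("missing corrections are reported by name", {
  err <- tryCatch(output_from_g90(list(reading = 1, mu = 100),
                                  list(n_dw = 1), 0.858),
                  error = function(e) conditionMessage(e))
  expect_match(err, "k_tp")
  expect_match(err, "k_pol")
  expect_match(err, "k_s")
  expect_match(err, "k_bq")
  expect_error(output_from_g90(list(reading = 1, mu = 100),
                               list(n_dw = 1, k_tp = 1, k_pol = 1, k_s = 1,
                                    k_bq = 1), 1.5),
               "tpr_10_5")
})

test_that("the expected vertical-beam output applies the cryostat difference", {
  expect_equal(expected_g0_output(1.000, 0.5), 1.005)
  expect_equal(expected_g0_output(1.000, 0.0), 1.000)
  expect_equal(expected_g0_output(2.000, 0.5), 2.010)
  expect_error(expected_g0_output(-1), "positive")
})

test_that("attenuation percentages follow the reading ratio", {
  expect_equal(attenuation_pct(1, 1), 0.0)
  expect_equal(attenuation_pct(0.994, 1.000), 0.6)
  expect_equal(attenuation_pct(1.001, 1.000), -0.1)  # noise can exceed effect
  expect_error(attenuation_pct(1, 0), "non-zero")
})

test_that("mean attenuation excludes beam-miss angles by default", {
  tab <- coil_attenuation_table()
  measured <- mean_attenuation(data.frame(attenuation_pct = tab$measured_pct))
  expect_equal(measured$mean_pct, 0.6)
  expect_equal(measured$n, 8)  # the 0.0 rows at 75 and 285 degrees drop out
  calculated <- mean_attenuation(data.frame(attenuation_pct = tab$calculated_pct))
  expect_equal(calculated$mean_pct, 0.8)
  # keeping the zero rows dilutes the measured mean to 0.5
  all_rows <- mean_attenuation(data.frame(attenuation_pct = tab$measured_pct),
                               exclude_zero = FALSE)
  expect_equal(all_rows$mean_pct, 0.5)
  same <- mean_attenuation(rep(0.7, 5))
  expect_equal(same$mean_pct, 0.7)
  expect_equal(same$sd_pct, 0)
  expect_error(mean_attenuation(c(0, 0)), "no attenuation records")
})

test_that("correction factors are unity at reference conditions", {
  expect_equal(k_tp(20, 101.325), 1)
  expect_equal(k_pol(3, -3), 1)
  expect_equal(k_s(2, 2), 1, tolerance = 1e-9)
  expect_equal(combine_kb(1, 1), 1)
})

test_that("tpr and attenuation are invariant to common reading rescales", {
  expect_equal(tpr(c(3.5, 3.6), c(5, 5.1))$tpr,
               tpr(c(7.0, 7.2), c(10, 10.2))$tpr)
  expect_equal(attenuation_pct(0.994 * 7, 1.000 * 7),
               attenuation_pct(0.994, 1.000))
})
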