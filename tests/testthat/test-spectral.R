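test_that("a pure tone yields a single dominant peak at its frequency", {
  tt <- seq(0, 16, by = 0.01)[-1]
  x <- sin(2 * pi * 20 * tt)
  p <- psd_estimate(x, fs = 100)
  expect_equal(peak_frequency(p), 20)
  # the 20 Hz bin towers over everything two bins away
  away <- abs(p$freq - 20) > 2
  expect_gt(p$power[p$freq == 20], 50 * max(p$power[away]))
})

test_that("the PSD integral satisfies Parseval for a tone", {
  tt <- seq(0, 16, by = 0.01)[-1]
  x <- sin(2 * pi * 20 * tt)  # power amplitude^2 / 2 = 0.5
  p <- psd_estimate(x, fs = 100)
  df <- p$freq[2] - p$freq[1]
  expect_equal(sum(p$power) * df, 0.5, tolerance = 0.01)
})

test_that("peak_frequency honours the search band and rejects empty ones", {
  tt <- seq(0, 8, by = 0.01)[-1]
  x <- sin(2 * pi * 10 * tt) + 0.5 * sin(2 * pi * 30 * tt)
  p <- psd_estimate(x, fs = 100)
  expect_equal(peak_frequency(p), 10)
  expect_equal(peak_frequency(p, band = c(25, 35)), 30)
  expect_error(peak_frequency(p, band = c(60, 70)), "band")
  expect_error(psd_estimate(numeric(50), fs = 100), "shorter")
})

test_that("band power tracks amplitude squared", {
  tt <- seq(0, 16, by = 0.01)[-1]
  amp <- ifelse(tt <= 8, 1, 2)  # amplitude doubles in the second half
  x <- amp * sin(2 * pi * 17 * tt)
  bp <- band_power_timecourse(x, fs = 100, band = c(14, 19))
  first <- bp$time < 7.5
  second <- bp$time > 9.5
  expect_equal(mean(bp$power[second]) / mean(bp$power[first]), 4,
               tolerance = 0.02)
  # constant signal: no beta-band power at all
  bpc <- band_power_timecourse(rep(3, 1600), fs = 100, band = c(14, 19))
  expect_lt(max(bpc$power), 1e-20)
  expect_error(band_power_timecourse(x, fs = 100, band = c(40, 60)), "Nyquist")
})

test_that("band power over stationary noise is flat and additive over bands", {
  set.seed(1)
  x <- rnorm(3200)
  full <- band_power_timecourse(x, fs = 100, band = c(1, 49))
  lo <- band_power_timecourse(x, fs = 100, band = c(1, 24))
  hi <- band_power_timecourse(x, fs = 100, band = c(25, 49))
  expect_equal(lo$power + hi$power, full$power, tolerance = 1e-12)
  # flat in time within sampling error
  expect_lt(sd(full$power) / mean(full$power), 0.5)
  # total sliding power close to the series variance
  expect_equal(mean(full$power), var(x), tolerance = 0.05)
})

test_that("ERD/ERS obeys the defining identities", {
  mk <- function(power) {
    structure(list(time = seq(0.5, 15.5, by = 0.1), power = power,
                   band = c(14, 19), fs = 100, window_s = 1, hop_s = 0.1,
                   taper = "hamming"),
              class = "band_power")
  }
  n <- length(seq(0.5, 15.5, by = 0.1))
  # P(t) = P_B -> 0 %
  expect_equal(erd_ers(mk(rep(2, n)))$erd_ers, rep(0, n))
  # quartered power -> -75 %, tripled -> +200 %
  p <- rep(2, n); p[100:n] <- 0.5
  expect_equal(erd_ers(mk(p))$erd_ers[100], -75)
  p <- rep(2, n); p[100:n] <- 6
  expect_equal(erd_ers(mk(p))$erd_ers[100], 200)
  # zero baseline power is an error
  expect_error(erd_ers(mk(rep(0, n))), "zero")
  # baseline must contain a full window
  expect_error(erd_ers(mk(rep(1, n)), baseline = c(0, 0.5)), "baseline")
})

test_that("within-baseline ERD/ERS averages to zero by construction", {
  r <- simulate_columns(seed = 5, modulating = modulating_spec(),
                        coupling = coupling_spec(K = 4))
  bp <- band_power_timecourse(r$v_out[, "left"], fs = 100, band = beta_band("LB"))
  e <- erd_ers(bp, baseline = c(0, 4))
  base <- (e$time - 0.5) >= 0 & (e$time + 0.5) <= 4
  expect_equal(mean(e$erd_ers[base]), 0, tolerance = 1e-9)
})

test_that("working points are window means of the rates", {
  expect_equal(working_point(rep(4, 100)), 4)
  expect_equal(working_point(numeric(50)), 0)
  r <- simulate_columns(n_columns = 1, sim = short_sim(), seed = 2)
  wp <- working_point(r)
  expect_equal(dim(wp), c(4L, 1L))
  expect_equal(wp["zp", 1], mean(r$zp), tolerance = 1e-12)
  wp2 <- working_point(r, window = c(1, 2))
  sel <- r$time >= 1 & r$time <= 2
  expect_equal(wp2["ze", 1], mean(r$ze[sel, 1]), tolerance = 1e-12)
  expect_error(working_point(r, window = c(50, 60)), "empty")
})
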