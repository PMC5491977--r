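test_that("sigmoid rate matches its analytic values and bounds", {
  # midpoint and saturation limits
  expect_equal(sigmoid_rate(6), 2.5)
  expect_equal(sigmoid_rate(1e6), 5)
  expect_equal(sigmoid_rate(-1e6), 0)
  # direct scalar evaluation of 2 e0 / (1 + exp(r (s0 - v))) at v = 0
  expect_equal(sigmoid_rate(0), 0.167846116407, tolerance = 1e-10)

  # strictly increasing and strictly inside (0, 2 e0) on a wide grid
  v <- seq(-50, 50, by = 0.5)
  z <- sigmoid_rate(v)
  expect_true(all(diff(z) > 0))
  expect_true(all(z > 0 & z < 5))

  # overflow-safe far beyond double saturation of the exponential
  ext <- sigmoid_rate(c(-1e308, 1e308))
  expect_false(any(is.nan(ext)))
  expect_true(all(ext >= 0 & ext <= 5))
  expect_error(sigmoid_rate(0, e0 = -1), "positive")
})

test_that("membrane potentials are assembled exactly as written", {
  conn <- column_params("LB")$conn
  expect_equal(membrane_potentials(column_state(), conn),
               c(vp = 0, ve = 0, vs = 0, vf = 0))

  s <- column_state(); s["yp"] <- 1
  pot <- membrane_potentials(s, conn)
  expect_equal(pot[["ve"]], 135)
  expect_equal(pot[["vs"]], 33.75)
  expect_equal(pot[["vf"]], 40.5)

  s <- column_state(); s[c("ye", "ys", "yf")] <- 1
  expect_equal(membrane_potentials(s, conn)[["vp"]],
               0.8 * 135 - 0.25 * 135 - 0.8 * 135)  # -33.75

  s["ye"] <- Inf
  expect_error(membrane_potentials(s, conn), "blow-up|non-finite")
})

test_that("population rates apply the shared sigmoid element-wise", {
  p <- column_params("MB")
  pot <- c(vp = 6, ve = 6, vs = 6, vf = 6)
  expect_equal(population_rates(pot, p$sigmoid),
               c(zp = 2.5, ze = 2.5, zs = 2.5, zf = 2.5))
  pot["vp"] <- -500
  expect_lt(population_rates(pot, p$sigmoid)[["zp"]], 1e-10)
  expect_equal(population_rates(c(vp = 0, ve = 0, vs = 0, vf = 0),
                                p$sigmoid)[["zp"]],
               0.167846116407, tolerance = 1e-10)
})

test_that("an isolated kernel has steady state G z / omega", {
  p <- column_params("LB")
  Ge <- p$kernels[["Ge"]]; we <- p$kernels[["omega_e"]]
  z <- 3.7
  s <- column_state()
  s["yl"] <- Ge * z / we  # auxiliary pathway driven only by u_f
  d <- column_derivatives(s, u_p = 0, u_f = z, params = p)
  expect_equal(d[["yl"]], 0)
  expect_equal(d[["xl"]], 0, tolerance = 1e-12)
})

test_that("kernel impulse response matches G w t exp(-w t)", {
  # RK4 on the derivative field, impulse fed through the auxiliary pathway
  p <- column_params("LB")
  Ge <- p$kernels[["Ge"]]; we <- p$kernels[["omega_e"]]
  dt <- 1e-4
  n <- round(0.25 / dt)
  s <- column_state()
  s["xl"] <- Ge * we  # equivalent initial condition of a unit impulse
  yl <- numeric(n)
  for (k in seq_len(n)) {
    f <- function(st) column_derivatives(st, 0, 0, p)
    k1 <- f(s); k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2); k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    yl[k] <- s[["yl"]]
  }
  tt <- seq_len(n) * dt
  href <- kernel_impulse_response(tt, Ge, we)
  big <- href > 0.01 * max(href)
  expect_lt(max(abs(yl[big] - href[big]) / href[big]), 1e-3)
  # peak position and value: t = 1/w, h = G w / e
  expect_equal(tt[which.max(yl)], 1 / we, tolerance = 2 * dt / (1 / we))
  expect_equal(max(yl), Ge * exp(-1), tolerance = 1e-3)  # h(1/w) = G/e
})

test_that("band presets carry the tabulated kernel constants", {
  hb <- column_params("HB")
  expect_equal(unname(hb$kernels),
               c(4.3, 90, 4.6, 36, 29, 380))
  expect_equal(unname(column_params("MB")$kernels),
               c(3.9, 75, 4.3, 33, 25, 330))
  # connectivity constants are the fixed multiples of C = 135 for all bands
  expect_equal(unname(hb$conn), 135 * c(1, 0.8, 0.25, 0.25, 0.3, 0.1, 0.8))
  expect_error(column_params("LB", nonsense = 1), "unknown")
  # overrides change only the named entry
  expect_equal(column_params("LB", Gf = 30)$kernels[["Gf"]], 30)
})
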