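test_that("coupled input follows u = n + K zp(t-T)", {
  expect_equal(coupled_input(3, 0.7 * 10, 4), 31)
  expect_equal(coupled_input(c(40, 41), 0, c(4, 5)), c(40, 41))  # K = 0 limit
  expect_error(coupled_input(3, -1, 4), "non-negative")
})

test_that("coupling and simulation specs validate invariants", {
  cp <- coupling_spec(K = 10)
  expect_equal(cp$Kp, 3); expect_equal(cp$Kf, 7)
  expect_error(coupling_spec(K = 1, split_p = 0.5, split_f = 0.6), "equal 1")
  expect_error(coupling_spec(K = -1), "non-negative")
  expect_error(simulation_spec(dt = 0.01), "dt")
  expect_error(simulation_spec(dt = 3e-4), "divide")  # 1/dt not multiple of 100
  expect_error(simulate_columns(n_columns = 1,
                                coupling = coupling_spec(K = 5)),
               "single column")
})

test_that("identical seeds give bit-identical trials", {
  r1 <- simulate_columns(sim = short_sim(), seed = 11)
  r2 <- simulate_columns(sim = short_sim(), seed = 11)
  expect_identical(r1$v_out, r2$v_out)
  expect_identical(r1$zp, r2$zp)
  expect_identical(r1$final_state, r2$final_state)
})

test_that("the model is left/right symmetric under seed swap", {
  ss <- derive_stream_seeds(21)
  swapped <- ss[, c(2, 1)]
  colnames(swapped) <- colnames(ss)
  r1 <- simulate_columns(coupling = coupling_spec(K = 20), sim = short_sim(),
                         stream_seeds = ss)
  r2 <- simulate_columns(coupling = coupling_spec(K = 20), sim = short_sim(),
                         stream_seeds = swapped)
  expect_identical(r1$v_out[, "left"], r2$v_out[, "right"])
  expect_identical(r1$zp[, "right"], r2$zp[, "left"])
})

test_that("stored v_out is exactly reproducible from the stored potentials", {
  r <- simulate_columns(coupling = coupling_spec(K = 15), sim = short_sim(),
                        seed = 4)
  conn <- column_params("LB")$conn
  for (cc in 1:2) {
    vp <- conn[["Cpe"]] * r$ye[, cc] - conn[["Cps"]] * r$ys[, cc] -
      conn[["Cpf"]] * r$yf[, cc]
    expect_identical(vp, unname(r$v_out[, cc]))
  }
})

test_that("the delay buffer reproduces u_i = n_i + K_i zp(t - T) exactly", {
  # noise-free, delay chosen as an exact multiple of the output interval
  cp <- coupling_spec(K = 10, delay_s = 0.02)
  r <- simulate_columns(coupling = cp, noise = quiet_noise(),
                        sim = simulation_spec(duration_s = 1, warmup_s = 0),
                        seed = 1)
  lag <- 2  # 0.02 s at 100 Hz
  i <- (lag + 1):nrow(r$u_f)
  expect_equal(unname(r$u_f[i, "right"]), 3 + cp$Kf * unname(r$zp[i - lag, "left"]),
               tolerance = 1e-12)
  expect_equal(unname(r$u_p[i, "left"]), 40 + cp$Kp * unname(r$zp[i - lag, "right"]),
               tolerance = 1e-12)
  # before one delay has elapsed the zero history gives u = n
  expect_equal(unname(r$u_f[1, "right"]), 3, tolerance = 1e-12)
})

test_that("rates stay strictly inside (0, 2 e0)", {
  r <- simulate_columns(coupling = coupling_spec(K = 70), seed = 2,
                        sim = short_sim(4, 1))
  for (m in list(r$zp, r$ze, r$zs, r$zf)) {
    expect_true(all(m >= 0 & m <= 5))
  }
})

test_that("the noise-free system settles onto the algebraic fixed point", {
  fp <- fixed_point(column_params("LB"), n_columns = 1)
  expect_length(fp, 1)
  r <- simulate_columns(column_params("LB"), n_columns = 1,
                        noise = quiet_noise(),
                        sim = simulation_spec(duration_s = 2, warmup_s = 4),
                        seed = 1)
  tail_mean <- colMeans(r$zp)
  expect_equal(unname(tail_mean), fp[[1]][[1]]$rates[["zp"]], tolerance = 1e-3)
  expect_equal(mean(r$ze), fp[[1]][[1]]$rates[["ze"]], tolerance = 1e-3)
  expect_equal(mean(r$zf), fp[[1]][[1]]$rates[["zf"]], tolerance = 1e-3)
})

test_that("starting at the fixed point, the noise-free system stays there", {
  fp <- fixed_point(column_params("MB"), n_columns = 1)
  st <- matrix(fp[[1]][[1]]$state, ncol = 1)
  r <- simulate_columns(column_params("MB"), n_columns = 1,
                        noise = quiet_noise(), init_state = st,
                        sim = simulation_spec(duration_s = 2, warmup_s = 0),
                        seed = 1)
  expect_lt(max(abs(r$zp - fp[[1]][[1]]$rates[["zp"]])), 1e-4)
})

test_that("halving dt leaves the noise-free mean zp unchanged to 1e-3", {
  m <- vapply(c(1e-4, 5e-5), function(dt) {
    r <- simulate_columns(column_params("LB"), n_columns = 1,
                          noise = quiet_noise(),
                          sim = simulation_spec(duration_s = 4, dt = dt,
                                                warmup_s = 2),
                          seed = 1)
    mean(r$zp)
  }, 0)
  expect_lt(abs(m[1] - m[2]), 1e-3)
})

test_that("two coupled identical columns share a symmetric equilibrium", {
  fp <- fixed_point(column_params("LB"), coupling = coupling_spec(K = 4))
  sym <- vapply(fp, function(eq)
    abs(eq[[1]]$rates[["zp"]] - eq[[2]]$rates[["zp"]]) < 1e-6, TRUE)
  expect_true(any(sym))
  # at small K the equilibrium is unique and symmetric
  expect_length(fp, 1)
})

test_that("uncoupled fixed point sits at the documented working points", {
  fp <- fixed_point(column_params("LB"), n_columns = 1)[[1]][[1]]
  expect_equal(fp$rates[["zp"]], 4.33, tolerance = 0.05)
  expect_gt(fp$rates[["ze"]], 4.99)
  expect_true(fp$rates[["zf"]] > 0.3 && fp$rates[["zf"]] < 0.9)
})

test_that("numerical blow-up is reported as an error", {
  init <- matrix(1e308, 10, 1)
  expect_error(
    simulate_columns(n_columns = 1, init_state = init, sim = short_sim(),
                     seed = 1),
    "blew up"
  )
})
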