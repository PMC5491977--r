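test_that("region boundaries are recovered exactly on a constructed curve", {
  # concave then convex decline with matched curvature magnitudes meeting at
  # K* = 20, then winner/loser separation from K = 45 onward
  K <- 0:60
  a <- 0.002
  m <- ifelse(K <= 20,
              4.3 - a * K^2,
              4.3 - a * 400 - 2 * a * 20 * (K - 20) + a * (K - 20)^2)
  w <- l <- m
  w[K >= 45] <- 4.3
  l[K >= 45] <- 0.1
  sweep <- list(K = K, zp_winner = w, zp_loser = l, band = "LB")
  rb <- classify_regions(sweep)
  expect_equal(rb$k_23, 45)
  expect_equal(rb$k_12, 20)
  expect_false(rb$open_12)
  expect_false(rb$open_23)
})

test_that("a sweep without collapse reports an open third region", {
  K <- seq(0, 30, 2)
  sweep <- list(K = K, zp_winner = 4.3 - 0.02 * K, zp_loser = 4.3 - 0.021 * K)
  rb <- classify_regions(sweep)
  expect_true(rb$open_23)
  expect_equal(rb$k_23, 30)
})

test_that("k_sweep sorts winners and losers and is reproducible", {
  sw1 <- k_sweep("LB", K_grid = c(0, 30), n_trials = 2, sim = short_sim(4, 1),
                 seed = 3)
  sw2 <- k_sweep("LB", K_grid = c(30, 0), n_trials = 2, sim = short_sim(4, 1),
                 seed = 3)
  expect_identical(sw1$zp_winner, sw2$zp_winner)  # grid is sorted internally
  expect_true(all(sw1$zp_winner >= sw1$zp_loser))
  expect_true(all(diff(sw1$K) > 0))
  # uncoupled limit: both columns near the single-column working point
  expect_equal(sw1$zp_winner[1], 4.3, tolerance = 0.15)
  expect_equal(sw1$zp_loser[1], 4.3, tolerance = 0.15)
})

test_that("mean zp declines with K before the winner-take-all region", {
  sw <- k_sweep("LB", K_grid = seq(0, 16, 4), n_trials = 2,
                sim = short_sim(8, 2), seed = 9)
  m <- (sw$zp_winner + sw$zp_loser) / 2
  expect_true(all(diff(m) < 0.05))  # non-increasing within noise tolerance
  expect_lt(m[length(m)], m[1] - 0.5)
})

test_that("the trial protocol returns averaged curves for both columns", {
  tr <- run_trial_protocol("HB", K = 4, n_trials = 2, seed = 6)
  expect_s3_class(tr, "erd_ers_trial")
  expect_equal(length(tr$time), length(tr$left))
  expect_equal(length(tr$left), length(tr$right))
  expect_true(all(is.finite(tr$left)) && all(is.finite(tr$right)))
  # the task saturates the target column: strong ERD during the plateau
  plat <- tr$time >= 6.5 & tr$time <= 9.5
  expect_lt(mean(tr$left[plat]), -30)
  # after the task both sides return towards baseline
  post <- tr$time >= 13.5
  expect_lt(abs(mean(tr$left[post])), 25)
})

test_that("the ERD/ERS map stacks trial averages over K", {
  mp <- erd_ers_map("LB", K_grid = c(0, 6), n_trials = 2, seed = 8)
  expect_equal(dim(mp$left), c(2L, length(mp$time)))
  expect_equal(dim(mp$right), dim(mp$left))
  base <- (mp$time - 0.5) >= 0 & (mp$time + 0.5) <= 4
  # baseline region of the map is ~0 by construction of the reference
  expect_lt(max(abs(rowMeans(mp$left[, base]))), 1e-9)
  expect_lt(max(abs(rowMeans(mp$right[, base]))), 1e-9)
})

test_that("per-trial sweeps are classified by collapse probability", {
  K <- seq(0, 10, 2)
  counts <- c(0, 0, 1, 2, 5, 5)  # collapsed trials out of 5 per K
  runs <- lapply(counts, function(k) {
    cbind(loser = c(rep(0.1, k), rep(3.5, 5 - k)),
          winner = rep(4.2, 5))
  })
  sweep <- list(K = K, zp_winner = rep(4, 6), zp_loser = rep(3, 6),
                zp_runs = runs, band = "HB")
  rb <- classify_regions(sweep)
  expect_equal(rb$k_23, 6)  # first K with collapse fraction >= 0.4
  # a non-monotone fluctuation below threshold does not trigger the boundary
  counts2 <- c(0, 1, 0, 0, 5, 5)
  runs2 <- lapply(counts2, function(k)
    cbind(loser = c(rep(0.1, k), rep(3.5, 5 - k)), winner = rep(4.2, 5)))
  sweep2 <- sweep
  sweep2$zp_runs <- runs2
  rb2 <- classify_regions(sweep2)
  expect_equal(rb2$k_23, 8)
})
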