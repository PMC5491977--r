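## Experiment suite over the transcallosal gain K: working-point sweeps,
## working-region classification, ERD/ERS trial protocols and maps.

## deterministic per-trial seeds from one master seed
.derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Sweep the transcallosal gain K
#'
#' For each value of `K` runs `n_trials` independently seeded two-column
#' simulations with driving noise only (no task input) and records the
#' time-mean pyramidal spike density of each column. Because which side
#' "wins" at strong coupling depends on the noise realisation, columns are
#' sorted per run by mean `zp` into a winner (larger) and loser before
#' averaging across trials.
#'
#' @param band band label selecting the column preset.
#' @param K_grid coupling gains to test (sorted ascending internally).
#' @param n_trials seeded trials per K.
#' @param noise,sim specs passed to [simulate_columns()].
#' @param seed master seed; per-(K, trial) seeds are derived from it.
#' @param keep_psd if `TRUE`, also store the trial-averaged output PSDs of
#'   the winner and loser columns per K.
#' @param coupling_template a [coupling_spec()] providing split and delay;
#'   its `K` is overridden by the grid.
#' @return object of class `k_sweep`: list with `K`, `zp_winner`,
#'   `zp_loser` (trial-averaged, per K), `zp_runs` (list of
#'   `n_trials` x 2 sorted matrices), optional `psd_winner`/`psd_loser`
#'   lists, and the metadata.
#' @examples
#' \donttest{
#' sw <- k_sweep("HB", K_grid = seq(0, 40, 4), n_trials = 2, seed = 1)
#' classify_regions(sw)
#' }
#' @export
k_sweep <- function(band = "LB", K_grid = seq(0, 100, by = 2), n_trials = 5,
                    noise = noise_spec(), sim = simulation_spec(), seed = 1L,
                    keep_psd = FALSE,
                    coupling_template = coupling_spec()) {
  K_grid <- sort(unique(K_grid))
  cols <- column_params(band)
  seeds <- matrix(.derive_seeds(seed, length(K_grid) * n_trials),
                  nrow = length(K_grid))
  zp_w <- zp_l <- numeric(length(K_grid))
  zp_runs <- vector("list", length(K_grid))
  psd_w <- psd_l <- if (keep_psd) vector("list", length(K_grid)) else NULL
  for (i in seq_along(K_grid)) {
    cp <- coupling_spec(K = K_grid[i], split_p = coupling_template$split_p,
                        split_f = coupling_template$split_f,
                        delay_s = coupling_template$delay_s)
    runs <- matrix(NA_real_, n_trials, 2,
                   dimnames = list(NULL, c("loser", "winner")))
    pw <- pl <- list()
    for (j in seq_len(n_trials)) {
      r <- simulate_columns(cols, coupling = cp, noise = noise, sim = sim,
                            seed = seeds[i, j], n_columns = 2)
      m <- colMeans(r$zp)
      ord <- order(m)  # loser first
      runs[j, ] <- m[ord]
      if (keep_psd) {
        pl[[j]] <- psd_estimate(r$v_out[, ord[1]], fs = sim$fs_out)
        pw[[j]] <- psd_estimate(r$v_out[, ord[2]], fs = sim$fs_out)
      }
    }
    zp_runs[[i]] <- runs
    zp_l[i] <- mean(runs[, "loser"])
    zp_w[i] <- mean(runs[, "winner"])
    if (keep_psd) {
      psd_l[[i]] <- .average_psd(pl)
      psd_w[[i]] <- .average_psd(pw)
    }
  }
  structure(list(K = K_grid, zp_winner = zp_w, zp_loser = zp_l,
                 zp_runs = zp_runs, psd_winner = psd_w, psd_loser = psd_l,
                 band = band, n_trials = n_trials, seed = seed),
            class = "k_sweep")
}

#' @export
print.k_sweep <- function(x, ...) {
  cat(sprintf("<k_sweep> band %s, K = %g..%g (%d values), %d trials/K\n",
              x$band, min(x$K), max(x$K), length(x$K), x$n_trials))
  invisible(x)
}

## centred running mean, partial windows at the edges
.running_mean <- function(x, width) {
  half <- floor(width / 2)
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), 0)
}

#' Classify the three working regions of a K sweep
#'
#' The mean-`zp`-versus-K curve falls in three regions: (1) a concave
#' decline while both columns leave the high-saturation region, (2) a convex
#' decline in the linear region, and (3) winner-take-all, where one column
#' collapses to silence. `k_23` is the smallest K at which the sorted means
#' separate (winner - loser above `asym_thresh`) or the loser falls below
#' `collapse_thresh`; `k_12` is the inflection (first concave-to-convex sign
#' change of the smoothed second difference) of the column-averaged curve
#' below `k_23`.
#'
#' @param sweep a [k_sweep()] result, or any list with elements `K`,
#'   `zp_winner`, `zp_loser`.
#' @details Because escape into the winner-take-all state within a finite
#' trial is stochastic, a sweep with per-trial records (`zp_runs` present,
#' as produced by [k_sweep()]) is classified probabilistically: per K, the
#' fraction of trials in the collapsed state (loser below
#' `collapse_thresh`, winner above `winner_thresh`) is estimated, made
#' monotone in K by isotonic regression (the regime can only become more
#' reachable as K grows), and region 3 is declared where this collapse
#' probability reaches `wta_prob`. For plain winner/loser curves without
#' per-trial records the threshold rule on the averaged means is used
#' instead.
#'
#' @param collapse_thresh loser mean `zp` (pps) below which a trial (or the
#'   averaged loser) counts as collapsed.
#' @param asym_thresh winner-loser gap (pps) above which the averaged curves
#'   are declared separated (fallback rule).
#' @param winner_thresh winner mean `zp` (pps) that must be retained for a
#'   trial to count as winner-take-all.
#' @param wta_prob collapse probability at which region 3 is declared.
#' @param smooth_width running-mean width (in K grid points) applied before
#'   the second difference.
#' @return object of class `region_boundaries`: list with `band`, `k_12`,
#'   `k_23` and logical flags `open_12`/`open_23` marking boundaries not
#'   found inside the grid (reported at the grid edge).
#' @export
classify_regions <- function(sweep, collapse_thresh = 0.5, asym_thresh = 2,
                             winner_thresh = 3, wta_prob = 0.4,
                             smooth_width = 5) {
  K <- sweep$K
  w <- sweep$zp_winner
  l <- sweep$zp_loser
  stopifnot(length(K) == length(w), length(K) == length(l))

  if (!is.null(sweep$zp_runs)) {
    frac <- vapply(sweep$zp_runs, function(r)
      mean(r[, "loser"] < collapse_thresh & r[, "winner"] > winner_thresh), 0)
    p <- stats::isoreg(K, frac)$yf
    in3 <- p >= wta_prob - 1e-9
  } else {
    in3 <- (w - l) > asym_thresh | l < collapse_thresh
  }
  open_23 <- !any(in3)
  k_23 <- if (open_23) K[length(K)] else K[which(in3)[1]]

  pre <- K < k_23
  k_12 <- NA_real_; open_12 <- TRUE
  if (sum(pre) >= 5) {
    m <- .running_mean((w[pre] + l[pre]) / 2, smooth_width)
    d2 <- diff(m, differences = 2)          # d2[i] ~ curvature at K[i+1]
    d2 <- .running_mean(d2, smooth_width)
    Kmid <- K[pre][seq_along(d2) + 1]
    for (i in seq_along(d2)[-1]) {
      if (d2[i - 1] < 0 && d2[i] >= 0) {
        k_12 <- Kmid[i]; open_12 <- FALSE; break
      }
    }
    if (open_12) k_12 <- Kmid[length(Kmid)]
  } else if (sum(pre) > 0) {
    k_12 <- K[pre][sum(pre)]
  }
  structure(list(band = sweep$band, k_12 = k_12, k_23 = k_23,
                 open_12 = open_12, open_23 = open_23),
            class = "region_boundaries")
}

#' @export
print.region_boundaries <- function(x, ...) {
  cat(sprintf("<region_boundaries>%s k_12 = %g%s, k_23 = %g%s\n",
              if (is.null(x$band)) "" else paste0(" band ", x$band),
              x$k_12, if (x$open_12) " (open: grid edge)" else "",
              x$k_23, if (x$open_23) " (open: grid edge)" else ""))
  invisible(x)
}

#' Run the motor-imagery trial protocol and average ERD/ERS
#'
#' Simulates `n_trials` independently seeded 16 s trials with the
#' smoothed-trapezoid task input applied to the left (contralateral) column,
#' computes the sliding band power of each column's output in the analysis
#' band, converts it to ERD/ERS% against the baseline interval, and averages
#' the curves across trials.
#'
#' @param band band label; also selects the default analysis band.
#' @param K transcallosal gain.
#' @param n_trials number of trials averaged.
#' @param erd_band analysis band `c(f_lo, f_hi)` (Hz); defaults to the beta
#'   sub-band of `band`.
#' @param baseline baseline interval (s) for the ERD/ERS reference power.
#' @param modulating a [modulating_spec()].
#' @param noise,sim,coupling_template,seed as in [k_sweep()].
#' @return object of class `erd_ers_trial`: list with `time`, `left`,
#'   `right` (trial-averaged ERD/ERS%, percent), per-trial baseline powers,
#'   and the metadata.
#' @examples
#' \donttest{
#' tr <- run_trial_protocol("LB", K = 10, n_trials = 3, seed = 1)
#' plot(tr)
#' }
#' @export
run_trial_protocol <- function(band = "LB", K = kh_kl(band)[["K_H"]],
                               n_trials = 20,
                               erd_band = NULL,
                               baseline = c(0, 4),
                               modulating = modulating_spec(),
                               noise = noise_spec(),
                               sim = simulation_spec(),
                               coupling_template = coupling_spec(),
                               seed = 1L) {
  if (is.null(erd_band)) erd_band <- beta_band(band)
  cols <- column_params(band)
  cp <- coupling_spec(K = K, split_p = coupling_template$split_p,
                      split_f = coupling_template$split_f,
                      delay_s = coupling_template$delay_s)
  seeds <- .derive_seeds(seed, n_trials)
  left <- right <- NULL
  pb_l <- pb_r <- numeric(n_trials)
  for (j in seq_len(n_trials)) {
    r <- simulate_columns(cols, coupling = cp, noise = noise,
                          modulating = modulating, sim = sim,
                          seed = seeds[j], n_columns = 2)
    el <- erd_ers(band_power_timecourse(r$v_out[, "left"], fs = sim$fs_out,
                                        band = erd_band), baseline = baseline)
    er <- erd_ers(band_power_timecourse(r$v_out[, "right"], fs = sim$fs_out,
                                        band = erd_band), baseline = baseline)
    left <- if (is.null(left)) el$erd_ers / n_trials else left + el$erd_ers / n_trials
    right <- if (is.null(right)) er$erd_ers / n_trials else right + er$erd_ers / n_trials
    pb_l[j] <- el$baseline_power; pb_r[j] <- er$baseline_power
  }
  structure(list(time = el$time, left = left, right = right,
                 baseline_power = cbind(left = pb_l, right = pb_r),
                 band = band, erd_band = erd_band, K = K,
                 n_trials = n_trials, baseline = baseline, seed = seed),
            class = "erd_ers_trial")
}

#' @export
print.erd_ers_trial <- function(x, ...) {
  plat <- x$time >= 6.5 & x$time <= 9.5
  cat(sprintf("<erd_ers_trial> band %s, K = %g, %d trials (band %g-%g Hz)\n",
              x$band, x$K, x$n_trials, x$erd_band[1], x$erd_band[2]))
  cat(sprintf("  plateau mean: left %.1f%%, right %.1f%%\n",
              mean(x$left[plat]), mean(x$right[plat])))
  invisible(x)
}

#' @export
plot.erd_ers_trial <- function(x, ...) {
  graphics::plot(x$time, x$left, type = "l", col = "darkgreen",
                 ylim = range(c(x$left, x$right)),
                 xlab = "time (s)", ylab = "ERD/ERS (%)", ...)
  graphics::lines(x$time, x$right, col = "steelblue")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", c("left (target)", "right"), lty = 1,
                   col = c("darkgreen", "steelblue"), bty = "n")
  invisible(x)
}

#' ERD/ERS map over coupling strength and trial time
#'
#' Repeats [run_trial_protocol()] over a grid of K values (normally within
#' working regions 1-2, i.e. below `k_23`) and stacks the trial-averaged
#' ERD/ERS% curves into K x time matrices for both columns.
#'
#' @inheritParams run_trial_protocol
#' @param K_grid coupling gains to map.
#' @return object of class `erd_ers_map`: list with `K`, `time`, matrices
#'   `left` and `right` (rows = K), and metadata.
#' @export
erd_ers_map <- function(band = "LB", K_grid = seq(0, 20, by = 2),
                        n_trials = 5, erd_band = NULL, baseline = c(0, 4),
                        modulating = modulating_spec(), noise = noise_spec(),
                        sim = simulation_spec(),
                        coupling_template = coupling_spec(), seed = 1L) {
  K_grid <- sort(unique(K_grid))
  seeds <- .derive_seeds(seed, length(K_grid))
  rows_l <- rows_r <- vector("list", length(K_grid))
  tt <- NULL
  for (i in seq_along(K_grid)) {
    tr <- run_trial_protocol(band, K = K_grid[i], n_trials = n_trials,
                             erd_band = erd_band, baseline = baseline,
                             modulating = modulating, noise = noise, sim = sim,
                             coupling_template = coupling_template,
                             seed = seeds[i])
    rows_l[[i]] <- tr$left; rows_r[[i]] <- tr$right; tt <- tr$time
  }
  structure(list(K = K_grid, time = tt,
                 left = do.call(rbind, rows_l), right = do.call(rbind, rows_r),
                 band = band, n_trials = n_trials, seed = seed),
            class = "erd_ers_map")
}

#' @export
print.erd_ers_map <- function(x, ...) {
  cat(sprintf("<erd_ers_map> band %s, %d K values x %d time points, %d trials/K\n",
              x$band, length(x$K), length(x$time), x$n_trials))
  invisible(x)
}
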