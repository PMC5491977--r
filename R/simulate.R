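## Forward integration of one or two coupled columns.

#' Transcallosal coupling specification
#'
#' The delayed excitatory projection from the pyramidal cells of one column
#' to the other column. A global gain `K` is split between the pyramidal
#' targets (`Kp = split_p K`, default 30%) and the fast inhibitory targets
#' (`Kf = split_f K`, default 70%), with conduction delay `T` (13 ms, the
#' typical transcallosal conduction time between motor cortices).
#'
#' @param K global transcallosal gain (dimensionless, 0-100).
#' @param split_p fraction of the gain reaching pyramidal targets.
#' @param split_f fraction reaching fast inhibitory targets; must satisfy
#'   `split_p + split_f = 1`.
#' @param delay_s conduction delay (s).
#' @return an object of class `coupling_spec` with derived `Kp` and `Kf`.
#' @examples
#' coupling_spec(K = 10)
#' @export
coupling_spec <- function(K = 0, split_p = 0.3, split_f = 0.7, delay_s = 0.013) {
  if (K < 0) stop("K must be non-negative")
  if (abs(split_p + split_f - 1) > 1e-9)
    stop("split_p + split_f must equal 1 (got ", split_p + split_f, ")")
  if (split_p < 0 || split_f < 0) stop("splits must be non-negative")
  if (delay_s <= 0) stop("delay must be positive")
  structure(list(K = K, split_p = split_p, split_f = split_f,
                 delay_s = delay_s, Kp = split_p * K, Kf = split_f * K),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("<coupling_spec> K = %g (Kp = %g, Kf = %g), delay = %g ms\n",
              x$K, x$Kp, x$Kf, 1000 * x$delay_s))
  invisible(x)
}

#' Simulation grid specification
#'
#' @param duration_s simulated trial length (s) retained in the output.
#' @param dt integration step (s); must be at most 1 ms, and `1/dt` must be
#'   an integer multiple of `fs_out`.
#' @param fs_out output sampling rate (Hz); outputs are decimated to this
#'   rate by direct subsampling.
#' @param warmup_s transient discarded before the trial starts (s); the
#'   integration starts from the given initial state and the delay history
#'   is pre-filled with zeros.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(duration_s = 16, dt = 1e-4, fs_out = 100,
                            warmup_s = 2) {
  if (dt <= 0 || dt > 1e-3) stop("dt must lie in (0, 1e-3] s")
  if (duration_s <= 0) stop("duration must be positive")
  if (warmup_s < 0) stop("warmup must be non-negative")
  decim <- 1 / (dt * fs_out)
  if (abs(decim - round(decim)) > 1e-8)
    stop("fs_out must divide 1/dt evenly (1/dt = ", 1 / dt,
         ", fs_out = ", fs_out, ")")
  structure(list(duration_s = duration_s, dt = dt, fs_out = fs_out,
                 warmup_s = warmup_s, decim = as.integer(round(decim))),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> %g s @ dt = %g s, output %g Hz, warmup %g s\n",
              x$duration_s, x$dt, x$fs_out, x$warmup_s))
  invisible(x)
}

#' External input with the delayed transcallosal term
#'
#' `u_i(t) = n_i(t) + K_i zp(t - T)`: the input a population receives is its
#' external drive plus the gain-weighted, delayed pyramidal rate of the
#' other column. Before one delay has elapsed the history value (zero by
#' default) is used.
#'
#' @param n_i external input (pps); vectorised.
#' @param K_i coupling gain reaching this population (`Kp` or `Kf`).
#' @param zp_delayed delayed pyramidal spike density of the source column.
#' @return combined input (pps).
#' @examples
#' coupled_input(3, 0.7 * 10, 4)  # 3 + 28 = 31
#' @export
coupled_input <- function(n_i, K_i, zp_delayed) {
  if (any(K_i < 0)) stop("coupling gain must be non-negative")
  n_i + K_i * zp_delayed
}

#' Derive independent per-stream seeds from one master seed
#'
#' Four noise streams (2 columns x pyramidal/fast targets) are given
#' distinct sub-seeds drawn deterministically from the master seed.
#'
#' @param seed master seed (integer).
#' @param n_columns 1 or 2.
#' @return integer matrix with rows `p`, `f` and one column per simulated
#'   column.
#' @export
derive_stream_seeds <- function(seed, n_columns = 2) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max, 2 * n_columns), nrow = 2,
         dimnames = list(c("p", "f"),
                         c("left", "right")[seq_len(n_columns)]))
}

#' Simulate one or two coupled cortical columns
#'
#' Fixed-step Euler-Maruyama integration of the full stochastic model:
#' 10 state variables per column, independent Gaussian noise streams into
#' the pyramidal and fast inhibitory pathways of each column, an optional
#' smoothed-trapezoid modulating input, and (for two columns) the delayed
#' transcallosal projections held in a circular buffer of pyramidal rates.
#' Outputs are decimated to `sim$fs_out` and the warm-up span is discarded.
#' Runs are bit-reproducible given the same seeds.
#'
#' @param columns a [column_params()] object (replicated over columns) or a
#'   list of one per column.
#' @param coupling a [coupling_spec()]; for a single column `K` must be 0.
#' @param noise a [noise_spec()].
#' @param modulating a [modulating_spec()] or `NULL`; when given, its total
#'   duration must equal the simulated trial duration. The waveform is added
#'   to the pyramidal driving input of the target column (zero during
#'   warm-up).
#' @param sim a [simulation_spec()].
#' @param seed master seed from which the per-stream seeds are derived.
#' @param n_columns 1 (uncoupled single column) or 2.
#' @param stream_seeds optional explicit seed matrix as returned by
#'   [derive_stream_seeds()]; overrides `seed`.
#' @param init_state initial state: a 10 x `n_columns` matrix or a single
#'   10-vector replicated across columns. Defaults to the zero state.
#' @return an object of class `trial_result`: a list with `time` (s, trial
#'   clock starting at 0), matrices `v_out`, `zp`, `ze`, `zs`, `zf`, `u_p`,
#'   `u_f` and the postsynaptic potentials `yp`, `ye`, `ys`, `yf`, `yl`
#'   (rows = samples, columns = `left`/`right`), the specs used, the seed
#'   manifest and the final integrator state.
#' @examples
#' r <- simulate_columns(column_params("LB"), n_columns = 1, seed = 1,
#'                       sim = simulation_spec(duration_s = 2, warmup_s = 0.5))
#' colMeans(r$zp)
#' @export
simulate_columns <- function(columns = column_params("LB"),
                             coupling = coupling_spec(K = 0),
                             noise = noise_spec(),
                             modulating = NULL,
                             sim = simulation_spec(),
                             seed = 1L,
                             n_columns = 2,
                             stream_seeds = NULL,
                             init_state = NULL) {
  stopifnot(inherits(coupling, "coupling_spec"), inherits(noise, "noise_spec"),
            inherits(sim, "simulation_spec"))
  if (!n_columns %in% c(1L, 2L)) stop("n_columns must be 1 or 2")
  if (n_columns == 1L && coupling$K != 0)
    stop("a single column cannot be coupled: set K = 0")
  if (inherits(columns, "column_params")) {
    columns <- rep(list(columns), n_columns)
  } else if (!(is.list(columns) && length(columns) == n_columns &&
               all(vapply(columns, inherits, TRUE, "column_params")))) {
    stop("columns must be a column_params object or a list of ", n_columns)
  }
  par <- vapply(columns, .param_vector, numeric(16))

  n_steps <- as.integer(round((sim$warmup_s + sim$duration_s) / sim$dt))
  warmup_steps <- as.integer(round(sim$warmup_s / sim$dt))
  delay_steps <- max(1L, as.integer(round(coupling$delay_s / sim$dt)))

  master <- if (is.null(stream_seeds)) seed else NA_integer_
  if (is.null(stream_seeds)) stream_seeds <- derive_stream_seeds(seed, n_columns)
  if (!is.matrix(stream_seeds) || nrow(stream_seeds) != 2 ||
      ncol(stream_seeds) != n_columns)
    stop("stream_seeds must be a 2 x n_columns matrix (rows p, f)")

  np <- matrix(0, n_steps, n_columns)
  nf <- matrix(0, n_steps, n_columns)
  for (c in seq_len(n_columns)) {
    np[, c] <- noise_sample(n_steps, noise$mean_p, noise$sd_p, sim$dt,
                            seed = stream_seeds[1, c])
    nf[, c] <- noise_sample(n_steps, noise$mean_f, noise$sd_f, sim$dt,
                            seed = stream_seeds[2, c])
  }

  if (!is.null(modulating)) {
    stopifnot(inherits(modulating, "modulating_spec"))
    if (abs(modulating$total_s - sim$duration_s) > 1e-9)
      stop("modulating input covers ", modulating$total_s,
           " s but the trial lasts ", sim$duration_s, " s")
    tgt <- if (modulating$target == "left") 1L else 2L
    if (tgt > n_columns) stop("modulating target column not simulated")
    tt <- (seq_len(n_steps) - 1) * sim$dt - sim$warmup_s
    wave <- numeric(n_steps)
    inside <- tt >= 0 & tt <= modulating$total_s
    wave[inside] <- modulating_value(tt[inside], modulating)
    np[, tgt] <- np[, tgt] + wave
  }

  if (is.null(init_state)) {
    init <- matrix(0, 10, n_columns)
  } else {
    init <- if (is.matrix(init_state)) init_state else
      matrix(rep(init_state, n_columns), 10, n_columns)
    if (nrow(init) != 10 || ncol(init) != n_columns)
      stop("init_state must be 10 x n_columns")
  }

  out <- integrate_columns_cpp(par, coupling$Kp, coupling$Kf, delay_steps,
                               np, nf, sim$dt, warmup_steps, sim$decim, init)

  cn <- c("left", "right")[seq_len(n_columns)]
  for (nm in c("v_out", "zp", "ze", "zs", "zf", "u_p", "u_f",
               "yp", "ye", "ys", "yf", "yl"))
    colnames(out[[nm]]) <- cn
  n_out <- nrow(out$v_out)
  structure(
    c(list(time = (seq_len(n_out) - 1) / sim$fs_out),
      out[c("v_out", "zp", "ze", "zs", "zf", "u_p", "u_f",
            "yp", "ye", "ys", "yf", "yl")],
      list(final_state = out$final_state,
           columns = columns, coupling = coupling, noise = noise,
           modulating = modulating, sim = sim,
           seeds = list(master = master, streams = stream_seeds))),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  nc <- ncol(x$v_out)
  cat(sprintf("<trial_result> %d column%s, %g s @ %g Hz (%d samples)\n",
              nc, if (nc > 1) "s" else "", x$sim$duration_s, x$sim$fs_out,
              nrow(x$v_out)))
  cat(sprintf("  band %s, K = %g; mean zp: %s pps\n",
              paste(unique(vapply(x$columns, `[[`, "", "band")), collapse = "/"),
              x$coupling$K,
              paste(sprintf("%.2f", colMeans(x$zp)), collapse = ", ")))
  invisible(x)
}
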