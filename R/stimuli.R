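## External inputs: Gaussian driving noise and the smoothed-trapezoid
## modulating input that emulates a motor-imagery task.

#' Driving-noise specification
#'
#' Gaussian white noise stands in for all inputs not represented in the
#' model. It drives the pyramidal pathway (mean 40 pps, excitatory) and the
#' fast inhibitory pathway (mean 3 pps, net inhibitory effect); both columns
#' receive statistically identical but independent streams.
#'
#' `sd` is the white-noise intensity in pps per sqrt(Hz): the integrator
#' draws one value per step with standard deviation `sd / sqrt(dt)`
#' (Euler-Maruyama convention), so the band-limited noise power is
#' independent of the integration step.
#'
#' @param mean_p,sd_p mean and intensity of the pyramidal-pathway input (pps).
#' @param mean_f,sd_f mean and intensity of the fast-inhibitory-pathway input.
#' @return an object of class `noise_spec`.
#' @examples
#' noise_spec()               # defaults: 40/1 pyramidal, 3/1 fast
#' noise_spec(sd_p = 0, sd_f = 0)  # noise-free (mean inputs only)
#' @export
noise_spec <- function(mean_p = 40, sd_p = 1, mean_f = 3, sd_f = 1) {
  if (sd_p < 0 || sd_f < 0) stop("noise sd must be non-negative")
  structure(list(mean_p = mean_p, sd_p = sd_p, mean_f = mean_f, sd_f = sd_f),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> pyramidal N(%g, %g^2), fast N(%g, %g^2) pps (per unit bandwidth)\n",
              x$mean_p, x$sd_p, x$mean_f, x$sd_f))
  invisible(x)
}

#' Sample a Gaussian driving-noise sequence
#'
#' Draws one i.i.d. Gaussian value per integration step. At the default
#' `dt = 1` the draws have standard deviation `sd`; for an integration step
#' `dt < 1` the per-step standard deviation is `sd / sqrt(dt)` so that the
#' white-noise intensity (power per unit bandwidth) stays fixed.
#'
#' @param n_steps number of samples.
#' @param mean mean (pps).
#' @param sd white-noise intensity (pps per sqrt(Hz)).
#' @param dt step duration (s) the samples will be held for.
#' @param seed optional integer seed; when given, the stream is reproducible
#'   and the caller's RNG state is left untouched.
#' @return numeric vector of length `n_steps`.
#' @examples
#' x <- noise_sample(1000, seed = 1)
#' identical(x, noise_sample(1000, seed = 1))
#' @export
noise_sample <- function(n_steps, mean = 40, sd = 1, dt = 1, seed = NULL) {
  if (n_steps <= 0) stop("n_steps must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  mean + (sd / sqrt(dt)) * stats::rnorm(n_steps)
}

#' Modulating-input specification
#'
#' The task input emulating persistent motor imagery: a smoothed trapezoid
#' added to the pyramidal driving input of the target column. With defaults
#' the 16 s trial is 4 s baseline, 2 s raised-cosine rise, 4 s plateau at
#' 100 pps, 2 s raised-cosine fall and 4 s rest.
#'
#' @param baseline_s,rise_s,plateau_s,fall_s,rest_s segment durations (s).
#' @param plateau_amp plateau amplitude (pps).
#' @param target which column receives the input, `"left"` (contralateral to
#'   an imagined right-hand movement) or `"right"`.
#' @return an object of class `modulating_spec`.
#' @export
modulating_spec <- function(baseline_s = 4, rise_s = 2, plateau_s = 4,
                            fall_s = 2, rest_s = 4, plateau_amp = 100,
                            target = c("left", "right")) {
  target <- match.arg(target)
  durs <- c(baseline_s, rise_s, plateau_s, fall_s, rest_s)
  if (any(durs < 0)) stop("segment durations must be non-negative")
  if (plateau_amp < 0) stop("plateau amplitude must be non-negative")
  structure(list(baseline_s = baseline_s, rise_s = rise_s,
                 plateau_s = plateau_s, fall_s = fall_s, rest_s = rest_s,
                 plateau_amp = plateau_amp, target = target,
                 total_s = sum(durs)),
            class = "modulating_spec")
}

#' @export
print.modulating_spec <- function(x, ...) {
  cat(sprintf("<modulating_spec> %g s baseline | %g s rise | %g s plateau @ %g pps | %g s fall | %g s rest -> %s column\n",
              x$baseline_s, x$rise_s, x$plateau_s, x$plateau_amp,
              x$fall_s, x$rest_s, x$target))
  invisible(x)
}

#' Evaluate the modulating input at a trial time
#'
#' The waveform is 0 during baseline and rest, `plateau_amp` during the
#' plateau, and follows raised-cosine (half-Hann) ramps during rise and
#' fall, so it is continuous and continuously differentiable at every
#' segment join.
#'
#' @param t trial time (s), vectorised; must lie within `[0, total]`.
#' @param spec a [modulating_spec()].
#' @return input amplitude(s) in pps.
#' @examples
#' modulating_value(c(2, 5, 7), modulating_spec())  # 0, 50, 100
#' @export
modulating_value <- function(t, spec = modulating_spec()) {
  if (any(t < 0 | t > spec$total_s))
    stop("t outside the trial [0, ", spec$total_s, "] s")
  t1 <- spec$baseline_s
  t2 <- t1 + spec$rise_s
  t3 <- t2 + spec$plateau_s
  t4 <- t3 + spec$fall_s
  a <- spec$plateau_amp
  out <- numeric(length(t))
  ris <- t >= t1 & t < t2
  out[ris] <- a / 2 * (1 - cos(pi * (t[ris] - t1) / spec$rise_s))
  out[t >= t2 & t < t3] <- a
  fal <- t >= t3 & t < t4
  out[fal] <- a / 2 * (1 + cos(pi * (t[fal] - t3) / spec$fall_s))
  out
}
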