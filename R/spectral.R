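## Spectral analysis: modified periodogram PSD, sliding band power, ERD/ERS.

.taper_window <- function(n, taper = c("hamming", "hann", "rect")) {
  taper <- match.arg(taper)
  k <- 0:(n - 1)
  switch(taper,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann    = 0.5 * (1 - cos(2 * pi * k / (n - 1))),
         rect    = rep(1, n))
}

## tapered, per-window demeaned periodograms over sliding windows
## returns list(freq, pxx [n_freq x n_windows], t [window centres])
.sliding_periodograms <- function(x, fs, window_s, hop_s, taper) {
  n <- round(window_s * fs)
  if (length(x) < n)
    stop("signal shorter than one analysis window (", n, " samples)")
  hop <- max(1L, as.integer(round(hop_s * fs)))
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  w <- .taper_window(n, taper)
  segs <- vapply(starts, function(s) x[s:(s + n - 1L)], numeric(n))
  segs <- segs - rep(colMeans(segs), each = n)
  segs <- segs * w
  ft <- stats::mvfft(segs)
  scale <- fs * sum(w^2)
  nk <- floor(n / 2) + 1L
  pxx <- (Mod(ft[seq_len(nk), , drop = FALSE])^2) / scale
  if (n %% 2 == 0) {
    pxx[2:(nk - 1L), ] <- 2 * pxx[2:(nk - 1L), ]
  } else {
    pxx[2:nk, ] <- 2 * pxx[2:nk, ]
  }
  list(freq = (seq_len(nk) - 1L) * fs / n,
       pxx = pxx,
       t = (starts - 1L) / fs + window_s / 2)
}

#' Power spectral density by the modified periodogram method
#'
#' Tapered periodograms of sliding windows (default 1 s Hamming windows
#' advanced by 0.01 s, i.e. 99% overlap), demeaned per window, averaged over
#' all windows. Scaling is one-sided density (signal units squared per Hz),
#' so the integral of the PSD over frequency approximates the signal's
#' variance (Parseval).
#'
#' @param x sampled signal (e.g. a `v_out` column of a `trial_result`).
#' @param fs sampling rate (Hz).
#' @param window_s analysis window length (s).
#' @param hop_s hop between window starts (s).
#' @param taper `"hamming"` (default), `"hann"` or `"rect"`.
#' @return object of class `psd_estimate`: list with `freq` (Hz, up to
#'   `fs/2`), `power` (density), `fs`, `window_s`, `hop_s`, `taper`,
#'   `n_windows`.
#' @examples
#' x <- sin(2 * pi * 20 * seq(0, 16, by = 0.01))
#' p <- psd_estimate(x[-1], fs = 100)
#' peak_frequency(p)  # 20 Hz
#' @export
psd_estimate <- function(x, fs = 100, window_s = 1, hop_s = 0.01,
                         taper = "hamming") {
  sp <- .sliding_periodograms(x, fs, window_s, hop_s, taper)
  structure(list(freq = sp$freq, power = rowMeans(sp$pxx), fs = fs,
                 window_s = window_s, hop_s = hop_s, taper = taper,
                 n_windows = ncol(sp$pxx)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins up to %g Hz (%g s %s windows, %d averaged)\n",
              length(x$freq), max(x$freq), x$window_s, x$taper, x$n_windows))
  cat(sprintf("  peak %g Hz\n", peak_frequency(x)))
  invisible(x)
}

#' @export
plot.psd_estimate <- function(x, log = "y", ...) {
  graphics::plot(x$freq, x$power, type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "PSD", ...)
  invisible(x)
}

## element-wise average of psd_estimate objects on a common grid
.average_psd <- function(psds) {
  stopifnot(length(psds) >= 1)
  p <- psds[[1]]
  p$power <- rowMeans(vapply(psds, `[[`, numeric(length(p$power)), "power"))
  p
}

#' Frequency of maximum spectral power
#'
#' @param psd a [psd_estimate()].
#' @param band optional `c(f_lo, f_hi)` (Hz) restricting the search; by
#'   default the full grid is searched. Ties resolve to the lower frequency.
#' @return frequency (Hz).
#' @export
peak_frequency <- function(psd, band = NULL) {
  stopifnot(inherits(psd, "psd_estimate"))
  sel <- if (is.null(band)) rep(TRUE, length(psd$freq)) else
    psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("no frequency bins inside the requested band")
  f <- psd$freq[sel]; p <- psd$power[sel]
  f[which.max(p)]
}

#' Sliding-window band power
#'
#' Band-integrated power of each sliding analysis window (same modified
#' periodogram as [psd_estimate()]), timestamped at the window centres.
#' This is the `P(t)` entering the ERD/ERS computation.
#'
#' @param x sampled signal.
#' @param fs sampling rate (Hz).
#' @param band `c(f_lo, f_hi)` (Hz); must lie below the Nyquist frequency.
#' @param window_s,hop_s,taper as in [psd_estimate()].
#' @return object of class `band_power`: list with `time` (s, window
#'   centres), `power`, and the band/window metadata.
#' @export
band_power_timecourse <- function(x, fs = 100, band = beta_band("LB"),
                                  window_s = 1, hop_s = 0.01,
                                  taper = "hamming") {
  if (band[2] > fs / 2) stop("band extends above the Nyquist frequency")
  if (band[1] >= band[2]) stop("band must satisfy f_lo < f_hi")
  sp <- .sliding_periodograms(x, fs, window_s, hop_s, taper)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(sel)) stop("no frequency bins inside the requested band")
  df <- sp$freq[2] - sp$freq[1]
  structure(list(time = sp$t, power = colSums(sp$pxx[sel, , drop = FALSE]) * df,
                 band = band, fs = fs, window_s = window_s, hop_s = hop_s,
                 taper = taper),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> %g-%g Hz, %d windows over %.2f-%.2f s\n",
              x$band[1], x$band[2], length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Event-related desynchronization / synchronization
#'
#' `ERD/ERS(%) = 100 (P(t) - P_B) / P_B`, where `P_B` is the mean band power
#' over the baseline interval (windows lying entirely inside it). Negative
#' values are ERD (power loss against baseline), positive values ERS.
#'
#' @param P_t a [band_power_timecourse()] result, or a numeric power series
#'   accompanied by `time` and `window_s`.
#' @param baseline `c(t0, t1)` baseline interval (s); must contain at least
#'   one full analysis window.
#' @param time,window_s only used when `P_t` is a bare numeric vector.
#' @return object of class `erd_ers_curve`: list with `time`, `erd_ers`
#'   (percent), `baseline_power`, `baseline`, `band`.
#' @examples
#' bp <- list(time = seq(0.5, 15.5, 0.01), power = rep(2, 1501),
#'            window_s = 1, band = c(14, 19))
#' class(bp) <- "band_power"
#' all(erd_ers(bp)$erd_ers == 0)
#' @export
erd_ers <- function(P_t, baseline = c(0, 4), time = NULL, window_s = 1) {
  if (inherits(P_t, "band_power")) {
    time <- P_t$time; window_s <- P_t$window_s
    band <- P_t$band; power <- P_t$power
  } else {
    power <- as.numeric(P_t); band <- NULL
    if (is.null(time) || length(time) != length(power))
      stop("a bare power series needs a matching time vector")
  }
  inb <- (time - window_s / 2) >= baseline[1] & (time + window_s / 2) <= baseline[2]
  if (!any(inb)) stop("baseline interval does not cover one full window")
  P_B <- mean(power[inb])
  if (P_B == 0) stop("baseline power is zero; ERD/ERS undefined")
  structure(list(time = time, erd_ers = 100 * (power - P_B) / P_B,
                 baseline_power = P_B, baseline = baseline, band = band),
            class = "erd_ers_curve")
}

#' @export
print.erd_ers_curve <- function(x, ...) {
  cat(sprintf("<erd_ers_curve> %d points, baseline %g-%g s (P_B = %.3g)\n",
              length(x$time), x$baseline[1], x$baseline[2], x$baseline_power))
  cat(sprintf("  range %.1f%% .. %.1f%%\n", min(x$erd_ers), max(x$erd_ers)))
  invisible(x)
}

#' @export
plot.erd_ers_curve <- function(x, ...) {
  graphics::plot(x$time, x$erd_ers, type = "l", xlab = "time (s)",
                 ylab = "ERD/ERS (%)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Working point: time-averaged population rates
#'
#' The working point of a population is the mean spike density around which
#' it operates; its position on the sigmoid (low saturation, linear, high
#' saturation) determines how the population responds to input changes.
#'
#' @param x a `trial_result` (averages all four rates per column) or a
#'   numeric rate series.
#' @param window `c(t0, t1)` averaging interval (s) on the trial clock;
#'   defaults to the whole trial.
#' @param time time vector, only for the numeric method.
#' @param ... unused.
#' @return for a `trial_result`: a matrix with rows `zp`, `ze`, `zs`, `zf`
#'   and one column per simulated column; for a numeric series: the mean.
#' @export
working_point <- function(x, ...) UseMethod("working_point")

#' @rdname working_point
#' @export
working_point.trial_result <- function(x, window = NULL, ...) {
  if (is.null(window)) window <- range(x$time)
  sel <- x$time >= window[1] & x$time <= window[2]
  if (!any(sel)) stop("empty averaging window")
  rbind(zp = colMeans(x$zp[sel, , drop = FALSE]),
        ze = colMeans(x$ze[sel, , drop = FALSE]),
        zs = colMeans(x$zs[sel, , drop = FALSE]),
        zf = colMeans(x$zf[sel, , drop = FALSE]))
}

#' @rdname working_point
#' @export
working_point.default <- function(x, window = NULL, time = NULL, ...) {
  if (is.null(time)) time <- seq_along(x)
  if (is.null(window)) window <- range(time)
  sel <- time >= window[1] & time <= window[2]
  if (!any(sel)) stop("empty averaging window")
  mean(x[sel])
}
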