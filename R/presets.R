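## Basal parameter sets for the three beta sub-band columns.
## Connectivity constants are fixed multiples of C = 135; the synaptic gains
## G (mV) and lumped rate constants omega (1/s) select the sub-band.

.C_BASE <- 135

.BAND_KERNELS <- list(
  LB = c(Ge = 3.9, omega_e = 55, Gs = 4.3, omega_s = 25, Gf = 25, omega_f = 250),
  MB = c(Ge = 3.9, omega_e = 75, Gs = 4.3, omega_s = 33, Gf = 25, omega_f = 330),
  HB = c(Ge = 4.3, omega_e = 90, Gs = 4.6, omega_s = 36, Gf = 29, omega_f = 380)
)

.BETA_BANDS <- list(
  LB  = c(14, 19),
  MB  = c(20, 24),
  HB  = c(25, 30),
  low = c(2, 7)
)

## coupling values used for the high/low-amplitude ERD/ERS demonstrations
.KH_KL <- list(
  LB = c(K_H = 10, K_L = 26),
  MB = c(K_H = 6,  K_L = 24),
  HB = c(K_H = 4,  K_L = 13)
)

#' Basal parameters of one cortical column
#'
#' Builds the full parameter set of a four-population cortical column for one
#' of the three beta sub-band presets. The sigmoid converting membrane
#' potential to firing rate is shared by all populations
#' (`e0` = 2.5 pps, `r` = 0.56 /mV, `s0` = 6 mV). The three synaptic kernels
#' (excitatory, slow inhibitory, fast inhibitory) are second-order critically
#' damped filters with gain `G` (mV) and rate constant `omega` (1/s); the
#' seven intra-column connectivity constants are fixed multiples of C = 135.
#'
#' @param band band label: `"LB"` (low beta, 14-19 Hz), `"MB"` (medium beta,
#'   20-24 Hz) or `"HB"` (high beta, 25-30 Hz). Selects the kernel preset.
#' @param ... named overrides for individual parameters (`e0`, `r`, `s0`,
#'   `Ge`, `omega_e`, `Gs`, `omega_s`, `Gf`, `omega_f`, `Cep`, `Cpe`, `Csp`,
#'   `Cps`, `Cfp`, `Cfs`, `Cpf`).
#' @return an object of class `column_params`: a named list with elements
#'   `band`, `sigmoid` (e0, r, s0), `kernels` (Ge, omega_e, Gs, omega_s, Gf,
#'   omega_f) and `conn` (the seven connectivity constants).
#' @examples
#' column_params("LB")
#' column_params("HB", Gf = 30)
#' @export
column_params <- function(band = c("LB", "MB", "HB"), ...) {
  band <- match.arg(band)
  p <- c(
    e0 = 2.5, r = 0.56, s0 = 6,
    .BAND_KERNELS[[band]],
    Cep = .C_BASE, Cpe = 0.8 * .C_BASE, Csp = 0.25 * .C_BASE,
    Cps = 0.25 * .C_BASE, Cfp = 0.3 * .C_BASE, Cfs = 0.1 * .C_BASE,
    Cpf = 0.8 * .C_BASE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown column parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- as.numeric(dots)
  }
  if (any(p[c("e0", "r")] <= 0))
    stop("sigmoid parameters e0 and r must be positive")
  if (any(p[c("Ge", "omega_e", "Gs", "omega_s", "Gf", "omega_f")] <= 0))
    stop("synaptic gains and rate constants must be positive")
  if (any(p[c("Cep", "Cpe", "Csp", "Cps", "Cfp", "Cfs", "Cpf")] < 0))
    stop("connectivity constants must be non-negative")
  structure(
    list(
      band = band,
      sigmoid = p[c("e0", "r", "s0")],
      kernels = p[c("Ge", "omega_e", "Gs", "omega_s", "Gf", "omega_f")],
      conn = p[c("Cep", "Cpe", "Csp", "Cps", "Cfp", "Cfs", "Cpf")]
    ),
    class = "column_params"
  )
}

#' @export
print.column_params <- function(x, ...) {
  cat("<column_params> band", x$band, "\n")
  cat("  sigmoid: e0 =", x$sigmoid[["e0"]], "pps, r =", x$sigmoid[["r"]],
      "/mV, s0 =", x$sigmoid[["s0"]], "mV\n")
  k <- x$kernels
  cat(sprintf("  kernels: Ge %.2f mV / %g s^-1, Gs %.2f / %g, Gf %.2f / %g\n",
              k[["Ge"]], k[["omega_e"]], k[["Gs"]], k[["omega_s"]],
              k[["Gf"]], k[["omega_f"]]))
  cat("  conn   :", paste(names(x$conn), x$conn, sep = "=", collapse = " "), "\n")
  invisible(x)
}

## flatten to the 16-value vector the C++ engine expects
.param_vector <- function(p) {
  stopifnot(inherits(p, "column_params"))
  c(p$sigmoid[c("e0", "r", "s0")],
    p$kernels[c("Ge", "omega_e", "Gs", "omega_s", "Gf", "omega_f")],
    p$conn[c("Cep", "Cpe", "Csp", "Cps", "Cfp", "Cfs", "Cpf")])
}

#' Frequency band definitions
#'
#' Frequency limits (Hz) of the three beta sub-bands and of the low-frequency
#' band used to characterise an inhibited column.
#'
#' @param label one of `"LB"` (14-19 Hz), `"MB"` (20-24), `"HB"` (25-30) or
#'   `"low"` (2-7).
#' @return numeric vector `c(f_lo, f_hi)` in Hz.
#' @examples
#' beta_band("MB")
#' @export
beta_band <- function(label = c("LB", "MB", "HB", "low")) {
  label <- match.arg(label)
  .BETA_BANDS[[label]]
}

#' Per-band coupling presets for the ERD/ERS trial demonstrations
#'
#' Returns the high- and low-amplitude transcallosal gain selections
#' (`K_H`, `K_L`) used to demonstrate ERD/ERS time courses in each beta
#' sub-band: 10/26 (LB), 6/24 (MB), 4/13 (HB).
#'
#' @param band band label.
#' @return named numeric vector `c(K_H, K_L)`.
#' @export
kh_kl <- function(band = c("LB", "MB", "HB")) {
  band <- match.arg(band)
  .KH_KL[[band]]
}
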