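## Deterministic part of the single-column model: sigmoid rate function,
## membrane-potential assembly and the 10-dimensional derivative field.
## The C++ engine re-implements the same field for speed; these R versions
## are the reference used by the fixed-point solver and the test suite.

.STATE_NAMES <- c("yp", "xp", "ye", "xe", "ys", "xs", "yf", "xf", "yl", "xl")

#' Sigmoid firing-rate function
#'
#' Converts an average membrane potential into an average spike density:
#' `z = 2 e0 / (1 + exp(r (s0 - v)))`. Strictly increasing, bounded in
#' (0, 2 e0), and overflow-safe for arbitrarily large `|v|`.
#'
#' @param v membrane potential (mV); vectorised.
#' @param e0 half-maximum firing rate (pps).
#' @param r sigmoid slope (1/mV).
#' @param s0 centre potential (mV), where the output equals `e0`.
#' @return firing rate(s) in pps.
#' @examples
#' sigmoid_rate(6)            # at the centre: e0 = 2.5
#' sigmoid_rate(c(-1e6, 1e6)) # saturation: ~0 and 2 e0
#' @export
sigmoid_rate <- function(v, e0 = 2.5, r = 0.56, s0 = 6) {
  if (e0 <= 0 || r <= 0) stop("e0 and r must be positive")
  2 * e0 * stats::plogis(r * (v - s0))
}

#' Empty (all-zero) column state
#'
#' The ten state variables of one column: postsynaptic potentials `y` (mV)
#' and their derivatives `x` (mV/s) for the pyramidal-, excitatory-, slow-,
#' fast-population synapses and the auxiliary input pathway `l`. The zero
#' state is a valid initial condition.
#'
#' @return named numeric vector of length 10.
#' @export
column_state <- function() {
  stats::setNames(numeric(10), .STATE_NAMES)
}

.check_state <- function(state) {
  if (length(state) != 10)
    stop("a column state has 10 components (", paste(.STATE_NAMES, collapse = ", "), ")")
  if (is.null(names(state)) || !all(.STATE_NAMES %in% names(state)))
    names(state) <- .STATE_NAMES
  if (!all(is.finite(state)))
    stop("non-finite column state: numerical blow-up")
  state[.STATE_NAMES]
}

#' Average membrane potentials from a column state
#'
#' Assembles the four population membrane potentials from the postsynaptic
#' potentials: `vp = Cpe ye - Cps ys - Cpf yf` (the column output),
#' `ve = Cep yp`, `vs = Csp yp`, `vf = Cfp yp - Cfs ys + yl`.
#'
#' @param state named state vector (see [column_state()]).
#' @param conn named connectivity constants (the `conn` element of a
#'   [column_params()] object).
#' @return named numeric vector `c(vp, ve, vs, vf)` in mV.
#' @export
membrane_potentials <- function(state, conn = column_params("LB")$conn) {
  state <- .check_state(state)
  c(vp = unname(conn[["Cpe"]] * state[["ye"]] - conn[["Cps"]] * state[["ys"]] -
                  conn[["Cpf"]] * state[["yf"]]),
    ve = unname(conn[["Cep"]] * state[["yp"]]),
    vs = unname(conn[["Csp"]] * state[["yp"]]),
    vf = unname(conn[["Cfp"]] * state[["yp"]] - conn[["Cfs"]] * state[["ys"]] +
                  state[["yl"]]))
}

#' Population firing rates from membrane potentials
#'
#' Applies the shared sigmoid element-wise to the four membrane potentials.
#'
#' @param pot named vector `c(vp, ve, vs, vf)` (mV).
#' @param sigmoid named vector `c(e0, r, s0)` (the `sigmoid` element of a
#'   [column_params()] object).
#' @return named vector `c(zp, ze, zs, zf)` of spike densities (pps), each
#'   strictly inside (0, 2 e0).
#' @export
population_rates <- function(pot, sigmoid = column_params("LB")$sigmoid) {
  if (!all(is.finite(pot))) stop("non-finite membrane potentials")
  z <- sigmoid_rate(pot[c("vp", "ve", "vs", "vf")],
                    e0 = sigmoid[["e0"]], r = sigmoid[["r"]], s0 = sigmoid[["s0"]])
  stats::setNames(as.numeric(z), c("zp", "ze", "zs", "zf"))
}

#' Time derivative of a column state
#'
#' The deterministic right-hand side of one cortical column. Each synapse is
#' a critically damped second-order kernel `y'' = G w drive - 2 w y' - w^2 y`
#' with drives: `zp` (pyramidal pathway), `ze + u_p / Cpe` (excitatory
#' pathway; the external input is divided by `Cpe` because the membrane
#' potential multiplies `ye` by `Cpe`, making the input gain independent of
#' `Cpe`), `zs` (slow inhibitory), `zf` (fast inhibitory), and `u_f` through
#' the auxiliary excitatory pathway that feeds the fast interneurons.
#'
#' @param state named state vector (see [column_state()]).
#' @param u_p external input to the pyramidal pathway (pps). May fluctuate
#'   below zero when it carries noise.
#' @param u_f external input to the fast inhibitory pathway (pps).
#' @param params a [column_params()] object.
#' @return named numeric vector: d/dt of the 10 state variables.
#' @export
column_derivatives <- function(state, u_p, u_f, params = column_params("LB")) {
  state <- .check_state(state)
  pot <- membrane_potentials(state, params$conn)
  z <- population_rates(pot, params$sigmoid)
  k <- params$kernels
  Ge <- k[["Ge"]]; we <- k[["omega_e"]]
  Gs <- k[["Gs"]]; ws <- k[["omega_s"]]
  Gf <- k[["Gf"]]; wf <- k[["omega_f"]]
  Cpe <- params$conn[["Cpe"]]
  c(yp = state[["xp"]],
    xp = Ge * we * z[["zp"]] - 2 * we * state[["xp"]] - we^2 * state[["yp"]],
    ye = state[["xe"]],
    xe = Ge * we * (z[["ze"]] + u_p / Cpe) - 2 * we * state[["xe"]] - we^2 * state[["ye"]],
    ys = state[["xs"]],
    xs = Gs * ws * z[["zs"]] - 2 * ws * state[["xs"]] - ws^2 * state[["ys"]],
    yf = state[["xf"]],
    xf = Gf * wf * z[["zf"]] - 2 * wf * state[["xf"]] - wf^2 * state[["yf"]],
    yl = state[["xl"]],
    xl = Ge * we * u_f - 2 * we * state[["xl"]] - we^2 * state[["yl"]])
}

#' Closed-form impulse response of a synaptic kernel
#'
#' The critically damped second-order kernel has impulse response
#' `h(t) = G w t exp(-w t)`, peaking at `t = 1/w` with value `G w / e`.
#' Used as the analytic reference for integration-accuracy checks.
#'
#' @param t time (s); vectorised.
#' @param G synaptic gain (mV).
#' @param omega lumped rate constant (1/s).
#' @return impulse response values (mV per unit impulse).
#' @export
kernel_impulse_response <- function(t, G, omega) {
  ifelse(t < 0, 0, G * omega * t * exp(-omega * t))
}
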