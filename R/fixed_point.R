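## Algebraic equilibria of the noise-free model, found independently of the
## time-stepping engine: all derivatives are set to zero and the resulting
## nonlinear system is solved by bracketed root-finding (one column) or
## multi-start Newton iteration (two coupled columns). Delay does not enter:
## equilibria of a delay system coincide with those of the undelayed system.

## residual of the pyramidal potential equation for one column, given the
## (equilibrium) pyramidal rate of the other column
.vp_residual <- function(vp, zp_other, params, coupling, u_p_mean, u_f_mean) {
  s <- params$sigmoid; k <- params$kernels; cc <- params$conn
  sg <- function(v) sigmoid_rate(v, s[["e0"]], s[["r"]], s[["s0"]])
  u_p <- u_p_mean + coupling$Kp * zp_other
  u_f <- u_f_mean + coupling$Kf * zp_other
  zp <- sg(vp)
  yp <- k[["Ge"]] / k[["omega_e"]] * zp
  ze <- sg(cc[["Cep"]] * yp)
  zs <- sg(cc[["Csp"]] * yp)
  ye <- k[["Ge"]] / k[["omega_e"]] * (ze + u_p / cc[["Cpe"]])
  ys <- k[["Gs"]] / k[["omega_s"]] * zs
  yl <- k[["Ge"]] / k[["omega_e"]] * u_f
  vf <- cc[["Cfp"]] * yp - cc[["Cfs"]] * ys + yl
  zf <- sg(vf)
  yf <- k[["Gf"]] / k[["omega_f"]] * zf
  (cc[["Cpe"]] * ye - cc[["Cps"]] * ys - cc[["Cpf"]] * yf) - vp
}

## reconstruct the full equilibrium state of one column from its vp
.equilibrium_state <- function(vp, zp_other, params, coupling, u_p_mean, u_f_mean) {
  s <- params$sigmoid; k <- params$kernels; cc <- params$conn
  sg <- function(v) sigmoid_rate(v, s[["e0"]], s[["r"]], s[["s0"]])
  u_p <- u_p_mean + coupling$Kp * zp_other
  u_f <- u_f_mean + coupling$Kf * zp_other
  zp <- sg(vp)
  yp <- k[["Ge"]] / k[["omega_e"]] * zp
  ve <- cc[["Cep"]] * yp; vs <- cc[["Csp"]] * yp
  ze <- sg(ve); zs <- sg(vs)
  ye <- k[["Ge"]] / k[["omega_e"]] * (ze + u_p / cc[["Cpe"]])
  ys <- k[["Gs"]] / k[["omega_s"]] * zs
  yl <- k[["Ge"]] / k[["omega_e"]] * u_f
  vf <- cc[["Cfp"]] * yp - cc[["Cfs"]] * ys + yl
  zf <- sg(vf)
  yf <- k[["Gf"]] / k[["omega_f"]] * zf
  state <- column_state()
  state[c("yp", "ye", "ys", "yf", "yl")] <- c(yp, ye, ys, yf, yl)
  list(state = state,
       potentials = c(vp = vp, ve = unname(ve), vs = unname(vs), vf = unname(vf)),
       rates = c(zp = unname(zp), ze = unname(ze), zs = unname(zs), zf = unname(zf)))
}

#' Algebraic fixed points of the noise-free model
#'
#' Solves the equilibrium equations obtained by zeroing all derivatives,
#' with the noise replaced by its mean and the delay ignored (equilibria do
#' not depend on the delay). For one column this is a bracketed scalar root
#' search over the pyramidal potential; for two coupled columns a damped
#' Newton iteration on both pyramidal potentials is started from a grid of
#' initial guesses and all distinct solutions are returned, so coexisting
#' symmetric and asymmetric (winner/loser) equilibria are all found.
#'
#' @param columns a [column_params()] object or a list of one per column.
#' @param coupling a [coupling_spec()].
#' @param u_p,u_f mean external inputs (pps) to the pyramidal and fast
#'   inhibitory pathways.
#' @param n_columns 1 or 2.
#' @param vp_range search interval for the pyramidal potential (mV).
#' @param grid_n number of scan/multi-start points across `vp_range`.
#' @param tol residual tolerance (mV).
#' @return an object of class `fixed_points`: a list of equilibria, each a
#'   list of per-column `state`, `potentials`, `rates`, ordered by the first
#'   column's `zp`. An error is thrown when no root converges.
#' @examples
#' fp <- fixed_point(column_params("LB"), n_columns = 1)
#' fp[[1]]$rates[[1]]  # zp ~ 4.3, ze ~ 5, zf ~ 0.5
#' @export
fixed_point <- function(columns = column_params("LB"),
                        coupling = coupling_spec(K = 0),
                        u_p = 40, u_f = 3,
                        n_columns = 2,
                        vp_range = c(-60, 60),
                        grid_n = 241,
                        tol = 1e-9) {
  if (!n_columns %in% c(1L, 2L)) stop("n_columns must be 1 or 2")
  if (inherits(columns, "column_params")) columns <- rep(list(columns), n_columns)
  stopifnot(length(columns) == n_columns)

  if (n_columns == 1L) {
    if (coupling$K != 0) stop("a single column cannot be coupled: set K = 0")
    g <- seq(vp_range[1], vp_range[2], length.out = grid_n)
    r <- vapply(g, .vp_residual, 0, zp_other = 0, params = columns[[1]],
                coupling = coupling, u_p_mean = u_p, u_f_mean = u_f)
    roots <- c()
    for (i in seq_len(grid_n - 1))
      if (r[i] == 0) roots <- c(roots, g[i])
      else if (r[i] * r[i + 1] < 0)
        roots <- c(roots, stats::uniroot(.vp_residual, c(g[i], g[i + 1]),
                                         zp_other = 0, params = columns[[1]],
                                         coupling = coupling, u_p_mean = u_p,
                                         u_f_mean = u_f, tol = tol)$root)
    if (!length(roots)) stop("no equilibrium found in the search interval")
    sols <- lapply(sort(unique(round(roots, 8))), function(vp)
      list(.equilibrium_state(vp, 0, columns[[1]], coupling, u_p, u_f)))
    return(structure(sols, class = "fixed_points"))
  }

  f <- function(v)
    c(.vp_residual(v[1], sigmoid_rate(v[2], columns[[2]]$sigmoid[["e0"]],
                                      columns[[2]]$sigmoid[["r"]],
                                      columns[[2]]$sigmoid[["s0"]]),
                   columns[[1]], coupling, u_p, u_f),
      .vp_residual(v[2], sigmoid_rate(v[1], columns[[1]]$sigmoid[["e0"]],
                                      columns[[1]]$sigmoid[["r"]],
                                      columns[[1]]$sigmoid[["s0"]]),
                   columns[[2]], coupling, u_p, u_f))

  starts <- as.matrix(expand.grid(
    seq(vp_range[1], vp_range[2], length.out = max(7, round(sqrt(grid_n)))),
    seq(vp_range[1], vp_range[2], length.out = max(7, round(sqrt(grid_n))))))
  sols <- list()
  for (s in seq_len(nrow(starts))) {
    v <- starts[s, ]
    ok <- FALSE
    for (it in 1:80) {
      fv <- f(v)
      if (max(abs(fv)) < tol) { ok <- TRUE; break }
      h <- 1e-6
      J <- matrix(0, 2, 2)
      for (m in 1:2) {
        vh <- v; vh[m] <- vh[m] + h
        J[, m] <- (f(vh) - fv) / h
      }
      dv <- tryCatch(solve(J, fv), error = function(e) NULL)
      if (is.null(dv) || any(!is.finite(dv))) break
      step <- pmin(pmax(dv, -10), 10)  # damp large Newton steps
      v <- v - step
      if (v[1] < vp_range[1] - 20 || v[1] > vp_range[2] + 20 ||
          v[2] < vp_range[1] - 20 || v[2] > vp_range[2] + 20) break
    }
    if (ok) sols[[length(sols) + 1]] <- v
  }
  if (!length(sols)) {
    res <- min(abs(f(c(8, 8))))
    stop("fixed-point iteration did not converge (best residual ", res, " mV)")
  }
  sols <- unique(round(do.call(rbind, sols), 7))
  sols <- sols[order(sols[, 1]), , drop = FALSE]
  out <- lapply(seq_len(nrow(sols)), function(i) {
    v <- sols[i, ]
    z2 <- sigmoid_rate(v[2], columns[[2]]$sigmoid[["e0"]],
                       columns[[2]]$sigmoid[["r"]], columns[[2]]$sigmoid[["s0"]])
    z1 <- sigmoid_rate(v[1], columns[[1]]$sigmoid[["e0"]],
                       columns[[1]]$sigmoid[["r"]], columns[[1]]$sigmoid[["s0"]])
    list(.equilibrium_state(v[1], z2, columns[[1]], coupling, u_p, u_f),
         .equilibrium_state(v[2], z1, columns[[2]], coupling, u_p, u_f))
  })
  structure(out, class = "fixed_points")
}

#' @export
print.fixed_points <- function(x, ...) {
  cat("<fixed_points>", length(x), "equilibrium/equilibria\n")
  for (i in seq_along(x)) {
    zp <- vapply(x[[i]], function(col) col$rates[["zp"]], 0)
    cat(sprintf("  #%d zp = (%s)\n", i, paste(sprintf("%.3f", zp), collapse = ", ")))
  }
  invisible(x)
}
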