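#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step Euler-Maruyama integrator for one or two four-population
// cortical columns with delayed excitatory cross-coupling.
//
// State layout per column (10 variables):
//   0 yp, 1 xp : pyramidal-target excitatory synapse
//   2 ye, 3 xe : excitatory-interneuron synapse (receives u_p / Cpe)
//   4 ys, 5 xs : slow inhibitory synapse
//   6 yf, 7 xf : fast inhibitory synapse
//   8 yl, 9 xl : auxiliary excitatory pathway feeding u_f into v_f
//
// Parameter layout per column (16 values):
//   0 e0, 1 r, 2 s0,
//   3 Ge, 4 we, 5 Gs, 6 ws, 7 Gf, 8 wf,
//   9 Cep, 10 Cpe, 11 Csp, 12 Cps, 13 Cfp, 14 Cfs, 15 Cpf

static inline double sigm(double v, double e0, double r, double s0) {
  // logistic, overflow-safe for large |v|
  double a = r * (s0 - v);
  if (a > 700.0) return 2.0 * e0 * std::exp(-a);
  return 2.0 * e0 / (1.0 + std::exp(a));
}

// [[Rcpp::export]]
List integrate_columns_cpp(NumericMatrix par,     // 16 x ncols
                           double Kp, double Kf,
                           int delay_steps,
                           NumericMatrix np,      // n_steps x ncols (mean + noise [+ modulation])
                           NumericMatrix nf,      // n_steps x ncols
                           double dt,
                           int warmup_steps,
                           int decim,
                           NumericMatrix init_state) {  // 10 x ncols
  const int ncols = par.ncol();
  const int n_steps = np.nrow();
  if (ncols < 1 || ncols > 2) stop("one or two columns supported");
  if (nf.nrow() != n_steps || nf.ncol() != ncols || np.ncol() != ncols)
    stop("noise matrices must be n_steps x n_columns");
  if (init_state.nrow() != 10 || init_state.ncol() != ncols)
    stop("init_state must be 10 x n_columns");
  if (delay_steps < 1) delay_steps = 1;

  const int n_out = (n_steps - warmup_steps + decim - 1) / decim;
  if (n_out <= 0) stop("no output samples: warmup exceeds simulated span");

  // recorded channels per column
  NumericMatrix vout(n_out, ncols), zp_o(n_out, ncols), ze_o(n_out, ncols),
      zs_o(n_out, ncols), zf_o(n_out, ncols), up_o(n_out, ncols),
      uf_o(n_out, ncols), yp_o(n_out, ncols), ye_o(n_out, ncols),
      ys_o(n_out, ncols), yf_o(n_out, ncols), yl_o(n_out, ncols);

  double y[2][10];
  for (int c = 0; c < ncols; ++c)
    for (int k = 0; k < 10; ++k) y[c][k] = init_state(k, c);

  // circular history of zp per column, pre-filled with zeros
  std::vector<std::vector<double>> hist(ncols, std::vector<double>(delay_steps, 0.0));

  double d[2][10];
  for (int t = 0; t < n_steps; ++t) {
    const int hpos = t % delay_steps;
    double vp[2], zp[2], ze[2], zs[2], zf[2], up[2], uf[2];

    for (int c = 0; c < ncols; ++c) {
      const double *p = &par(0, c);
      const double e0 = p[0], r = p[1], s0 = p[2];
      vp[c] = p[10] * y[c][2] - p[12] * y[c][4] - p[15] * y[c][6];
      const double ve = p[9] * y[c][0];
      const double vs = p[11] * y[c][0];
      const double vf = p[13] * y[c][0] - p[14] * y[c][4] + y[c][8];
      zp[c] = sigm(vp[c], e0, r, s0);
      ze[c] = sigm(ve, e0, r, s0);
      zs[c] = sigm(vs, e0, r, s0);
      zf[c] = sigm(vf, e0, r, s0);
    }

    for (int c = 0; c < ncols; ++c) {
      const double zp_del = (ncols == 2) ? hist[1 - c][hpos] : 0.0;
      up[c] = np(t, c) + Kp * zp_del;
      uf[c] = nf(t, c) + Kf * zp_del;
    }

    if (t >= warmup_steps && (t - warmup_steps) % decim == 0) {
      const int i = (t - warmup_steps) / decim;
      for (int c = 0; c < ncols; ++c) {
        vout(i, c) = vp[c]; zp_o(i, c) = zp[c]; ze_o(i, c) = ze[c];
        zs_o(i, c) = zs[c]; zf_o(i, c) = zf[c]; up_o(i, c) = up[c];
        uf_o(i, c) = uf[c]; yp_o(i, c) = y[c][0]; ye_o(i, c) = y[c][2];
        ys_o(i, c) = y[c][4]; yf_o(i, c) = y[c][6]; yl_o(i, c) = y[c][8];
      }
    }

    for (int c = 0; c < ncols; ++c) {
      const double *p = &par(0, c);
      const double Ge = p[3], we = p[4], Gs = p[5], ws = p[6], Gf = p[7], wf = p[8];
      const double Cpe = p[10];
      d[c][0] = y[c][1];
      d[c][1] = Ge * we * zp[c] - 2.0 * we * y[c][1] - we * we * y[c][0];
      d[c][2] = y[c][3];
      d[c][3] = Ge * we * (ze[c] + up[c] / Cpe) - 2.0 * we * y[c][3] - we * we * y[c][2];
      d[c][4] = y[c][5];
      d[c][5] = Gs * ws * zs[c] - 2.0 * ws * y[c][5] - ws * ws * y[c][4];
      d[c][6] = y[c][7];
      d[c][7] = Gf * wf * zf[c] - 2.0 * wf * y[c][7] - wf * wf * y[c][6];
      d[c][8] = y[c][9];
      d[c][9] = Ge * we * uf[c] - 2.0 * we * y[c][9] - we * we * y[c][8];
    }

    for (int c = 0; c < ncols; ++c) {
      hist[c][hpos] = zp[c];
      for (int k = 0; k < 10; ++k) {
        y[c][k] += dt * d[c][k];
        if (!std::isfinite(y[c][k]))
          stop("state blew up (non-finite) at step %d (t = %.4f s), column %d, state %d",
               t, t * dt, c + 1, k + 1);
      }
    }
  }

  NumericMatrix final_state(10, ncols);
  for (int c = 0; c < ncols; ++c)
    for (int k = 0; k < 10; ++k) final_state(k, c) = y[c][k];

  return List::create(
      _["v_out"] = vout, _["zp"] = zp_o, _["ze"] = ze_o, _["zs"] = zs_o,
      _["zf"] = zf_o, _["u_p"] = up_o, _["u_f"] = uf_o, _["yp"] = yp_o,
      _["ye"] = ye_o, _["ys"] = ys_o, _["yf"] = yf_o, _["yl"] = yl_o,
      _["final_state"] = final_state);
}
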