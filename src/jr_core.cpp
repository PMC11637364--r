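#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

// Parameter vector layout shared with R/params.R (par_vector()):
// 0:A 1:B 2:a 3:b 4:v0 5:r 6:c1 7:c2 8:c3 9:c4 10:vmax
static inline double sigm(double v, const double* p) {
  // 2*vmax / (1 + exp(r*(v0 - v))); saturates without overflow
  double z = p[5] * (p[4] - v);
  if (z > 700.0) return 0.0;
  return 2.0 * p[10] / (1.0 + std::exp(z));
}

// Jansen-Rit right-hand side for one node. y has 6 entries, dy filled in place.
static inline void jr_rhs(const double* y, double wfic, double I_ext,
                          const double* p, double* dy) {
  const double A = p[0], B = p[1], a = p[2], b = p[3];
  const double c1 = p[6], c2 = p[7], c3 = p[8], c4 = p[9];
  dy[0] = y[3];
  dy[3] = A * a * sigm(y[1] - wfic * y[2], p) - 2.0 * a * y[3] - a * a * y[0];
  dy[1] = y[4];
  dy[4] = A * a * (c2 * sigm(c1 * y[0], p) + I_ext) - 2.0 * a * y[4] - a * a * y[1];
  dy[2] = y[5];
  dy[5] = B * b * c4 * sigm(c3 * y[0], p) - 2.0 * b * y[5] - b * b * y[2];
}

// [[Rcpp::export]]
double cpp_sigmoid(double v, NumericVector par) {
  return sigm(v, REAL(par));
}

// [[Rcpp::export]]
NumericVector cpp_node_rhs(NumericVector y, double wfic, double I_ext,
                           NumericVector par) {
  NumericVector dy(6);
  jr_rhs(REAL(y), wfic, I_ext, REAL(par), REAL(dy));
  return dy;
}

// Deterministic Heun run of a single isolated node at constant input.
// Records y0 and PSP (= y1 - y2) every `record_every` steps once t >= t_record.
// [[Rcpp::export]]
List cpp_node_run(double I_ext, double wfic, NumericVector y_init,
                  NumericVector par, double t_total, double t_record,
                  double dt, int record_every) {
  const double* p = REAL(par);
  double y[6], yp[6], f1[6], f2[6];
  for (int k = 0; k < 6; ++k) y[k] = y_init[k];
  long n_steps = (long)std::llround(t_total / dt);
  long rec_from = (long)std::llround(t_record / dt);
  std::vector<double> y0_rec, psp_rec, t_rec;
  y0_rec.reserve((n_steps - rec_from) / record_every + 2);
  psp_rec.reserve((n_steps - rec_from) / record_every + 2);
  t_rec.reserve((n_steps - rec_from) / record_every + 2);
  for (long s = 0; s < n_steps; ++s) {
    if (s >= rec_from && ((s - rec_from) % record_every) == 0) {
      y0_rec.push_back(y[0]);
      psp_rec.push_back(y[1] - y[2]);
      t_rec.push_back(s * dt);
    }
    jr_rhs(y, wfic, I_ext, p, f1);
    for (int k = 0; k < 6; ++k) yp[k] = y[k] + dt * f1[k];
    jr_rhs(yp, wfic, I_ext, p, f2);
    for (int k = 0; k < 6; ++k) y[k] += 0.5 * dt * (f1[k] + f2[k]);
    if ((s & 1023) == 0 && !std::isfinite(y[0]))
      stop("state diverged (non-finite y0) at t = %f ms", s * dt);
  }
  NumericVector y_final(6);
  for (int k = 0; k < 6; ++k) y_final[k] = y[k];
  return List::create(_["times"] = wrap(t_rec), _["y0"] = wrap(y0_rec),
                      _["psp"] = wrap(psp_rec), _["y_final"] = y_final);
}

// Delay-coupled network integration with stochastic Heun and optional dFIC
// augmentation.  The ring buffer stores the firing rate S(y1 - wfic*y2) of
// every node at every step, so delayed reads use the historic wfic value.
// Noise (sigma * sqrt(dt) * xi) enters the y3 equation only, with the same
// increment in predictor and corrector.  wfic derivatives are frozen during
// the transient window and wfic is clipped below at 0.
// [[Rcpp::export]]
List cpp_network_run(NumericMatrix weights, IntegerMatrix delay_steps,
                     NumericVector par, double G, double mu,
                     NumericMatrix y_init, NumericVector wfic_init,
                     double t_total, double dt, int record_every,
                     double sigma, int seed,
                     bool tuning, double eta, double tau_d, double y0_target,
                     double transient,
                     NumericVector y0d_init, NumericVector y2d_init,
                     bool record_input, IntegerVector record_vars) {
  const int N = weights.nrow();
  const double* p = REAL(par);
  long n_steps = (long)std::llround(t_total / dt);
  long n_transient = (long)std::llround(transient / dt);

  int max_delay = 0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (delay_steps(i, j) > max_delay) max_delay = delay_steps(i, j);
  const int H = max_delay + 1;

  std::vector<double> y(6 * N), yp(6 * N), f1(6 * N), f2(6 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 6; ++k) y[6 * i + k] = y_init(i, k);
  std::vector<double> wfic(wfic_init.begin(), wfic_init.end());
  std::vector<double> y0d(y0d_init.begin(), y0d_init.end());
  std::vector<double> y2d(y2d_init.begin(), y2d_init.end());
  std::vector<double> wfic_p(N), y0d_p(N), y2d_p(N);
  std::vector<double> I_ext(N), noise(N, 0.0);

  // history of rates, H rows (time slots) x N nodes
  std::vector<double> hist((size_t)H * N);
  for (int i = 0; i < N; ++i) {
    double r0 = sigm(y[6 * i + 1] - wfic[i] * y[6 * i + 2], p);
    for (int h = 0; h < H; ++h) hist[(size_t)h * N + i] = r0;
  }

  std::mt19937_64 rng((unsigned long long)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  const double sqdt = std::sqrt(dt);

  const int n_rv = record_vars.size();
  long n_rec = n_steps / record_every + 1;
  NumericVector times(n_rec);
  std::vector<NumericMatrix> recs;
  for (int v = 0; v < n_rv; ++v) recs.push_back(NumericMatrix(n_rec, N));
  NumericMatrix wfic_rec = tuning ? NumericMatrix(n_rec, N) : NumericMatrix(0, 0);
  NumericMatrix y0d_rec = tuning ? NumericMatrix(n_rec, N) : NumericMatrix(0, 0);
  NumericMatrix y2d_rec = tuning ? NumericMatrix(n_rec, N) : NumericMatrix(0, 0);
  NumericMatrix inp_rec = record_input ? NumericMatrix(n_rec, N) : NumericMatrix(0, 0);

  long ri = 0;
  bool blew_up = false;
  for (long s = 0; s <= n_steps; ++s) {
    const int slot = (int)(s % H);
    // store current rates into the ring buffer before using them
    for (int i = 0; i < N; ++i)
      hist[(size_t)slot * N + i] = sigm(y[6 * i + 1] - wfic[i] * y[6 * i + 2], p);
    // coupling input evaluated once per step from the history
    for (int i = 0; i < N; ++i) {
      double acc = 0.0;
      for (int j = 0; j < N; ++j) {
        double w = weights(i, j);
        if (w == 0.0) continue;
        int lag = delay_steps(i, j);
        int hs = slot - lag;
        if (hs < 0) hs += H;
        // before warm-up the buffer holds the initial rate, as initialized
        acc += w * hist[(size_t)hs * N + j];
      }
      I_ext[i] = mu + G * acc;
    }
    if (s % record_every == 0 && ri < n_rec) {
      times[ri] = s * dt;
      for (int v = 0; v < n_rv; ++v) {
        int k = record_vars[v];
        for (int i = 0; i < N; ++i) recs[v](ri, i) = y[6 * i + k];
      }
      if (tuning)
        for (int i = 0; i < N; ++i) {
          wfic_rec(ri, i) = wfic[i];
          y0d_rec(ri, i) = y0d[i];
          y2d_rec(ri, i) = y2d[i];
        }
      if (record_input)
        for (int i = 0; i < N; ++i) inp_rec(ri, i) = I_ext[i];
      ++ri;
    }
    if (s == n_steps) break;

    if (sigma > 0.0)
      for (int i = 0; i < N; ++i) noise[i] = sigma * sqdt * norm(rng);

    const bool wfic_active = tuning && (s >= n_transient);
    for (int i = 0; i < N; ++i) {
      jr_rhs(&y[6 * i], wfic[i], I_ext[i], p, &f1[6 * i]);
      for (int k = 0; k < 6; ++k) yp[6 * i + k] = y[6 * i + k] + dt * f1[6 * i + k];
      yp[6 * i + 3] += noise[i];
    }
    if (tuning) {
      for (int i = 0; i < N; ++i) {
        double d0 = (y[6 * i + 0] - y0d[i]) / tau_d;
        double d2 = (y[6 * i + 2] - y2d[i]) / tau_d;
        double dw = wfic_active ? eta * y2d[i] * (y0d[i] - y0_target) : 0.0;
        y0d_p[i] = y0d[i] + dt * d0;
        y2d_p[i] = y2d[i] + dt * d2;
        wfic_p[i] = wfic[i] + dt * dw;
        if (wfic_p[i] < 0.0) wfic_p[i] = 0.0;
        // corrector for the slow states
        double d0c = (yp[6 * i + 0] - y0d_p[i]) / tau_d;
        double d2c = (yp[6 * i + 2] - y2d_p[i]) / tau_d;
        double dwc = wfic_active ? eta * y2d_p[i] * (y0d_p[i] - y0_target) : 0.0;
        y0d[i] += 0.5 * dt * (d0 + d0c);
        y2d[i] += 0.5 * dt * (d2 + d2c);
        wfic[i] += 0.5 * dt * (dw + dwc);
        if (wfic[i] < 0.0) wfic[i] = 0.0;
      }
      for (int i = 0; i < N; ++i) {
        jr_rhs(&yp[6 * i], wfic_p[i], I_ext[i], p, &f2[6 * i]);
        for (int k = 0; k < 6; ++k)
          y[6 * i + k] += 0.5 * dt * (f1[6 * i + k] + f2[6 * i + k]);
        y[6 * i + 3] += noise[i];
      }
    } else {
      for (int i = 0; i < N; ++i) {
        jr_rhs(&yp[6 * i], wfic[i], I_ext[i], p, &f2[6 * i]);
        for (int k = 0; k < 6; ++k)
          y[6 * i + k] += 0.5 * dt * (f1[6 * i + k] + f2[6 * i + k]);
        y[6 * i + 3] += noise[i];
      }
    }
    if ((s & 255) == 0) {
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(y[6 * i])) { blew_up = true; break; }
      if (blew_up) stop("network state diverged (non-finite y0) at t = %f ms", s * dt);
    }
  }

  NumericMatrix y_final(N, 6);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 6; ++k) y_final(i, k) = y[6 * i + k];
  NumericVector wfic_final(N), y0d_final(N), y2d_final(N);
  for (int i = 0; i < N; ++i) {
    wfic_final[i] = wfic[i];
    y0d_final[i] = y0d[i];
    y2d_final[i] = y2d[i];
  }
  List states(n_rv);
  for (int v = 0; v < n_rv; ++v) states[v] = recs[v];
  return List::create(
      _["times"] = times, _["states"] = states,
      _["wfic"] = wfic_rec, _["y0d"] = y0d_rec, _["y2d"] = y2d_rec,
      _["input"] = inp_rec, _["y_final"] = y_final,
      _["wfic_final"] = wfic_final, _["y0d_final"] = y0d_final,
      _["y2d_final"] = y2d_final);
}

// Balloon hemodynamic model (vasodilatory signal s, inflow f, volume v,
// deoxyhemoglobin q) driven per node by a neural time series; Heun
// integration at the neural dt, sampled (not averaged) at multiples of TR.
// [[Rcpp::export]]
List cpp_balloon_run(NumericMatrix drive, double dt, double kappa,
                     double gamma, double tau, double alpha, double rho,
                     double V0, double TR) {
  const int T = drive.nrow(), N = drive.ncol();
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const double ialpha = 1.0 / alpha;
  const double tau_s = tau * 1000.0;          // s -> ms
  const double kappa_ms = kappa / 1000.0;     // 1/s -> 1/ms
  const double gamma_ms = gamma / 1000.0;
  int tr_steps = (int)std::llround(TR / dt);
  if (tr_steps < 1) stop("TR shorter than dt");
  int n_out = (T - 1) / tr_steps + 1;
  NumericMatrix bold(n_out, N);
  NumericVector times(n_out);
  for (int i = 0; i < N; ++i) {
    double st = 0.0, fl = 1.0, vo = 1.0, qd = 1.0;
    int oi = 0;
    for (int t = 0; t < T; ++t) {
      if (t % tr_steps == 0) {
        bold(oi, i) = 100.0 * V0 *
          (k1 * (1.0 - qd) + k2 * (1.0 - qd / vo) + k3 * (1.0 - vo));
        if (i == 0) times[oi] = t * dt;
        ++oi;
      }
      if (t == T - 1) break;
      // drive follows the conventional per-second form of the Balloon
      // equations; all rates are converted to per-ms for integration
      double x0 = drive(t, i) / 1000.0, x1 = drive(t + 1, i) / 1000.0;
      if (!std::isfinite(x0)) stop("non-finite drive at step %d", t);
      // predictor
      double ds1 = x0 - kappa_ms * st - gamma_ms * (fl - 1.0);
      double df1 = st / 1000.0;  // s state in 1/s units, f dimensionless
      double E0 = 1.0 - std::pow(1.0 - rho, 1.0 / fl);
      double dv1 = (fl - std::pow(vo, ialpha)) / tau_s;
      double dq1 = (fl * E0 / rho - std::pow(vo, ialpha) * qd / vo) / tau_s;
      double sp = st + dt * ds1, fp = fl + dt * df1;
      double vp = vo + dt * dv1, qp = qd + dt * dq1;
      if (fp < 1e-6) fp = 1e-6;
      if (vp < 1e-6) vp = 1e-6;
      // corrector
      double ds2 = x1 - kappa_ms * sp - gamma_ms * (fp - 1.0);
      double df2 = sp / 1000.0;
      double E0p = 1.0 - std::pow(1.0 - rho, 1.0 / fp);
      double dv2 = (fp - std::pow(vp, ialpha)) / tau_s;
      double dq2 = (fp * E0p / rho - std::pow(vp, ialpha) * qp / vp) / tau_s;
      st += 0.5 * dt * (ds1 + ds2);
      fl += 0.5 * dt * (df1 + df2);
      vo += 0.5 * dt * (dv1 + dv2);
      qd += 0.5 * dt * (dq1 + dq2);
      if (fl < 1e-6) fl = 1e-6;
      if (vo < 1e-6) vo = 1e-6;
    }
  }
  return List::create(_["times"] = times, _["signal"] = bold);
}

// Strict local maxima of a series within a +/- half_window neighborhood.
// Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_window_maxima(NumericVector x, int half_window) {
  const int T = x.size();
  std::vector<int> idx;
  for (int t = 1; t < T - 1; ++t) {
    if (!(x[t] > x[t - 1] && x[t] >= x[t + 1])) continue;
    int lo = std::max(0, t - half_window), hi = std::min(T - 1, t + half_window);
    bool is_max = true;
    for (int u = lo; u <= hi; ++u) {
      if (u == t) continue;
      if (x[u] >= x[t]) { is_max = false; break; }
    }
    if (is_max) idx.push_back(t + 1);
  }
  return wrap(idx);
}
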