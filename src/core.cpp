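#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Numerically stable softplus with a small positive floor so that log-rates
// stay finite even for very negative arguments.
static const double RATE_FLOOR = 1e-6;

static inline double softplus(double x) {
  double v;
  if (x > 30.0) v = x;
  else if (x < -30.0) v = std::exp(x);
  else v = std::log1p(std::exp(x));
  return v < RATE_FLOOR ? RATE_FLOOR : v;
}

// [[Rcpp::export]]
double cpp_softplus(double x) { return softplus(x); }

// ---------------------------------------------------------------------------
// Sensory adaptation (inter-click exponential relaxation to 1, multiplicative
// jump C -> phi * C at each click).  A click's own magnitude is the pre-jump
// state C(t-).  `side` is 0 for left, 1 for right; with `shared = false` each
// side carries its own adaptation state.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_adapt_clicks(NumericVector times, IntegerVector side,
                      double phi, double tau_phi, bool shared) {
  int m = times.size();
  NumericVector mags(m);
  if (shared) {
    double C = 1.0, tprev = 0.0;
    for (int i = 0; i < m; ++i) {
      C = 1.0 - (1.0 - C) * std::exp(-(times[i] - tprev) / tau_phi);
      mags[i] = C;
      C *= phi;
      tprev = times[i];
    }
  } else {
    double Cs[2] = {1.0, 1.0}, tp[2] = {0.0, 0.0};
    for (int i = 0; i < m; ++i) {
      int s = side[i];
      Cs[s] = 1.0 - (1.0 - Cs[s]) * std::exp(-(times[i] - tp[s]) / tau_phi);
      mags[i] = Cs[s];
      Cs[s] *= phi;
      tp[s] = times[i];
    }
  }
  return List::create(_["mags"] = mags);
}

// ---------------------------------------------------------------------------
// Settling: deposit mass onto the two nearest grid centers with linear
// distance weighting; anything at or beyond +-B is absorbed by the bound bin.
// `lo_hint` lets callers walk ascending positions in O(1) amortized.
// ---------------------------------------------------------------------------
static inline void settle_mass(double x, double w, const double* c, int n,
                               double* col, int& lo_hint) {
  if (x <= c[0]) { col[0] += w; return; }
  if (x >= c[n - 1]) { col[n - 1] += w; return; }
  int lo = lo_hint;
  if (lo < 0 || lo > n - 2 || c[lo] > x) lo = 0;
  while (lo < n - 2 && c[lo + 1] <= x) ++lo;
  lo_hint = lo;
  double d = c[lo + 1] - c[lo];
  double wr = (x - c[lo]) / d;
  col[lo] += w * (1.0 - wr);
  col[lo + 1] += w * wr;
}

// Precomputed discretization of a zero-mean Gaussian on a refined sub-grid
// (truncated at +-4 SD, renormalized).  The kernel depends only on the
// variance, so it is shared by every source bin of a transition operator.
struct GaussKernel {
  double sub = 0.0;
  int K = 0;
  std::vector<double> w;
  // `correct` subtracts the expected cloud-in-cell settling inflation
  // (width^2/6) from the kernel variance so that the settled one-step
  // kernel's variance matches the Fokker-Planck target.
  void set(double var, double width, int refine, bool correct = true) {
    if (correct) var -= width * width / 6.0;
    if (var <= 0.0) { K = 0; w.assign(1, 1.0); sub = 0.0; return; }
    double sd = std::sqrt(var);
    sub = width / refine;
    if (sub > sd / 2.0) sub = sd / 2.0;
    K = (int)std::ceil(4.0 * sd / sub);
    if (K > 600) { K = 600; sub = 4.0 * sd / K; }
    w.assign(2 * K + 1, 0.0);
    double wsum = 0.0, wss = 0.0;
    // taper to zero at the truncation edge so the discretized kernel (and
    // hence the likelihood) varies continuously with the parameters
    double edge = std::exp(-0.5 * 16.0);
    for (int k = -K; k <= K; ++k) {
      double z = k * sub / sd;
      w[k + K] = std::exp(-0.5 * z * z) - edge;
      if (w[k + K] < 0.0) w[k + K] = 0.0;
      wsum += w[k + K];
      wss += w[k + K] * (k * sub) * (k * sub);
    }
    for (double& x : w) x /= wsum;
    // rescale the point spacing so the discrete kernel's variance equals
    // the target exactly (undoes truncation/taper shrinkage)
    if (wss > 0.0) sub *= sd / std::sqrt(wss / wsum);
  }
};

// Deposit the kernel centered at mu onto the grid, tracking the touched row
// range (for band-aware matrix-vector products downstream).
static void settle_kernel(double mu, const GaussKernel& g, const double* c,
                          int n, double* col, int* rlo = nullptr,
                          int* rhi = nullptr) {
  int hint = -1;
  int lo = n, hi = -1;
  for (int k = -g.K; k <= g.K; ++k) {
    double x = mu + k * g.sub;
    int before = hint;
    settle_mass(x, g.w[k + g.K], c, n, col, hint);
    int a, b;
    if (x <= c[0]) { a = b = 0; }
    else if (x >= c[n - 1]) { a = b = n - 1; }
    else { a = hint; b = hint + 1; }
    if (a < lo) lo = a;
    if (b > hi) hi = b;
    (void)before;
  }
  if (rlo) *rlo = lo;
  if (rhi) *rhi = hi;
}

static void settle_gaussian(double mu, double var, const double* c, int n,
                            double* col, double width, int refine,
                            bool correct) {
  GaussKernel g;
  g.set(var, width, refine, correct);
  settle_kernel(mu, g, c, n, col);
}

// Exact one-step variance amplification of noise injected during a bin of
// an Ornstein-Uhlenbeck step: (e^{2 lambda dt} - 1) / (2 lambda dt) -> 1 as
// lambda -> 0.
static inline double ou_vfac(double lambda, double dt) {
  double q = 2.0 * lambda * dt;
  return std::fabs(q) < 1e-10 ? 1.0 + q / 2.0 : std::expm1(q) / q;
}

// [[Rcpp::export]]
double cpp_ou_vfac(double lambda, double dt) { return ou_vfac(lambda, dt); }

// Deterministic one-step update of a source location under da = lambda*a*dt
// plus an impulse of total size `delta` spread over the bin (exact linear-ODE
// integration over dt).
static inline double det_update(double a, double lambda, double dt,
                                double delta) {
  double ld = lambda * dt;
  if (std::fabs(ld) < 1e-10) return a * (1.0 + ld) + delta;
  return a * std::exp(ld) + delta * std::expm1(ld) / ld;
}

// ---------------------------------------------------------------------------
// One-step transition operator M: column j holds the destination of mass that
// starts in bin j.  Bound-bin columns are identity (absorbing).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_transition_matrix(NumericVector centers, double lambda,
                                    double dt, double delta, double var,
                                    int refine, bool correct = true) {
  int n = centers.size();
  NumericMatrix M(n, n);
  M(0, 0) = 1.0;
  M(n - 1, n - 1) = 1.0;
  double width = centers[2] - centers[1];
  const double* c = REAL(centers);
  GaussKernel g;
  g.set(var, width, refine, correct);
  for (int j = 1; j < n - 1; ++j) {
    double mu = det_update(c[j], lambda, dt, delta);
    settle_kernel(mu, g, c, n, &M(0, j));
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_initial_dist(NumericVector centers, double sigma2_i,
                               int refine, bool correct = true) {
  int n = centers.size();
  NumericVector p(n);
  double width = centers[2] - centers[1];
  settle_gaussian(0.0, sigma2_i, REAL(centers), n, REAL(p), width, refine,
                  correct);
  return p;
}

// ---------------------------------------------------------------------------
// Per-bin spike log-factors: out(i, t) = sum over neurons of the log-pmf of
// y(n, t) under rate softplus(slope_n * a_i + theta0(n, t)).
// family: 0 = Poisson, 1 = negative binomial with per-neuron dispersion.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_spike_logfac(NumericVector centers, NumericVector slopes,
                               NumericMatrix theta0, IntegerMatrix y,
                               double dt, int family, NumericVector disp) {
  int n = centers.size(), N = y.nrow(), T = y.ncol();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    double* o = &out(0, t);
    for (int nn = 0; nn < N; ++nn) {
      double yy = y(nn, t);
      double th0 = theta0(nn, t), sl = slopes[nn];
      if (family == 0) {
        double norm = yy > 0 ? std::lgamma(yy + 1.0) : 0.0;
        for (int i = 0; i < n; ++i) {
          double mu = softplus(sl * centers[i] + th0) * dt;
          o[i] += yy > 0 ? yy * std::log(mu) - mu - norm : -mu;
        }
      } else {
        double th = disp[nn];
        double norm = std::lgamma(yy + th) - std::lgamma(th)
                      - std::lgamma(yy + 1.0);
        for (int i = 0; i < n; ++i) {
          double mu = softplus(sl * centers[i] + th0) * dt;
          o[i] += norm + th * std::log(th / (th + mu))
                + (yy > 0 ? yy * std::log(mu / (th + mu)) : 0.0);
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forward (filtering) pass for one trial.  delta/sigma are the binned adapted
// click difference/sum.  logfac is the n x T spike log-factor matrix (0 x 0
// to skip spike conditioning).  M0 is the prebuilt no-click operator, reused
// for bins with no clicks.  Returns the running log-marginal of the spike
// factors, the final (normalized) filtered distribution, and optionally all
// filtered slices and per-bin operators (for smoothing).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_trial_filter(NumericVector centers, double lambda, double dt,
                      double sigma2_a, double sigma2_s,
                      NumericVector delta, NumericVector sigma,
                      NumericMatrix logfac, NumericVector p0,
                      NumericMatrix M0, int refine,
                      bool want_alpha, bool want_M, bool correct = true) {
  int n = centers.size(), T = delta.size();
  bool use_spikes = logfac.nrow() == n && logfac.ncol() >= T;
  NumericVector p = clone(p0);
  NumericVector pnew(n);
  double ll = 0.0;
  NumericMatrix alpha;
  List Ms(want_M ? T : 0);
  if (want_alpha) alpha = NumericMatrix(n, T);
  double width = centers[2] - centers[1];
  const double* c = REAL(centers);
  // column band of the prebuilt no-click operator
  std::vector<int> lo0(n, 0), hi0(n, n - 1);
  for (int j = 0; j < n; ++j) {
    int lo = n, hi = -1;
    for (int i = 0; i < n; ++i)
      if (M0(i, j) != 0.0) { if (i < lo) lo = i; if (i > hi) hi = i; }
    lo0[j] = lo; hi0[j] = hi;
  }
  std::vector<int> loM(n), hiM(n);
  for (int t = 0; t < T; ++t) {
    // propagate (band-aware matvec)
    std::fill(pnew.begin(), pnew.end(), 0.0);
    if (delta[t] == 0.0 && sigma[t] == 0.0) {
      for (int j = 0; j < n; ++j) {
        double pj = p[j];
        if (pj == 0.0) continue;
        const double* col = &M0(0, j);
        for (int i = lo0[j]; i <= hi0[j]; ++i) pnew[i] += col[i] * pj;
      }
      if (want_M) Ms[t] = M0;
    } else {
      NumericMatrix M(n, n);
      M(0, 0) = 1.0; M(n - 1, n - 1) = 1.0;
      loM[0] = hiM[0] = 0; loM[n - 1] = hiM[n - 1] = n - 1;
      double var = (sigma2_a * dt + sigma2_s * sigma[t]) * ou_vfac(lambda, dt);
      GaussKernel g;
      g.set(var, width, refine, correct);
      for (int j = 1; j < n - 1; ++j) {
        double mu = det_update(c[j], lambda, dt, delta[t]);
        settle_kernel(mu, g, c, n, &M(0, j), &loM[j], &hiM[j]);
      }
      for (int j = 0; j < n; ++j) {
        double pj = p[j];
        if (pj == 0.0) continue;
        const double* col = &M(0, j);
        for (int i = loM[j]; i <= hiM[j]; ++i) pnew[i] += col[i] * pj;
      }
      if (want_M) Ms[t] = M;
    }
    // condition on spikes in this bin
    if (use_spikes) {
      double mx = R_NegInf;
      for (int i = 0; i < n; ++i)
        if (logfac(i, t) > mx) mx = logfac(i, t);
      double csum = 0.0;
      for (int i = 0; i < n; ++i) {
        pnew[i] *= std::exp(logfac(i, t) - mx);
        csum += pnew[i];
      }
      if (!(csum > 0.0) || !R_FINITE(csum)) {
        return List::create(_["loglik"] = R_NegInf, _["pT"] = p,
                            _["alpha"] = alpha, _["M"] = Ms,
                            _["bad_bin"] = t + 1);
      }
      ll += std::log(csum) + mx;
      for (int i = 0; i < n; ++i) p[i] = pnew[i] / csum;
    } else {
      for (int i = 0; i < n; ++i) p[i] = pnew[i];
    }
    if (want_alpha)
      for (int i = 0; i < n; ++i) alpha(i, t) = p[i];
  }
  return List::create(_["loglik"] = ll, _["pT"] = p, _["alpha"] = alpha,
                      _["M"] = Ms, _["bad_bin"] = -1);
}

// Bin adapted clicks: delta = sum(signed mags), sigma = sum(|mags|) per click
// bin [t*dt, (t+1)*dt); clicks at exactly `duration` go to the last bin.
// [[Rcpp::export]]
List cpp_bin_clicks(NumericVector times, IntegerVector side,
                    NumericVector mags, double dt, int T) {
  NumericVector delta(T), sigma(T);
  int m = times.size();
  for (int k = 0; k < m; ++k) {
    int b = (int)std::floor(times[k] / dt + 1e-9);
    if (b >= T) b = T - 1;
    double s = side[k] == 1 ? mags[k] : -mags[k];
    delta[b] += s;
    sigma[b] += mags[k];
  }
  return List::create(_["delta"] = delta, _["sigma"] = sigma);
}

// Forward pass reusing per-bin transition operators already built for this
// trial (used by the independent-noise model, where every neuron shares the
// same stimulus-dependent operators).
// [[Rcpp::export]]
List cpp_filter_given_M(List Ms, NumericMatrix logfac, NumericVector p0,
                        bool want_alpha) {
  int T = Ms.size(), n = p0.size();
  bool use_spikes = logfac.nrow() == n && logfac.ncol() >= T;
  NumericVector p = clone(p0), pnew(n);
  double ll = 0.0;
  NumericMatrix alpha;
  if (want_alpha) alpha = NumericMatrix(n, T);
  for (int t = 0; t < T; ++t) {
    NumericMatrix M = Ms[t];
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += M(i, j) * p[j];
      pnew[i] = s;
    }
    if (use_spikes) {
      double mx = R_NegInf;
      for (int i = 0; i < n; ++i)
        if (logfac(i, t) > mx) mx = logfac(i, t);
      double csum = 0.0;
      for (int i = 0; i < n; ++i) {
        pnew[i] *= std::exp(logfac(i, t) - mx);
        csum += pnew[i];
      }
      if (!(csum > 0.0) || !R_FINITE(csum))
        return List::create(_["loglik"] = R_NegInf, _["pT"] = p,
                            _["alpha"] = alpha);
      ll += std::log(csum) + mx;
      for (int i = 0; i < n; ++i) p[i] = pnew[i] / csum;
    } else {
      for (int i = 0; i < n; ++i) p[i] = pnew[i];
    }
    if (want_alpha)
      for (int i = 0; i < n; ++i) alpha(i, t) = p[i];
  }
  return List::create(_["loglik"] = ll, _["pT"] = p, _["alpha"] = alpha);
}

// ---------------------------------------------------------------------------
// Euler-Maruyama simulation of the bounded accumulator.  Clicks are applied
// at their exact times with their (signed) adapted magnitude plus Gaussian
// click noise of variance sigma2_s * |magnitude|.  The path freezes (sticky
// at +-B) once the bound is reached.  Returns the state at `t_choice` and at
// `t_end` for each repetition and, when dt_out > 0, per-spike-bin averages
// (bins centered at t*dt_out, half-offset convention) for repetition 1.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_sim_paths(NumericVector ctimes, NumericVector cmags,
                   double t_end, double t_choice, double step,
                   double sigma2_i, double B, double lambda,
                   double sigma2_a, double sigma2_s,
                   int nreps, double dt_out, int n_out) {
  int nsteps = (int)std::ceil(t_end / step - 1e-9);
  int nclicks = ctimes.size();
  NumericVector a_choice(nreps), a_end(nreps);
  NumericVector binsum(n_out > 0 ? n_out : 0), bincnt(n_out > 0 ? n_out : 0);
  double sd_a = std::sqrt(sigma2_a * step);
  double sd_i = std::sqrt(sigma2_i);
  for (int r = 0; r < nreps; ++r) {
    double a = sd_i > 0 ? norm_rand() * sd_i : 0.0;
    bool frozen = std::fabs(a) >= B;
    if (frozen) a = a > 0 ? B : -B;
    int ci = 0;
    bool got_choice = false;
    double t = 0.0;
    for (int s = 0; s < nsteps; ++s) {
      double tn = (s + 1) * step;
      if (tn > t_end) tn = t_end;
      // clicks in [t, tn) -- each click applied exactly once per repetition
      while (ci < nclicks && ctimes[ci] <= tn + 1e-12) {
        if (!frozen) {
          double m = cmags[ci];
          a += m + norm_rand() * std::sqrt(sigma2_s * std::fabs(m));
          if (std::fabs(a) >= B) { a = a > 0 ? B : -B; frozen = true; }
        }
        ++ci;
      }
      if (!frozen) {
        a += lambda * a * (tn - t) + norm_rand() * sd_a;
        if (std::fabs(a) >= B) { a = a > 0 ? B : -B; frozen = true; }
      }
      if (!got_choice && tn >= t_choice - 1e-12) {
        a_choice[r] = a;
        got_choice = true;
      }
      if (r == 0 && n_out > 0) {
        int idx = (int)std::ceil((tn - dt_out / 2.0) / dt_out - 1e-12);
        if (idx < 1) idx = 1;
        if (idx <= n_out) { binsum[idx - 1] += a; bincnt[idx - 1] += 1.0; }
      }
      t = tn;
    }
    if (!got_choice) a_choice[r] = a;
    a_end[r] = a;
  }
  NumericVector avg(n_out > 0 ? n_out : 0);
  for (int i = 0; i < n_out; ++i)
    avg[i] = bincnt[i] > 0 ? binsum[i] / bincnt[i] : a_end[0];
  return List::create(_["a_choice"] = a_choice, _["a_end"] = a_end,
                      _["bin_avg"] = avg);
}
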