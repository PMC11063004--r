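#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gauss-Legendre nodes/weights on [-1, 1], computed by Newton iteration on
// the Legendre polynomial and cached per order.
// ---------------------------------------------------------------------------
static void gauss_legendre(int n, std::vector<double>& x, std::vector<double>& w) {
  static std::map<int, std::pair<std::vector<double>, std::vector<double> > > cache;
  std::map<int, std::pair<std::vector<double>, std::vector<double> > >::iterator it =
    cache.find(n);
  if (it != cache.end()) { x = it->second.first; w = it->second.second; return; }
  x.assign(n, 0.0); w.assign(n, 0.0);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; i++) {
    double xi = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int iter = 0; iter < 100; iter++) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < n; j++) {
        double p2 = p1; p1 = p0;
        p0 = ((2.0 * j + 1.0) * xi * p1 - j * p2) / (j + 1.0);
      }
      pp = n * (xi * p0 - p1) / (xi * xi - 1.0);
      double dx = p0 / pp;
      xi -= dx;
      if (std::fabs(dx) < 1e-15) break;
    }
    x[i] = -xi; x[n - 1 - i] = xi;
    w[i] = 2.0 / ((1.0 - xi * xi) * pp * pp);
    w[n - 1 - i] = w[i];
  }
  cache[n] = std::make_pair(x, w);
}

// ---------------------------------------------------------------------------
// First-passage-time density of a unit-variance Wiener process between
// absorbing boundaries, absorption at the LOWER boundary.
//   tdec : decision time (rt minus non-decision time), > 0
//   v    : drift; a : boundary separation; w : relative start point in (0,1)
// Series in normalized time u = t/a^2; small- and large-time expansions with
// truncation counts chosen for error < eps (standard first-passage
// literature).  Diffusion scale fixed at 1.
// ---------------------------------------------------------------------------
static double wfpt_lower(double tdec, double v, double a, double w, double eps) {
  if (tdec <= 0.0) return 0.0;
  double u = tdec / (a * a);
  // number of terms for each expansion
  double ks, kl;
  double tmp = 2.0 * std::sqrt(2.0 * M_PI * u) * eps;
  if (tmp < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(tmp));
    double lo = std::sqrt(u) + 1.0;
    if (ks < lo) ks = lo;
  } else ks = 2.0;
  tmp = M_PI * u * eps;
  if (tmp < 1.0) {
    kl = std::sqrt(-2.0 * std::log(tmp) / (M_PI * M_PI * u));
    double lo = 1.0 / (M_PI * std::sqrt(u));
    if (kl < lo) kl = lo;
  } else kl = 1.0 / (M_PI * std::sqrt(u));

  double f;
  if (ks < kl) {              // small-time expansion
    int K = (int)std::ceil(ks);
    int klo = -((K - 1) / 2), khi = (K - 1) / 2 + ((K - 1) % 2);
    double s = 0.0;
    for (int k = klo; k <= khi; k++) {
      double q = w + 2.0 * k;
      s += q * std::exp(-q * q / (2.0 * u));
    }
    f = s / std::sqrt(2.0 * M_PI * u * u * u);
  } else {                    // large-time expansion
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; k++) {
      s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f = s * M_PI;
  }
  if (f < 0.0) f = 0.0;
  // back-transform from normalized (v=0, a=1) to full parameters
  return f * std::exp(-v * a * w - v * v * tdec / 2.0) / (a * a);
}

// density at upper/lower boundary with uniform start-point variability of
// total range sw, averaged by Gauss-Legendre quadrature over w.
static double wfpt_density(double tdec, bool upper, double v, double a,
                           double w, double sw, double eps, int nodes) {
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  if (sw <= 0.0) return wfpt_lower(tdec, vv, a, ww, eps);
  if (ww - sw / 2.0 <= 0.0 || ww + sw / 2.0 >= 1.0) return -1.0; // infeasible
  std::vector<double> gx, gw;
  gauss_legendre(nodes, gx, gw);
  double s = 0.0;
  for (int i = 0; i < nodes; i++) {
    double wi = ww + 0.5 * sw * gx[i];
    s += gw[i] * wfpt_lower(tdec, vv, a, wi, eps);
  }
  return 0.5 * s; // nodes integrate to 2 over [-1,1]; mean over the range
}

// [[Rcpp::export]]
NumericVector wfpt_logdensity_cpp(NumericVector rt, IntegerVector upper,
                                  double v, double a, double t0, double z,
                                  double sz, double eps, int nodes) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double tdec = rt[i] - t0;
    if (tdec <= 0.0) { out[i] = R_NegInf; continue; }
    double f = wfpt_density(tdec, upper[i] != 0, v, a, z, sz, eps, nodes);
    if (f < 0.0) { out[i] = NA_REAL; continue; }   // infeasible z/sz
    out[i] = (f > 0.0) ? std::log(f) : R_NegInf;
  }
  return out;
}

// Summed log likelihood for one session under stimulus coding: the trial
// drift is sign[i] * v (sign +1 for rightward stimuli, -1 for leftward) and
// upper[i] = 1 codes a rightward (upper-boundary) response.
// [[Rcpp::export]]
double wfpt_loglik_cpp(NumericVector rt, IntegerVector upper,
                       NumericVector sign, double v, double a, double t0,
                       double z, double sz, double eps, int nodes) {
  int n = rt.size();
  if (a <= 0.0 || t0 < 0.0 || z <= 0.0 || z >= 1.0 || sz < 0.0) return R_NegInf;
  if (sz > 0.0 && (z - sz / 2.0 <= 1e-9 || z + sz / 2.0 >= 1.0 - 1e-9))
    return R_NegInf;
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    double tdec = rt[i] - t0;
    if (tdec <= 0.0) return R_NegInf;
    double f = wfpt_density(tdec, upper[i] != 0, sign[i] * v, a, z, sz, eps, nodes);
    if (f <= 0.0) return R_NegInf;
    ll += std::log(f);
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama trial simulator (brute-force oracle).  drift is the signed
// per-trial drift; response 1 = upper boundary (rightward).  Uses R's RNG.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix ddm_simulate_cpp(NumericVector drift, double a, double t0,
                               double z, double sz, double dt, double tmax) {
  int n = drift.size();
  NumericMatrix out(n, 2);
  double sdt = std::sqrt(dt);
  int max_steps = (int)(tmax / dt);
  for (int i = 0; i < n; i++) {
    double w = z;
    if (sz > 0.0) w = z + sz * (unif_rand() - 0.5);
    double x = w * a;
    int resp = -1; int step = 0;
    while (step < max_steps) {
      step++;
      x += drift[i] * dt + sdt * norm_rand();
      if (x >= a) { resp = 1; break; }
      if (x <= 0.0) { resp = 0; break; }
    }
    if (resp < 0) resp = (x >= a * 0.5) ? 1 : 0; // pathological cap; ~never hit
    out(i, 0) = resp;
    out(i, 1) = t0 + step * dt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// One MCMC chain for the hierarchical DDM.  Metropolis-within-Gibbs:
//  - per-session block random-walk update of (v, log a, t, logit z)
//  - conjugate Gibbs draws for group means, random-walk MH for log spreads
//  - random-walk MH for the group-level starting-point range sz
// Step sizes adapt toward 25% acceptance during burn-in only.  All
// randomness comes from R's RNG so runs are set.seed-deterministic.
//
// state layout per draw: v[1..n], a[1..n], t[1..n], z[1..n],
//   mu_v, sig_v, mu_la, sig_la, mu_t, sig_t, mu_lz, sig_lz, sz
// ---------------------------------------------------------------------------
static inline double dnorm_log(double x, double m, double s) {
  double r = (x - m) / s;
  return -0.5 * r * r - std::log(s) - 0.918938533204672742; // log sqrt(2 pi)
}

// [[Rcpp::export]]
List hddm_chain_cpp(List rt_list, List upper_list, List sign_list,
                    int n_samples, int burn_in,
                    NumericVector init, NumericVector prior,
                    bool estimate_sz, double eps, int nodes,
                    int sz_every) {
  int n = rt_list.size();
  std::vector<NumericVector> rts(n), sgn(n);
  std::vector<IntegerVector> up(n);
  for (int j = 0; j < n; j++) {
    rts[j] = as<NumericVector>(rt_list[j]);
    up[j] = as<IntegerVector>(upper_list[j]);
    sgn[j] = as<NumericVector>(sign_list[j]);
  }
  // prior constants: m, s (group-mean prior), hs (half-normal spread scale)
  // for v, log a, t, logit z in that order
  double pm[4], ps[4], ph[4];
  for (int p = 0; p < 4; p++) {
    pm[p] = prior[3 * p]; ps[p] = prior[3 * p + 1]; ph[p] = prior[3 * p + 2];
  }
  // state: transformed subject params th[p][j] (v, log a, t, logit z)
  std::vector<std::vector<double> > th(4, std::vector<double>(n));
  for (int j = 0; j < n; j++) {
    th[0][j] = init[j];
    th[1][j] = std::log(init[n + j]);
    th[2][j] = init[2 * n + j];
    th[3][j] = std::log(init[3 * n + j] / (1.0 - init[3 * n + j]));
  }
  double mu[4], sig[4];
  for (int p = 0; p < 4; p++) { mu[p] = init[4 * n + 2 * p]; sig[p] = init[4 * n + 2 * p + 1]; }
  double sz = init[4 * n + 8];

  // cached per-session log likelihood
  std::vector<double> llik(n);
  for (int j = 0; j < n; j++) {
    llik[j] = wfpt_loglik_cpp(rts[j], up[j], sgn[j], th[0][j],
                              std::exp(th[1][j]), th[2][j],
                              1.0 / (1.0 + std::exp(-th[3][j])), sz, eps, nodes);
  }
  // proposal scales
  std::vector<double> step_subj(n, 1.0);
  double rel[4] = {0.15, 0.08, 0.008, 0.20};
  double step_sig[4] = {0.1, 0.1, 0.1, 0.1};
  std::vector<int> acc_subj(n, 0);
  int acc_sig[4] = {0, 0, 0, 0};
  int adapt_window = 25, win = 0;

  // adaptive-Metropolis accumulators: per-subject running mean and scatter
  // of the transformed 4-vector (Welford), turned into a Cholesky proposal
  // once enough burn-in history exists; frozen after burn-in
  int am_start = burn_in / 4;
  if (am_start < 100) am_start = 100;
  std::vector<std::vector<double> > am_mean(n, std::vector<double>(4, 0.0));
  std::vector<std::vector<double> > am_M2(n, std::vector<double>(16, 0.0));
  std::vector<std::vector<double> > am_chol(n, std::vector<double>(16, 0.0));
  std::vector<bool> am_ready(n, false);
  long am_count = 0;

  int n_keep = n_samples - burn_in;
  NumericMatrix draws(n_keep, 4 * n + 9);

  for (int iter = 0; iter < n_samples; iter++) {
    // --- subject blocks (several sweeps: cheap relative to the global
    // sz step, and subject-level mixing limits the retained-sample ESS) ---
    for (int ss = 0; ss < 3; ss++)
    for (int j = 0; j < n; j++) {
      double prop[4];
      if (am_ready[j]) {
        double zr[4];
        for (int p = 0; p < 4; p++) zr[p] = norm_rand();
        const std::vector<double>& L = am_chol[j];
        for (int p = 0; p < 4; p++) {
          double d = 0.0;
          for (int q = 0; q <= p; q++) d += L[4 * p + q] * zr[q];
          prop[p] = th[p][j] + step_subj[j] * d;
        }
      } else {
        for (int p = 0; p < 4; p++)
          prop[p] = th[p][j] + step_subj[j] * rel[p] * norm_rand();
      }
      double zp = 1.0 / (1.0 + std::exp(-prop[3]));
      double llp = (prop[2] <= 0.0) ? R_NegInf :
        wfpt_loglik_cpp(rts[j], up[j], sgn[j], prop[0], std::exp(prop[1]),
                        prop[2], zp, sz, eps, nodes);
      if (R_finite(llp) || llp == R_NegInf) {
        double lr = llp - llik[j];
        for (int p = 0; p < 4; p++)
          lr += dnorm_log(prop[p], mu[p], sig[p]) - dnorm_log(th[p][j], mu[p], sig[p]);
        if (llp > R_NegInf && std::log(unif_rand()) < lr) {
          for (int p = 0; p < 4; p++) th[p][j] = prop[p];
          llik[j] = llp;
          acc_subj[j]++;
        }
      }
    }
    // --- group means: conjugate normal Gibbs ---
    for (int sweep = 0; sweep < 3; sweep++) {
    for (int p = 0; p < 4; p++) {
      double s2 = sig[p] * sig[p];
      double prec = n / s2 + 1.0 / (ps[p] * ps[p]);
      double sum = 0.0;
      for (int j = 0; j < n; j++) sum += th[p][j];
      double mean = (sum / s2 + pm[p] / (ps[p] * ps[p])) / prec;
      mu[p] = mean + norm_rand() / std::sqrt(prec);
    }
    // --- group spreads: RW on log sigma, half-normal prior ---
    for (int p = 0; p < 4; p++) {
      double ls = std::log(sig[p]);
      double lsp = ls + step_sig[p] * norm_rand();
      double sp = std::exp(lsp);
      double lr = 0.0;
      for (int j = 0; j < n; j++)
        lr += dnorm_log(th[p][j], mu[p], sp) - dnorm_log(th[p][j], mu[p], sig[p]);
      lr += -0.5 * (sp * sp - sig[p] * sig[p]) / (ph[p] * ph[p]); // half-normal
      lr += lsp - ls;                                             // Jacobian
      if (std::log(unif_rand()) < lr) { sig[p] = sp; acc_sig[p]++; }
    }
    }
    // --- adaptive-Metropolis bookkeeping (burn-in only) ---
    if (iter < burn_in) {
      am_count++;
      for (int j = 0; j < n; j++) {
        double* mn = &am_mean[j][0];
        double* M2 = &am_M2[j][0];
        double d[4], d2[4];
        for (int p = 0; p < 4; p++) {
          d[p] = th[p][j] - mn[p];
          mn[p] += d[p] / am_count;
          d2[p] = th[p][j] - mn[p];
        }
        for (int p = 0; p < 4; p++)
          for (int q = 0; q < 4; q++)
            M2[4 * p + q] += d[p] * d2[q];
      }
      if (am_count >= am_start && am_count % 50 == 0) {
        double sc = 2.38 * 2.38 / 4.0;
        for (int j = 0; j < n; j++) {
          double C[16];
          for (int k = 0; k < 16; k++)
            C[k] = sc * am_M2[j][k] / (am_count - 1);
          for (int p = 0; p < 4; p++) C[4 * p + p] += 1e-8;
          // Cholesky (4x4)
          double L[16] = {0};
          bool ok = true;
          for (int p = 0; p < 4 && ok; p++) {
            for (int q = 0; q <= p; q++) {
              double s = C[4 * p + q];
              for (int k = 0; k < q; k++) s -= L[4 * p + k] * L[4 * q + k];
              if (p == q) {
                if (s <= 0) { ok = false; break; }
                L[4 * p + p] = std::sqrt(s);
              } else L[4 * p + q] = s / L[4 * q + q];
            }
          }
          if (ok) {
            for (int k = 0; k < 16; k++) am_chol[j][k] = L[k];
            if (!am_ready[j]) { am_ready[j] = true; step_subj[j] = 1.0; }
          }
        }
      }
    }
    // --- sz: univariate slice sampler on its full conditional (flat prior
    // on the feasible range).  sz is weakly identified and nearly
    // independent of the other parameters, so exact conditional draws make
    // its chain mix at effectively lag-one.
    if (estimate_sz && (iter % sz_every == 0)) {
      double szmax = 1.0;
      for (int j = 0; j < n; j++) {
        double zj = 1.0 / (1.0 + std::exp(-th[3][j]));
        double b = 2.0 * std::min(zj, 1.0 - zj) - 4e-6;
        if (b < szmax) szmax = b;
      }
      if (szmax < 0) szmax = 0;
      std::vector<double> llp(n);
      // total data loglik at a candidate sz (vector kept for cache update)
      // lambda-free for C++98-compatible toolchains
      #define SZ_TOTLL(cand, out, tot) do {                               \
        tot = 0.0;                                                        \
        for (int jj = 0; jj < n; jj++) {                                  \
          out[jj] = wfpt_loglik_cpp(rts[jj], up[jj], sgn[jj], th[0][jj],  \
                                    std::exp(th[1][jj]), th[2][jj],       \
                                    1.0 / (1.0 + std::exp(-th[3][jj])),   \
                                    cand, eps, nodes);                    \
          tot += out[jj];                                                 \
          if (tot == R_NegInf) break;                                     \
        }                                                                 \
      } while (0)
      double cur = 0.0;
      for (int j = 0; j < n; j++) cur += llik[j];
      double logy = cur + std::log(unif_rand());
      double w = 0.04;
      double L = sz - w * unif_rand();
      double Rr = L + w;
      if (L < 0) L = 0;
      if (Rr > szmax) Rr = szmax;
      double tll;
      int guard = 0;
      while (L > 0 && guard++ < 25) {
        SZ_TOTLL(L, llp, tll);
        if (tll <= logy) break;
        L -= w; if (L < 0) L = 0;
      }
      guard = 0;
      while (Rr < szmax && guard++ < 25) {
        SZ_TOTLL(Rr, llp, tll);
        if (tll <= logy) break;
        Rr += w; if (Rr > szmax) Rr = szmax;
      }
      guard = 0;
      while (guard++ < 50) {
        double cand = L + (Rr - L) * unif_rand();
        SZ_TOTLL(cand, llp, tll);
        if (tll > logy) { sz = cand; llik = llp; break; }
        if (cand < sz) L = cand; else Rr = cand;
        if (Rr - L < 1e-9) break;
      }
      #undef SZ_TOTLL
    }
    // --- adaptation during burn-in ---
    win++;
    if (iter < burn_in && win == adapt_window) {
      for (int j = 0; j < n; j++) {
        double r = (double)acc_subj[j] / adapt_window;
        step_subj[j] *= std::exp(0.66 * (r - 0.25));
        acc_subj[j] = 0;
      }
      for (int p = 0; p < 4; p++) {
        double r = (double)acc_sig[p] / adapt_window;
        step_sig[p] *= std::exp(0.66 * (r - 0.35));
        acc_sig[p] = 0;
      }
      win = 0;
    }
    // --- store ---
    if (iter >= burn_in) {
      int r = iter - burn_in;
      for (int j = 0; j < n; j++) {
        draws(r, j) = th[0][j];
        draws(r, n + j) = std::exp(th[1][j]);
        draws(r, 2 * n + j) = th[2][j];
        draws(r, 3 * n + j) = 1.0 / (1.0 + std::exp(-th[3][j]));
      }
      for (int p = 0; p < 4; p++) {
        draws(r, 4 * n + 2 * p) = mu[p];
        draws(r, 4 * n + 2 * p + 1) = sig[p];
      }
      draws(r, 4 * n + 8) = sz;
    }
  }
  double fin = 0.0;
  for (int j = 0; j < n; j++) fin += llik[j];
  return List::create(_["draws"] = draws, _["final_loglik"] = fin);
}
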