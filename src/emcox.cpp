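// Computational kernels for the two-latent-class mixture Cox model:
// weighted Breslow partial likelihood (Newton-Raphson with step halving),
// weighted Breslow baseline hazard, and the fused EM loop.
//
// All kernels operate on data sorted by decreasing observed time so that
// the risk set at an event time is a prefix of the sorted arrays; ties are
// handled by accumulating whole tied-time groups before any event in the
// group contributes (Breslow convention, risk set {j : y_j >= y_i}).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Solve A x = b for small p with partial-pivot Gaussian elimination.
// Returns false when A is numerically singular.
static bool solve_small(std::vector<double> A, std::vector<double> b,
                        int p, std::vector<double>& x) {
  for (int col = 0; col < p; ++col) {
    int piv = col;
    double best = std::fabs(A[col * p + col]);
    for (int r = col + 1; r < p; ++r) {
      double v = std::fabs(A[r * p + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-12) return false;
    if (piv != col) {
      for (int c = 0; c < p; ++c) std::swap(A[col * p + c], A[piv * p + c]);
      std::swap(b[col], b[piv]);
    }
    double d = A[col * p + col];
    for (int r = col + 1; r < p; ++r) {
      double f = A[r * p + col] / d;
      if (f == 0.0) continue;
      for (int c = col; c < p; ++c) A[r * p + c] -= f * A[col * p + c];
      b[r] -= f * b[col];
    }
  }
  x.assign(p, 0.0);
  for (int r = p - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < p; ++c) s -= A[r * p + c] * x[c];
    x[r] = s / A[r * p + r];
  }
  return true;
}

// Weighted Breslow partial log-likelihood with score and information,
// on data sorted by decreasing time.
static void cox_eval(const std::vector<double>& ts,
                     const std::vector<int>& ev,
                     const std::vector<double>& Xs, // n x p, column major
                     const std::vector<double>& w,
                     int n, int p,
                     const std::vector<double>& beta,
                     double& ll, std::vector<double>& score,
                     std::vector<double>& info) {
  ll = 0.0;
  score.assign(p, 0.0);
  info.assign(p * p, 0.0);
  double S0 = 0.0;
  std::vector<double> S1(p, 0.0), S2(p * p, 0.0), mu(p);
  std::vector<double> eta(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int k = 0; k < p; ++k) e += Xs[k * n + i] * beta[k];
    eta[i] = e;
  }
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && ts[j] == ts[i]) {
      double we = w[j] * std::exp(eta[j]);
      S0 += we;
      for (int k = 0; k < p; ++k) {
        double xk = Xs[k * n + j];
        S1[k] += we * xk;
        for (int l = 0; l <= k; ++l)
          S2[k * p + l] += we * xk * Xs[l * n + j];
      }
      ++j;
    }
    if (S0 > 0.0) {
      for (int k = 0; k < p; ++k) mu[k] = S1[k] / S0;
      for (int m = i; m < j; ++m) {
        if (ev[m] != 1 || w[m] <= 0.0) continue;
        ll += w[m] * (eta[m] - std::log(S0));
        for (int k = 0; k < p; ++k) {
          score[k] += w[m] * (Xs[k * n + m] - mu[k]);
          for (int l = 0; l <= k; ++l)
            info[k * p + l] += w[m] * (S2[k * p + l] / S0 - mu[k] * mu[l]);
        }
      }
    }
    i = j;
  }
  for (int k = 0; k < p; ++k)
    for (int l = k + 1; l < p; ++l) {
      info[k * p + l] = info[l * p + k];
    }
}

struct CoxResult {
  std::vector<double> beta;
  double ll;
  std::vector<double> score;
  std::vector<double> info;
  bool converged;
  bool diverged;
  bool degenerate;
  int n_iter;
};

// Newton-Raphson with step halving; |beta_k| capped at `cap`.
static CoxResult cox_newton(const std::vector<double>& ts,
                            const std::vector<int>& ev,
                            const std::vector<double>& Xs,
                            const std::vector<double>& w,
                            int n, int p,
                            std::vector<double> beta,
                            double tol, int max_iter, double cap) {
  CoxResult res;
  res.converged = false;
  res.diverged = false;
  res.degenerate = false;
  res.n_iter = 0;

  double wev = 0.0, wtot = 0.0;
  for (int i = 0; i < n; ++i) { wtot += w[i]; if (ev[i] == 1) wev += w[i]; }
  if (wtot <= 0.0 || wev <= 0.0) {
    res.degenerate = true;
    res.beta = beta;
    res.ll = NA_REAL;
    res.score.assign(p, NA_REAL);
    res.info.assign(p * p, NA_REAL);
    return res;
  }

  double ll;
  // the score is a sum over events, so the tolerance scales with the
  // total weighted event mass (its numerical noise floor does too)
  const double sc_tol = tol * std::max(1.0, wev);
  std::vector<double> score, info, step;
  cox_eval(ts, ev, Xs, w, n, p, beta, ll, score, info);
  for (int it = 0; it < max_iter; ++it) {
    double smax = 0.0;
    for (int k = 0; k < p; ++k) smax = std::max(smax, std::fabs(score[k]));
    if (smax < sc_tol) { res.converged = true; break; }
    res.n_iter = it + 1;
    if (!solve_small(info, score, p, step)) {
      // ridge fallback for a flat/singular information matrix
      std::vector<double> ridged = info;
      for (int k = 0; k < p; ++k) ridged[k * p + k] += 1e-8 + 1e-8 * ridged[k * p + k];
      if (!solve_small(ridged, score, p, step)) { res.diverged = true; break; }
    }
    double ll_new;
    std::vector<double> cand(p), score_new, info_new;
    double frac = 1.0;
    bool accepted = false;
    for (int h = 0; h < 30; ++h) {
      for (int k = 0; k < p; ++k) {
        double b = beta[k] + frac * step[k];
        cand[k] = std::max(-cap, std::min(cap, b));
      }
      cox_eval(ts, ev, Xs, w, n, p, cand, ll_new, score_new, info_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) { accepted = true; break; }
      frac *= 0.5;
    }
    if (!accepted) break; // cannot improve: keep current beta
    beta = cand;
    ll = ll_new;
    score = score_new;
    info = info_new;
  }
  // monotone likelihood: the score decays to zero as |beta| grows, so a
  // "converged" coefficient near the cap is separation, not an estimate
  for (int k = 0; k < p; ++k)
    if (std::fabs(beta[k]) > cap - 2.0) res.diverged = true;
  res.beta = beta;
  res.ll = ll;
  res.score = score;
  res.info = info;
  return res;
}

struct BreslowResult {
  std::vector<double> times;  // distinct event times, increasing
  std::vector<double> jumps;
  std::vector<double> cum;
  int n_zero_risk;
};

// Weighted Breslow baseline hazard on data sorted by decreasing time.
static BreslowResult breslow_sorted(const std::vector<double>& ts,
                                    const std::vector<int>& ev,
                                    const std::vector<double>& w,
                                    const std::vector<double>& eta,
                                    int n) {
  BreslowResult br;
  br.n_zero_risk = 0;
  double S0 = 0.0;
  int i = 0;
  std::vector<double> t_desc, j_desc;
  while (i < n) {
    int j = i;
    double numer = 0.0;
    bool has_event = false;
    while (j < n && ts[j] == ts[i]) {
      S0 += w[j] * std::exp(eta[j]);
      if (ev[j] == 1) { has_event = true; numer += w[j]; }
      ++j;
    }
    if (has_event) {
      t_desc.push_back(ts[i]);
      if (S0 > 0.0) {
        j_desc.push_back(numer / S0);
      } else {
        j_desc.push_back(0.0);
        br.n_zero_risk++;
      }
    }
    i = j;
  }
  int K = (int)t_desc.size();
  br.times.resize(K);
  br.jumps.resize(K);
  br.cum.resize(K);
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    br.times[k] = t_desc[K - 1 - k];
    br.jumps[k] = j_desc[K - 1 - k];
  }
  for (int k = 0; k < K; ++k) { c += br.jumps[k]; br.cum[k] = c; }
  return br;
}

// Sort helper: indices ordered by decreasing time.
static std::vector<int> order_desc(const NumericVector& time) {
  int n = time.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return time[a] > time[b]; });
  return ord;
}

// [[Rcpp::export(name = ".cox_newton_cpp")]]
List cox_newton_cpp(NumericVector time, IntegerVector event, NumericMatrix X,
                    NumericVector w, NumericVector init, double tol,
                    int max_iter, double cap) {
  int n = time.size(), p = X.ncol();
  std::vector<int> ord = order_desc(time);
  std::vector<double> ts(n), Xs(n * p), ws(n);
  std::vector<int> ev(n);
  for (int i = 0; i < n; ++i) {
    int o = ord[i];
    ts[i] = time[o];
    ev[i] = event[o];
    ws[i] = w[o];
    for (int k = 0; k < p; ++k) Xs[k * n + i] = X(o, k);
  }
  std::vector<double> beta(init.begin(), init.end());
  CoxResult res = cox_newton(ts, ev, Xs, ws, n, p, beta, tol, max_iter, cap);
  NumericMatrix imat(p, p);
  if (!res.degenerate)
    for (int k = 0; k < p; ++k)
      for (int l = 0; l < p; ++l) imat(k, l) = res.info[k * p + l];
  return List::create(
      _["beta"] = NumericVector(res.beta.begin(), res.beta.end()),
      _["loglik"] = res.ll,
      _["score"] = NumericVector(res.score.begin(), res.score.end()),
      _["imat"] = imat,
      _["converged"] = res.converged,
      _["diverged"] = res.diverged,
      _["degenerate"] = res.degenerate,
      _["n_iter"] = res.n_iter);
}

// [[Rcpp::export(name = ".breslow_cpp")]]
List breslow_cpp(NumericVector time, IntegerVector event, NumericVector w,
                 NumericVector eta) {
  int n = time.size();
  std::vector<int> ord = order_desc(time);
  std::vector<double> ts(n), ws(n), es(n);
  std::vector<int> ev(n);
  for (int i = 0; i < n; ++i) {
    int o = ord[i];
    ts[i] = time[o];
    ev[i] = event[o];
    ws[i] = w[o];
    es[i] = eta[o];
  }
  BreslowResult br = breslow_sorted(ts, ev, ws, es, n);
  return List::create(
      _["times"] = NumericVector(br.times.begin(), br.times.end()),
      _["jumps"] = NumericVector(br.jumps.begin(), br.jumps.end()),
      _["cumulative"] = NumericVector(br.cum.begin(), br.cum.end()),
      _["n_zero_risk"] = br.n_zero_risk);
}

// Right-continuous step lookup: index (1-based) of largest grid time <= t,
// 0 when t precedes the first grid time.
static int step_index(const std::vector<double>& grid, double t) {
  return (int)(std::upper_bound(grid.begin(), grid.end(), t) - grid.begin());
}

// Fused EM loop for the two-class mixture Cox model with a shared
// baseline hazard: the two latent classes differ in their regression
// coefficients only, and the common baseline is re-estimated each
// iteration by the mixture-weighted Breslow formula
//   jump(t) = d_t / sum_{j at risk} [x_j exp(eta+_j) + (1-x_j) exp(eta-_j)].
// With fix_neg the false-positive coefficients stay at their initial
// values (hazard ratio 1 encodes a therapy inert without the target).
// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericVector time, IntegerVector event, NumericMatrix X,
                double gamma0, NumericVector beta_pos0, NumericVector beta_neg0,
                double tol, double tol_rel, int max_iter, bool fix_gamma,
                bool fix_neg, double inner_tol, int inner_max_iter,
                double cap, double gamma_clip) {
  int n = time.size(), p = X.ncol();
  std::vector<int> ord = order_desc(time);
  std::vector<double> ts(n), Xs(n * p);
  std::vector<int> ev(n);
  for (int i = 0; i < n; ++i) {
    int o = ord[i];
    ts[i] = time[o];
    ev[i] = event[o];
    for (int k = 0; k < p; ++k) Xs[k * n + i] = X(o, k);
  }

  // pooled Nelson-Aalen start for both class baselines
  std::vector<double> unitw(n, 1.0), zeroeta(n, 0.0);
  BreslowResult na0 = breslow_sorted(ts, ev, unitw, zeroeta, n);
  const std::vector<double> grid = na0.times; // fixed across iterations
  int K = (int)grid.size();
  if (K == 0) stop("no events in the data");

  // per-record step index into the grid (sorted order), computed once
  std::vector<int> gidx(n);
  for (int i = 0; i < n; ++i) gidx[i] = step_index(grid, ts[i]);

  std::vector<double> jp = na0.jumps, cp = na0.cum; // shared baseline
  std::vector<double> beta_p(beta_pos0.begin(), beta_pos0.end());
  std::vector<double> beta_n(beta_neg0.begin(), beta_neg0.end());
  double gamma = gamma0;

  std::vector<double> xh(n), lA(n), lB(n), one_minus(n);
  std::vector<double> eta_p(n), eta_n(n), logjp(K), mixw(n);
  std::vector<double> trace;
  trace.reserve(64);
  double ll_prev = NA_REAL;
  bool converged = false, mstep_ok = true;
  int n_iter = 0, n_zero = 0, n_zero_risk = 0;

  std::vector<double> unit(n, 1.0);
  for (int it = 0; it < max_iter; ++it) {
    // E-step at current parameters (shared baseline jumps jp / cumulative cp)
    double lg = std::log(gamma), l1g = std::log1p(-gamma);
    for (int k = 0; k < K; ++k)
      logjp[k] = jp[k] > 0.0 ? std::log(jp[k]) : NEG_INF;
    double ll = 0.0;
    n_zero = 0;
    for (int i = 0; i < n; ++i) {
      double ep = 0.0, en = 0.0;
      for (int k = 0; k < p; ++k) {
        double x = Xs[k * n + i];
        ep += x * beta_p[k];
        en += x * beta_n[k];
      }
      eta_p[i] = ep;
      eta_n[i] = en;
      int g = gidx[i];
      double H = g > 0 ? cp[g - 1] : 0.0;
      double la = lg - H * std::exp(ep);
      double lb = l1g - H * std::exp(en);
      if (ev[i] == 1) {
        double lj = g > 0 ? logjp[g - 1] : NEG_INF;
        la += lj + ep;
        lb += lj + en;
      }
      lA[i] = la;
      lB[i] = lb;
      double m = std::max(la, lb);
      if (m == NEG_INF) {
        xh[i] = gamma;
        ll += -745.0;
        ++n_zero;
      } else {
        double sa = std::exp(la - m), sb = std::exp(lb - m);
        xh[i] = sa / (sa + sb);
        ll += m + std::log(sa + sb);
      }
      one_minus[i] = 1.0 - xh[i];
    }
    trace.push_back(ll);
    n_iter = it + 1;
    double thresh = std::max(tol, tol_rel * std::fabs(ll));
    if (it > 0 && std::fabs(ll - ll_prev) < thresh) { converged = true; break; }
    ll_prev = ll;

    // M-step
    if (!fix_gamma) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xh[i];
      gamma = std::min(1.0 - gamma_clip, std::max(gamma_clip, s / n));
    }
    CoxResult fp = cox_newton(ts, ev, Xs, xh, n, p, beta_p,
                              inner_tol, inner_max_iter, cap);
    if (fp.degenerate) { mstep_ok = false; break; }
    beta_p = fp.beta;
    if (!fix_neg) {
      CoxResult fn = cox_newton(ts, ev, Xs, one_minus, n, p, beta_n,
                                inner_tol, inner_max_iter, cap);
      if (fn.degenerate) { mstep_ok = false; break; }
      beta_n = fn.beta;
    }
    for (int i = 0; i < n; ++i) {
      double ep = 0.0, en = 0.0;
      for (int k = 0; k < p; ++k) {
        double x = Xs[k * n + i];
        ep += x * beta_p[k];
        en += x * beta_n[k];
      }
      // mixture risk score for the shared-baseline Breslow update
      mixw[i] = std::log(xh[i] * std::exp(ep) + one_minus[i] * std::exp(en));
    }
    BreslowResult bs = breslow_sorted(ts, ev, unit, mixw, n);
    jp = bs.jumps;
    cp = bs.cum;
    n_zero_risk = bs.n_zero_risk;
  }

  // Eq 6 one final time so that mean(x_hat) == gamma_hat exactly
  if (!fix_gamma) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xh[i];
    gamma = std::min(1.0 - gamma_clip, std::max(gamma_clip, s / n));
  }

  // reorder posterior to the original record order
  NumericVector xhat(n), Apos(n), Bneg(n);
  for (int i = 0; i < n; ++i) {
    int o = ord[i];
    xhat[o] = xh[i];
    Apos[o] = std::exp(lA[i]);
    Bneg[o] = std::exp(lB[i]);
  }
  return List::create(
      _["gamma"] = gamma,
      _["beta_pos"] = NumericVector(beta_p.begin(), beta_p.end()),
      _["beta_neg"] = NumericVector(beta_n.begin(), beta_n.end()),
      _["times"] = NumericVector(grid.begin(), grid.end()),
      _["jumps"] = NumericVector(jp.begin(), jp.end()),
      _["cum"] = NumericVector(cp.begin(), cp.end()),
      _["x_hat"] = xhat,
      _["evidence_pos"] = Apos,
      _["evidence_neg"] = Bneg,
      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
      _["converged"] = converged,
      _["mstep_ok"] = mstep_ok,
      _["n_iter"] = n_iter,
      _["n_zero_evidence"] = n_zero,
      _["n_zero_risk"] = n_zero_risk);
}
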