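// Core of the bivariate linear mixed model: full-information Gaussian
// log-likelihood for paired (symptom, feature) longitudinal series with
// correlated random intercepts and correlated occasion residuals, plus a
// compact BFGS driver so that large simulation studies run quickly.
//
// Model, participant i, occasion j:
//   s_ij = mu_s (+ trend_j) + b_si + e_sij
//   f_ij = mu_f             + b_fi + e_fij
//   (b_si, b_fi) ~ N2(0, D),  (e_sij, e_fij) ~ N2(0, Sigma), independent.
// Any subset of {s_ij, f_ij} may be missing; the likelihood marginalises to
// the observed components (FIML).  Covariance matrices are parameterised by
// their log-Cholesky factors:  L = [[exp(a), 0], [b, exp(c)]], M = L L'.
//
// Marginalisation uses the matrix identities
//   V_i = B_i + Z_i D Z_i'
//   V_i^{-1} = B_i^{-1} - B_i^{-1} Z_i M_i^{-1} Z_i' B_i^{-1},
//   det V_i  = det B_i * det D * det M_i,  M_i = D^{-1} + Z_i' B_i^{-1} Z_i,
// where B_i is block-diagonal over occasions (Sigma restricted to the
// observed components), so everything reduces to 2x2 algebra.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct BlmmData {
  const int* id;      // 0-based participant index, rows sorted by (id, tp)
  const int* tp;      // 0-based occasion index
  const double* s;    // symptom value or NaN
  const double* f;    // feature value or NaN
  int n;              // rows (participant-occasions)
  int nid;            // participants
  int ntp;            // occasions
  bool t_means;       // occasion-specific symptom means?
};

const double BIG = 1e10;

// par layout: [mu_s (ntp if t_means else 1), mu_f, aD, bD, cD, aS, bS, cS]
inline int npar_of(const BlmmData& d) { return (d.t_means ? d.ntp : 1) + 1 + 6; }

double blmm_nll(const double* par, const BlmmData& d,
                std::vector<double>& u1, std::vector<double>& u2,
                std::vector<int>& nb, std::vector<int>& ns,
                std::vector<int>& nf) {
  const int nmu_s = d.t_means ? d.ntp : 1;
  const double* mu_s = par;
  const double mu_f = par[nmu_s];
  const double* th = par + nmu_s + 1;
  for (int k = 0; k < 6; ++k)
    if (!std::isfinite(th[k]) || std::fabs(th[k]) > 40.0) return BIG;

  const double lD11 = std::exp(th[0]), lD21 = th[1], lD22 = std::exp(th[2]);
  const double lS11 = std::exp(th[3]), lS21 = th[4], lS22 = std::exp(th[5]);
  const double D11 = lD11 * lD11, D12 = lD11 * lD21,
               D22 = lD21 * lD21 + lD22 * lD22;
  const double S11 = lS11 * lS11, S12 = lS11 * lS21,
               S22 = lS21 * lS21 + lS22 * lS22;
  const double dD = D11 * D22 - D12 * D12;   // = (lD11*lD22)^2 > 0
  const double dS = S11 * S22 - S12 * S12;
  if (dD <= 0.0 || dS <= 0.0) return BIG;
  const double logdetD = std::log(dD), logdetS = std::log(dS);
  const double a11 = S22 / dS, a22 = S11 / dS, a12 = -S12 / dS; // Sigma^{-1}
  const double Di11 = D22 / dD, Di22 = D11 / dD, Di12 = -D12 / dD;

  std::fill(u1.begin(), u1.end(), 0.0);
  std::fill(u2.begin(), u2.end(), 0.0);
  std::fill(nb.begin(), nb.end(), 0);
  std::fill(ns.begin(), ns.end(), 0);
  std::fill(nf.begin(), nf.end(), 0);

  double q0 = 0.0;
  long nobs = 0;
  for (int r = 0; r < d.n; ++r) {
    const bool hs = !ISNAN(d.s[r]), hf = !ISNAN(d.f[r]);
    if (!hs && !hf) continue;
    const int i = d.id[r];
    const double ms = d.t_means ? mu_s[d.tp[r]] : mu_s[0];
    if (hs && hf) {
      const double rs = d.s[r] - ms, rf = d.f[r] - mu_f;
      const double w1 = a11 * rs + a12 * rf, w2 = a12 * rs + a22 * rf;
      u1[i] += w1; u2[i] += w2;
      q0 += rs * w1 + rf * w2;
      ++nb[i]; nobs += 2;
    } else if (hs) {
      const double rs = d.s[r] - ms;
      u1[i] += rs / S11;
      q0 += rs * rs / S11;
      ++ns[i]; ++nobs;
    } else {
      const double rf = d.f[r] - mu_f;
      u2[i] += rf / S22;
      q0 += rf * rf / S22;
      ++nf[i]; ++nobs;
    }
  }

  double quad = q0, logdet = 0.0;
  for (int i = 0; i < d.nid; ++i) {
    if (nb[i] + ns[i] + nf[i] == 0) continue;
    const double M11 = Di11 + nb[i] * a11 + ns[i] / S11;
    const double M12 = Di12 + nb[i] * a12;
    const double M22 = Di22 + nb[i] * a22 + nf[i] / S22;
    const double detM = M11 * M22 - M12 * M12;
    if (detM <= 0.0 || M11 <= 0.0) return BIG;
    quad -= (M22 * u1[i] * u1[i] - 2.0 * M12 * u1[i] * u2[i] +
             M11 * u2[i] * u2[i]) / detM;
    logdet += std::log(detM) + logdetD + nb[i] * logdetS +
              ns[i] * std::log(S11) + nf[i] * std::log(S22);
  }
  if (quad < 0.0) {  // r'V^{-1}r >= 0: negative values are cancellation
    if (quad < -1e-6 * (std::fabs(q0) + 1.0)) return BIG;
    quad = 0.0;
  }
  const double nll = 0.5 * (quad + logdet + nobs * M_LN_SQRT_2PI * 2.0);
  return std::isfinite(nll) ? nll : BIG;
}

// Per-participant raw moments: with a single mean per series the likelihood
// depends on the data only through these, so each evaluation is O(nid)
// instead of O(rows).
struct SuffStats {
  std::vector<int> nb, ns, nf;
  std::vector<double> bs, bf, bss, bff, bsf;  // both-observed occasions
  std::vector<double> os, oss;                // symptom-only occasions
  std::vector<double> of, off;                // feature-only occasions
  long nobs = 0;

  explicit SuffStats(const BlmmData& d)
      : nb(d.nid), ns(d.nid), nf(d.nid), bs(d.nid), bf(d.nid), bss(d.nid),
        bff(d.nid), bsf(d.nid), os(d.nid), oss(d.nid), of(d.nid), off(d.nid) {
    for (int r = 0; r < d.n; ++r) {
      const bool hs = !ISNAN(d.s[r]), hf = !ISNAN(d.f[r]);
      if (!hs && !hf) continue;
      const int i = d.id[r];
      if (hs && hf) {
        ++nb[i]; bs[i] += d.s[r]; bf[i] += d.f[r];
        bss[i] += d.s[r] * d.s[r]; bff[i] += d.f[r] * d.f[r];
        bsf[i] += d.s[r] * d.f[r];
        nobs += 2;
      } else if (hs) {
        ++ns[i]; os[i] += d.s[r]; oss[i] += d.s[r] * d.s[r]; ++nobs;
      } else {
        ++nf[i]; of[i] += d.f[r]; off[i] += d.f[r] * d.f[r]; ++nobs;
      }
    }
  }
};

double blmm_nll_stats(const double* par, const SuffStats& st, int nid) {
  const double mu_s = par[0], mu_f = par[1];
  const double* th = par + 2;
  for (int k = 0; k < 6; ++k)
    if (!std::isfinite(th[k]) || std::fabs(th[k]) > 40.0) return BIG;
  const double lD11 = std::exp(th[0]), lD21 = th[1], lD22 = std::exp(th[2]);
  const double lS11 = std::exp(th[3]), lS21 = th[4], lS22 = std::exp(th[5]);
  const double D11 = lD11 * lD11, D12 = lD11 * lD21,
               D22 = lD21 * lD21 + lD22 * lD22;
  const double S11 = lS11 * lS11, S12 = lS11 * lS21,
               S22 = lS21 * lS21 + lS22 * lS22;
  const double dD = D11 * D22 - D12 * D12;
  const double dS = S11 * S22 - S12 * S12;
  if (dD <= 0.0 || dS <= 0.0) return BIG;
  const double logdetD = std::log(dD), logdetS = std::log(dS);
  const double a11 = S22 / dS, a22 = S11 / dS, a12 = -S12 / dS;
  const double Di11 = D22 / dD, Di22 = D11 / dD, Di12 = -D12 / dD;
  const double lS11l = std::log(S11), lS22l = std::log(S22);

  double quad = 0.0, logdet = 0.0;
  for (int i = 0; i < nid; ++i) {
    const int nbi = st.nb[i], nsi = st.ns[i], nfi = st.nf[i];
    if (nbi + nsi + nfi == 0) continue;
    // centred moments on both-observed occasions
    const double Rs = st.bs[i] - nbi * mu_s;
    const double Rf = st.bf[i] - nbi * mu_f;
    const double Rss = st.bss[i] - 2.0 * mu_s * st.bs[i] + nbi * mu_s * mu_s;
    const double Rff = st.bff[i] - 2.0 * mu_f * st.bf[i] + nbi * mu_f * mu_f;
    const double Rsf = st.bsf[i] - mu_s * st.bf[i] - mu_f * st.bs[i] +
                       nbi * mu_s * mu_f;
    // single-series occasions
    const double Os = st.os[i] - nsi * mu_s;
    const double Oss = st.oss[i] - 2.0 * mu_s * st.os[i] + nsi * mu_s * mu_s;
    const double Of = st.of[i] - nfi * mu_f;
    const double Off = st.off[i] - 2.0 * mu_f * st.of[i] + nfi * mu_f * mu_f;

    double q0 = a11 * Rss + 2.0 * a12 * Rsf + a22 * Rff +
                Oss / S11 + Off / S22;
    const double u1 = a11 * Rs + a12 * Rf + Os / S11;
    const double u2 = a12 * Rs + a22 * Rf + Of / S22;
    const double M11 = Di11 + nbi * a11 + nsi / S11;
    const double M12 = Di12 + nbi * a12;
    const double M22 = Di22 + nbi * a22 + nfi / S22;
    const double detM = M11 * M22 - M12 * M12;
    if (detM <= 0.0 || M11 <= 0.0) return BIG;
    quad += q0 - (M22 * u1 * u1 - 2.0 * M12 * u1 * u2 + M11 * u2 * u2) / detM;
    logdet += std::log(detM) + logdetD + nbi * logdetS +
              nsi * lS11l + nfi * lS22l;
  }
  if (quad < 0.0) {
    if (quad < -1e-3) return BIG;  // genuine blow-up, not rounding
    quad = 0.0;
  }
  const double nll = 0.5 * (quad + logdet + st.nobs * M_LN_SQRT_2PI * 2.0);
  return std::isfinite(nll) ? nll : BIG;
}

// Objective over the free-parameter subspace (fixed entries held constant).
struct Objective {
  BlmmData d;
  std::vector<double> full;     // full parameter vector (fixed slots kept)
  std::vector<int> free_idx;    // indices into `full` that are optimised
  std::vector<double> u1, u2;
  std::vector<int> nb, ns, nf;
  SuffStats* st = nullptr;      // fast path for constant means

  Objective(const BlmmData& dd, const std::vector<double>& start,
            const std::vector<int>& fidx)
      : d(dd), full(start), free_idx(fidx),
        u1(dd.nid), u2(dd.nid), nb(dd.nid), ns(dd.nid), nf(dd.nid) {
    if (!d.t_means) st = new SuffStats(d);
  }
  ~Objective() { delete st; }

  double operator()(const std::vector<double>& x) {
    for (size_t k = 0; k < free_idx.size(); ++k) full[free_idx[k]] = x[k];
    if (st) return blmm_nll_stats(full.data(), *st, d.nid);
    return blmm_nll(full.data(), d, u1, u2, nb, ns, nf);
  }

  void grad(const std::vector<double>& x, std::vector<double>& g) {
    std::vector<double> xt = x;
    for (size_t k = 0; k < x.size(); ++k) {
      const double h = 1e-5 * (1.0 + std::fabs(x[k]));
      xt[k] = x[k] + h; const double fp = (*this)(xt);
      xt[k] = x[k] - h; const double fm = (*this)(xt);
      xt[k] = x[k];
      g[k] = (fp - fm) / (2.0 * h);
    }
  }
};

// Plain BFGS with Armijo backtracking; adequate for this smooth, small
// problem when started from method-of-moments values.
List bfgs(Objective& obj, std::vector<double> x, int maxit, double gtol) {
  const int p = (int)x.size();
  double fx = obj(x);
  std::vector<double> g(p), gn(p), dir(p), xn(p), sv(p), yv(p);
  obj.grad(x, g);
  std::vector<double> H(p * p, 0.0);
  for (int i = 0; i < p; ++i) H[i * p + i] = 1.0;
  bool conv = false;
  int it = 0;
  for (; it < maxit; ++it) {
    double gmax = 0.0;
    for (int i = 0; i < p; ++i) gmax = std::max(gmax, std::fabs(g[i]));
    if (gmax < gtol * (1.0 + std::fabs(fx))) { conv = true; break; }
    // dir = -H g
    double dg = 0.0;
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += H[i * p + j] * g[j];
      dir[i] = -s;
    }
    for (int i = 0; i < p; ++i) dg += dir[i] * g[i];
    if (dg >= 0.0) {  // not a descent direction: reset
      for (int i = 0; i < p; ++i) { std::fill(H.begin(), H.end(), 0.0); }
      for (int i = 0; i < p; ++i) H[i * p + i] = 1.0;
      for (int i = 0; i < p; ++i) dir[i] = -g[i];
      dg = 0.0; for (int i = 0; i < p; ++i) dg += dir[i] * g[i];
    }
    double t = 1.0, fn = fx;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int i = 0; i < p; ++i) xn[i] = x[i] + t * dir[i];
      fn = obj(xn);
      if (fn <= fx + 1e-4 * t * dg) { ok = true; break; }
      t *= 0.5;
    }
    if (!ok) { conv = true; break; }  // no further progress possible
    obj.grad(xn, gn);
    double sy = 0.0;
    for (int i = 0; i < p; ++i) {
      sv[i] = xn[i] - x[i];
      yv[i] = gn[i] - g[i];
      sy += sv[i] * yv[i];
    }
    if (sy > 1e-12) {  // BFGS update (skip when curvature is lost)
      std::vector<double> Hy(p, 0.0);
      for (int i = 0; i < p; ++i)
        for (int j = 0; j < p; ++j) Hy[i] += H[i * p + j] * yv[j];
      double yHy = 0.0;
      for (int i = 0; i < p; ++i) yHy += yv[i] * Hy[i];
      for (int i = 0; i < p; ++i)
        for (int j = 0; j < p; ++j)
          H[i * p + j] += ((sy + yHy) * sv[i] * sv[j]) / (sy * sy)
                          - (Hy[i] * sv[j] + sv[i] * Hy[j]) / sy;
    }
    const double fdrop = fx - fn;
    x = xn; fx = fn; g = gn;
    if (fdrop < 1e-12 * (1.0 + std::fabs(fx))) { conv = true; break; }
  }
  obj.grad(x, g);
  double gmax = 0.0;
  for (int i = 0; i < p; ++i) gmax = std::max(gmax, std::fabs(g[i]));
  return List::create(_["par"] = NumericVector(x.begin(), x.end()),
                      _["value"] = fx, _["converged"] = conv,
                      _["iterations"] = it, _["grad_max"] = gmax);
}

BlmmData as_data(const IntegerVector& id, const IntegerVector& tp,
                 const NumericVector& s, const NumericVector& f,
                 int nid, int ntp, bool t_means) {
  BlmmData d;
  d.id = INTEGER(id); d.tp = INTEGER(tp);
  d.s = REAL(s); d.f = REAL(f);
  d.n = id.size(); d.nid = nid; d.ntp = ntp; d.t_means = t_means;
  return d;
}

}  // namespace

// [[Rcpp::export]]
double cpp_blmm_nll(NumericVector par, IntegerVector id, IntegerVector tp,
                    NumericVector s, NumericVector f, int nid, int ntp,
                    bool t_means) {
  BlmmData d = as_data(id, tp, s, f, nid, ntp, t_means);
  if (par.size() != npar_of(d)) stop("parameter vector has wrong length");
  std::vector<double> u1(nid), u2(nid);
  std::vector<int> nb(nid), ns(nid), nf(nid);
  return blmm_nll(REAL(par), d, u1, u2, nb, ns, nf);
}

// [[Rcpp::export]]
List cpp_blmm_fit(NumericVector start, LogicalVector free_mask,
                  IntegerVector id, IntegerVector tp, NumericVector s,
                  NumericVector f, int nid, int ntp, bool t_means,
                  int maxit, double gtol) {
  BlmmData d = as_data(id, tp, s, f, nid, ntp, t_means);
  if (start.size() != npar_of(d)) stop("start vector has wrong length");
  std::vector<double> st(start.begin(), start.end());
  std::vector<int> fidx;
  for (int i = 0; i < free_mask.size(); ++i)
    if (free_mask[i]) fidx.push_back(i);
  Objective obj(d, st, fidx);
  std::vector<double> x0(fidx.size());
  for (size_t k = 0; k < fidx.size(); ++k) x0[k] = st[fidx[k]];
  List res = bfgs(obj, x0, maxit, gtol);
  NumericVector xf = res["par"];
  NumericVector full(start.begin(), start.end());
  for (size_t k = 0; k < fidx.size(); ++k) full[fidx[k]] = xf[k];
  res["par_full"] = full;
  return res;
}

// Numeric central-difference Hessian of the negative log-likelihood over
// the free parameters, evaluated at `par`.
// [[Rcpp::export]]
NumericMatrix cpp_blmm_hessian(NumericVector par, LogicalVector free_mask,
                               IntegerVector id, IntegerVector tp,
                               NumericVector s, NumericVector f, int nid,
                               int ntp, bool t_means, double h_rel) {
  BlmmData d = as_data(id, tp, s, f, nid, ntp, t_means);
  if (par.size() != npar_of(d)) stop("parameter vector has wrong length");
  std::vector<double> st(par.begin(), par.end());
  std::vector<int> fidx;
  for (int i = 0; i < free_mask.size(); ++i)
    if (free_mask[i]) fidx.push_back(i);
  Objective obj(d, st, fidx);
  const int p = (int)fidx.size();
  std::vector<double> x(p), h(p);
  for (int k = 0; k < p; ++k) {
    x[k] = st[fidx[k]];
    h[k] = h_rel * (1.0 + std::fabs(x[k]));
  }
  NumericMatrix H(p, p);
  const double f0 = obj(x);
  std::vector<double> xt = x;
  for (int i = 0; i < p; ++i) {
    xt[i] = x[i] + h[i]; const double fp = obj(xt);
    xt[i] = x[i] - h[i]; const double fm = obj(xt);
    xt[i] = x[i];
    H(i, i) = (fp + fm - 2.0 * f0) / (h[i] * h[i]);
    for (int j = 0; j < i; ++j) {
      xt[i] = x[i] + h[i]; xt[j] = x[j] + h[j]; const double fpp = obj(xt);
      xt[j] = x[j] - h[j]; const double fpm = obj(xt);
      xt[i] = x[i] - h[i]; const double fmm = obj(xt);
      xt[j] = x[j] + h[j]; const double fmp = obj(xt);
      xt[i] = x[i]; xt[j] = x[j];
      H(i, j) = H(j, i) = (fpp - fpm - fmp + fmm) / (4.0 * h[i] * h[j]);
    }
  }
  return H;
}
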