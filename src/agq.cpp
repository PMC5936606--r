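// Marginal log-likelihood and analytic score for baseline-category logit
// models with cluster random intercepts following Bridge distributions.
//
// The joint model couples the two outcome-specific Bridge intercepts through
// a Gaussian copula with correlation rho.  Integration is over the copula's
// latent normal scale z: u_k = Q_bridge(Phi(z_k); phi_k), so the integrand is
// exp(a1(z1) + a2(z2)) * bvn(z1, z2; rho) and a tensor Gauss-Hermite rule
// applies.  By default the rule is adapted per cluster: nodes are centred at
// the mode of the log-integrand and rescaled by the Cholesky factor of the
// inverse negative Hessian (the same scheme PROC NLMIXED and modern GLMM
// fitters use); `adaptive = false` recovers the plain (unshifted) rule.
//
// The score returned is the quadrature approximation of the exact score,
// E_posterior[ d log f(y, u) / d theta ]; the (second-order) dependence of
// the adapted nodes on the parameters is not differentiated.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

struct BridgeZ {
  double u;        // Q_bridge(Phi(z); phi)
  double du_dz;
  double d2u_dz2;
  double du_dphi;
};

// Bridge quantile (and derivatives) evaluated at p = Phi(z).
static inline BridgeZ bridge_at(double z, double phi, bool need2, bool needphi) {
  double p = R::pnorm(z, 0.0, 1.0, 1, 0);
  const double eps = 1e-15;
  if (p < eps) p = eps; else if (p > 1.0 - eps) p = 1.0 - eps;
  double A = phi * M_PI * p, B = phi * M_PI * (1.0 - p);
  double sA = std::sin(A), sB = std::sin(B);
  double u = (std::log(sA) - std::log(sB)) / phi;
  double cotA = std::cos(A) / sA, cotB = std::cos(B) / sB;
  double dq_dp = M_PI * (cotA + cotB);
  double dn = R::dnorm(z, 0.0, 1.0, 0);
  BridgeZ out;
  out.u = u;
  out.du_dz = dq_dp * dn;
  out.d2u_dz2 = 0.0;
  out.du_dphi = 0.0;
  if (need2) {
    double d2q_dp2 = M_PI * M_PI * phi * (1.0 / (sB * sB) - 1.0 / (sA * sA));
    out.d2u_dz2 = d2q_dp2 * dn * dn - dq_dp * z * dn;
  }
  if (needphi)
    out.du_dphi = -u / phi + (M_PI / phi) * (p * cotA - (1.0 - p) * cotB);
  return out;
}

// Sum over rows [r0, r1) of log P(y_r | u) for one 3-category outcome with
// baseline-category logits l_c = u + eta_c (c = 1, 2; category 0 = reference).
// Optionally the first two derivatives in u:
//   su  = sum( 1[y != 0] - pi_plus ),   suu = -sum( pi_plus (1 - pi_plus) )
static void clust_eval(const int* y, const double* e1, const double* e2,
                       int r0, int r1, double u,
                       double* a, double* su, double* suu) {
  double aa = 0.0, s = 0.0, ss = 0.0;
  for (int r = r0; r < r1; ++r) {
    double l1 = u + e1[r], l2 = u + e2[r];
    double mx = l1 > l2 ? l1 : l2; if (mx < 0.0) mx = 0.0;
    double t1 = std::exp(l1 - mx), t2 = std::exp(l2 - mx);
    double d = std::exp(-mx) + t1 + t2;
    double logD = mx + std::log(d);
    int yi = y[r];
    aa += (yi == 0 ? 0.0 : (yi == 1 ? l1 : l2)) - logD;
    if (su) {
      double pp = (t1 + t2) / d;
      s += (yi != 0 ? 1.0 : 0.0) - pp;
      ss -= pp * (1.0 - pp);
    }
  }
  *a = aa;
  if (su) { *su = s; *suu = ss; }
}

// As clust_eval but also stores per-row category probabilities (for the
// score) into pa, pb (length >= r1 - r0).
static void clust_eval_store(const int* y, const double* e1, const double* e2,
                             int r0, int r1, double u,
                             double* a, double* su, double* pa, double* pb) {
  double aa = 0.0, s = 0.0;
  for (int r = r0; r < r1; ++r) {
    double l1 = u + e1[r], l2 = u + e2[r];
    double mx = l1 > l2 ? l1 : l2; if (mx < 0.0) mx = 0.0;
    double t1 = std::exp(l1 - mx), t2 = std::exp(l2 - mx);
    double d = std::exp(-mx) + t1 + t2;
    double logD = mx + std::log(d);
    int yi = y[r];
    aa += (yi == 0 ? 0.0 : (yi == 1 ? l1 : l2)) - logD;
    double p1 = t1 / d, p2 = t2 / d;
    pa[r - r0] = p1; pb[r - r0] = p2;
    s += (yi != 0 ? 1.0 : 0.0) - (p1 + p2);
  }
  *a = aa; *su = s;
}

static inline double log_bvn(double z1, double z2, double rho) {
  double om = 1.0 - rho * rho;
  double Q = z1 * z1 - 2.0 * rho * z1 * z2 + z2 * z2;
  return -LOG2PI - 0.5 * std::log(om) - Q / (2.0 * om);
}

static inline double dlog_bvn_drho(double z1, double z2, double rho) {
  double om = 1.0 - rho * rho;
  double Q = z1 * z1 - 2.0 * rho * z1 * z2 + z2 * z2;
  return rho / om + (z1 * z2 * om - rho * Q) / (om * om);
}

// Per-cluster linear predictors eta_c = thresh_c + X beta_c, c = 1, 2.
static void fill_eta(const NumericMatrix& X, const NumericVector& thr,
                     const NumericMatrix& sl, std::vector<double>& e1,
                     std::vector<double>& e2) {
  int n = X.nrow(), p = X.ncol();
  e1.assign(n, thr[0]); e2.assign(n, thr[1]);
  for (int j = 0; j < p; ++j) {
    double b1 = sl(j, 0), b2 = sl(j, 1);
    for (int r = 0; r < n; ++r) {
      double x = X(r, j);
      e1[r] += x * b1; e2[r] += x * b2;
    }
  }
}

// 2-D Newton search for the mode of
//   h(z) = a1(z1) + a2(z2) + log bvn(z; rho).
static void find_mode2(const int* y1, const double* e11, const double* e12,
                       const int* y2, const double* e21, const double* e22,
                       int r0, int r1, double phi1, double phi2, double rho,
                       double* zh1, double* zh2,
                       double* h11o, double* h12o, double* h22o) {
  double z1 = 0.0, z2 = 0.0;
  double om = 1.0 - rho * rho;
  double a1, s1, ss1, a2, s2, ss2;
  double h11 = -1.0, h12 = 0.0, h22 = -1.0;
  BridgeZ b1 = bridge_at(z1, phi1, true, false);
  BridgeZ b2 = bridge_at(z2, phi2, true, false);
  clust_eval(y1, e11, e12, r0, r1, b1.u, &a1, &s1, &ss1);
  clust_eval(y2, e21, e22, r0, r1, b2.u, &a2, &s2, &ss2);
  double hval = a1 + a2 + log_bvn(z1, z2, rho);
  for (int it = 0; it < 50; ++it) {
    double g1 = s1 * b1.du_dz - (z1 - rho * z2) / om;
    double g2 = s2 * b2.du_dz - (z2 - rho * z1) / om;
    h11 = ss1 * b1.du_dz * b1.du_dz + s1 * b1.d2u_dz2 - 1.0 / om;
    h22 = ss2 * b2.du_dz * b2.du_dz + s2 * b2.d2u_dz2 - 1.0 / om;
    h12 = rho / om;
    if (std::fabs(g1) < 1e-10 && std::fabs(g2) < 1e-10) break;
    // ensure negative definiteness before solving
    double m11 = h11, m22 = h22, det = m11 * m22 - h12 * h12;
    double lam = 1e-3 * (std::fabs(m11) + std::fabs(m22) + 1.0);
    while (!(m11 < 0.0 && det > 0.0)) {
      m11 -= lam; m22 -= lam;
      det = m11 * m22 - h12 * h12;
      lam *= 10.0;
    }
    double d1 = -(m22 * g1 - h12 * g2) / det;
    double d2 = -(-h12 * g1 + m11 * g2) / det;
    double nrm = std::sqrt(d1 * d1 + d2 * d2);
    if (nrm > 3.0) { d1 *= 3.0 / nrm; d2 *= 3.0 / nrm; }
    double step = 1.0;
    for (int half = 0; half < 30; ++half) {
      double t1 = z1 + step * d1, t2 = z2 + step * d2;
      BridgeZ c1 = bridge_at(t1, phi1, true, false);
      BridgeZ c2 = bridge_at(t2, phi2, true, false);
      double na1, ns1, nss1, na2, ns2, nss2;
      clust_eval(y1, e11, e12, r0, r1, c1.u, &na1, &ns1, &nss1);
      clust_eval(y2, e21, e22, r0, r1, c2.u, &na2, &ns2, &nss2);
      double nh = na1 + na2 + log_bvn(t1, t2, rho);
      if (nh >= hval - 1e-12 || step < 1e-6) {
        z1 = t1; z2 = t2; hval = nh;
        b1 = c1; b2 = c2;
        a1 = na1; s1 = ns1; ss1 = nss1;
        a2 = na2; s2 = ns2; ss2 = nss2;
        break;
      }
      step *= 0.5;
    }
  }
  *zh1 = z1; *zh2 = z2;
  *h11o = h11; *h12o = h12; *h22o = h22;
}

// [[Rcpp::export]]
List agq_joint_cpp(IntegerVector cl_off,
                   IntegerVector y1, NumericMatrix X1,
                   NumericVector om, NumericMatrix al,
                   IntegerVector y2, NumericMatrix X2,
                   NumericVector th, NumericMatrix be,
                   double phi1, double phi2, double rho,
                   NumericVector gh_t, NumericVector gh_w,
                   bool adaptive, bool want_grad,
                   NumericMatrix fixed_adapt) {
  int ncl = cl_off.size() - 1;
  int n = y1.size();
  int p1 = X1.ncol(), p2 = X2.ncol();
  int m = gh_t.size(), m2 = m * m;

  std::vector<double> e11, e12, e21, e22;
  fill_eta(X1, om, al, e11, e12);
  fill_eta(X2, th, be, e21, e22);

  std::vector<double> lw(m);
  for (int q = 0; q < m; ++q) lw[q] = std::log(gh_w[q]);

  int nmax = 0;
  for (int i = 0; i < ncl; ++i) nmax = std::max(nmax, cl_off[i + 1] - cl_off[i]);

  // node-level buffers (reused across clusters)
  std::vector<double> a1v(m), su1(m), dphi1v(m), z1v(m);
  std::vector<double> a2v(m2), su2(m2), dphi2v(m2), z2v(m2), gq(m2), Pq(m2);
  std::vector<double> P1a, P1b, P2a, P2b;
  if (want_grad) {
    P1a.resize((size_t)nmax * m); P1b.resize((size_t)nmax * m);
    P2a.resize((size_t)nmax * m2); P2b.resize((size_t)nmax * m2);
  }

  int ngrad = 2 + 2 * p1 + 2 + 2 * p2 + 3;
  NumericVector grad(ngrad);
  NumericVector llc(ncl);
  NumericMatrix adapt_out(ncl, 5);
  bool use_fixed = (fixed_adapt.nrow() == ncl && fixed_adapt.ncol() == 5);
  double ll = 0.0;

  const int* py1 = INTEGER(y1); const int* py2 = INTEGER(y2);

  for (int i = 0; i < ncl; ++i) {
    int r0 = cl_off[i], r1 = cl_off[i + 1];
    int ni = r1 - r0;
    double zh1 = 0.0, zh2 = 0.0, L11 = 1.0, L21 = 0.0, L22 = 1.0;
    if (use_fixed) {
      zh1 = fixed_adapt(i, 0); zh2 = fixed_adapt(i, 1);
      L11 = fixed_adapt(i, 2); L21 = fixed_adapt(i, 3); L22 = fixed_adapt(i, 4);
    } else if (adaptive) {
      double h11, h12, h22;
      find_mode2(py1, e11.data(), e12.data(), py2, e21.data(), e22.data(),
                 r0, r1, phi1, phi2, rho, &zh1, &zh2, &h11, &h12, &h22);
      // Sigma = (-H)^{-1}, L its lower Cholesky factor
      double m11 = -h11, m12 = -h12, m22 = -h22;
      double det = m11 * m22 - m12 * m12;
      if (!(det > 0.0 && m11 > 0.0)) { m11 += 1.0; m22 += 1.0; det = m11 * m22 - m12 * m12; }
      double s11 = m22 / det, s12 = -m12 / det, s22 = m11 / det;
      L11 = std::sqrt(s11);
      L21 = s12 / L11;
      double r2 = s22 - L21 * L21;
      L22 = std::sqrt(r2 > 1e-12 ? r2 : 1e-12);
    }
    adapt_out(i, 0) = zh1; adapt_out(i, 1) = zh2;
    adapt_out(i, 2) = L11; adapt_out(i, 3) = L21; adapt_out(i, 4) = L22;

    // outcome 1 at the m distinct z1 nodes
    for (int q1 = 0; q1 < m; ++q1) {
      double z1 = zh1 + L11 * gh_t[q1];
      z1v[q1] = z1;
      BridgeZ b = bridge_at(z1, phi1, false, want_grad);
      dphi1v[q1] = b.du_dphi;
      if (want_grad)
        clust_eval_store(py1, e11.data(), e12.data(), r0, r1, b.u,
                         &a1v[q1], &su1[q1], &P1a[(size_t)q1 * ni], &P1b[(size_t)q1 * ni]);
      else {
        double s, ss;
        clust_eval(py1, e11.data(), e12.data(), r0, r1, b.u, &a1v[q1], &s, &ss);
      }
    }

    // outcome 2 at the m^2 (z1, z2) nodes
    for (int q1 = 0; q1 < m; ++q1) {
      for (int q2 = 0; q2 < m; ++q2) {
        int q = q1 * m + q2;
        double z2 = zh2 + L21 * gh_t[q1] + L22 * gh_t[q2];
        z2v[q] = z2;
        BridgeZ b = bridge_at(z2, phi2, false, want_grad);
        dphi2v[q] = b.du_dphi;
        if (want_grad)
          clust_eval_store(py2, e21.data(), e22.data(), r0, r1, b.u,
                           &a2v[q], &su2[q], &P2a[(size_t)q * ni], &P2b[(size_t)q * ni]);
        else {
          double s, ss;
          clust_eval(py2, e21.data(), e22.data(), r0, r1, b.u, &a2v[q], &s, &ss);
        }
        double tt = gh_t[q1] * gh_t[q1] + gh_t[q2] * gh_t[q2];
        gq[q] = lw[q1] + lw[q2] + a1v[q1] + a2v[q] +
                log_bvn(z1v[q1], z2, rho) + 0.5 * tt + LOG2PI;
      }
    }

    double mxg = gq[0];
    for (int q = 1; q < m2; ++q) if (gq[q] > mxg) mxg = gq[q];
    double sme = 0.0;
    for (int q = 0; q < m2; ++q) { Pq[q] = std::exp(gq[q] - mxg); sme += Pq[q]; }
    double Li = std::log(L11) + std::log(L22) + mxg + std::log(sme);
    llc[i] = Li;
    ll += Li;

    if (!want_grad) continue;

    for (int q = 0; q < m2; ++q) Pq[q] /= sme;

    // outcome-1 node weights collapsed over q2
    std::vector<double> W1(m, 0.0);
    for (int q1 = 0; q1 < m; ++q1)
      for (int q2 = 0; q2 < m; ++q2) W1[q1] += Pq[q1 * m + q2];

    // thresholds / slopes, outcome 1
    for (int r = r0; r < r1; ++r) {
      double pbar1 = 0.0, pbar2 = 0.0;
      for (int q1 = 0; q1 < m; ++q1) {
        pbar1 += W1[q1] * P1a[(size_t)q1 * ni + (r - r0)];
        pbar2 += W1[q1] * P1b[(size_t)q1 * ni + (r - r0)];
      }
      int yi = py1[r];
      double r1c = (yi == 1 ? 1.0 : 0.0) - pbar1;
      double r2c = (yi == 2 ? 1.0 : 0.0) - pbar2;
      grad[0] += r1c; grad[1] += r2c;
      for (int j = 0; j < p1; ++j) {
        grad[2 + j] += X1(r, j) * r1c;
        grad[2 + p1 + j] += X1(r, j) * r2c;
      }
    }
    // thresholds / slopes, outcome 2
    int off2 = 2 + 2 * p1;
    for (int r = r0; r < r1; ++r) {
      double pbar1 = 0.0, pbar2 = 0.0;
      for (int q = 0; q < m2; ++q) {
        pbar1 += Pq[q] * P2a[(size_t)q * ni + (r - r0)];
        pbar2 += Pq[q] * P2b[(size_t)q * ni + (r - r0)];
      }
      int yi = py2[r];
      double r1c = (yi == 1 ? 1.0 : 0.0) - pbar1;
      double r2c = (yi == 2 ? 1.0 : 0.0) - pbar2;
      grad[off2] += r1c; grad[off2 + 1] += r2c;
      for (int j = 0; j < p2; ++j) {
        grad[off2 + 2 + j] += X2(r, j) * r1c;
        grad[off2 + 2 + p2 + j] += X2(r, j) * r2c;
      }
    }
    // phi1, phi2, rho
    int offd = 2 + 2 * p1 + 2 + 2 * p2;
    for (int q1 = 0; q1 < m; ++q1)
      grad[offd] += W1[q1] * su1[q1] * dphi1v[q1];
    for (int q = 0; q < m2; ++q)
      grad[offd + 1] += Pq[q] * su2[q] * dphi2v[q];
    for (int q1 = 0; q1 < m; ++q1)
      for (int q2 = 0; q2 < m; ++q2) {
        int q = q1 * m + q2;
        grad[offd + 2] += Pq[q] * dlog_bvn_drho(z1v[q1], z2v[q], rho);
      }
  }

  List out = List::create(_["loglik"] = ll, _["by_cluster"] = llc,
                          _["adapt"] = adapt_out);
  if (want_grad) out["grad"] = grad;
  return out;
}

// 1-D Newton for h(z) = a(z) + log dnorm(z)
static void find_mode1(const int* y, const double* e1, const double* e2,
                       int r0, int r1, double phi,
                       double* zh, double* h2o) {
  double z = 0.0;
  double a, s, ss;
  BridgeZ b = bridge_at(z, phi, true, false);
  clust_eval(y, e1, e2, r0, r1, b.u, &a, &s, &ss);
  double hval = a - 0.5 * z * z;
  double h2 = -1.0;
  for (int it = 0; it < 50; ++it) {
    double g = s * b.du_dz - z;
    h2 = ss * b.du_dz * b.du_dz + s * b.d2u_dz2 - 1.0;
    if (std::fabs(g) < 1e-10) break;
    double m2 = h2 < -1e-8 ? h2 : -1.0;
    double d = -g / m2;
    if (std::fabs(d) > 3.0) d = d > 0 ? 3.0 : -3.0;
    double step = 1.0;
    for (int half = 0; half < 30; ++half) {
      double t = z + step * d;
      BridgeZ c = bridge_at(t, phi, true, false);
      double na, ns, nss;
      clust_eval(y, e1, e2, r0, r1, c.u, &na, &ns, &nss);
      double nh = na - 0.5 * t * t;
      if (nh >= hval - 1e-12 || step < 1e-6) {
        z = t; hval = nh; b = c; a = na; s = ns; ss = nss;
        break;
      }
      step *= 0.5;
    }
  }
  *zh = z; *h2o = h2;
}

// [[Rcpp::export]]
List agq_uni_cpp(IntegerVector cl_off,
                 IntegerVector y, NumericMatrix X,
                 NumericVector om, NumericMatrix al, double phi,
                 NumericVector gh_t, NumericVector gh_w,
                 bool adaptive, bool want_grad,
                 NumericMatrix fixed_adapt) {
  int ncl = cl_off.size() - 1;
  int p = X.ncol();
  int m = gh_t.size();

  std::vector<double> e1, e2;
  fill_eta(X, om, al, e1, e2);
  std::vector<double> lw(m);
  for (int q = 0; q < m; ++q) lw[q] = std::log(gh_w[q]);

  int nmax = 0;
  for (int i = 0; i < ncl; ++i) nmax = std::max(nmax, cl_off[i + 1] - cl_off[i]);

  std::vector<double> av(m), suv(m), dphiv(m), gq(m), Pq(m);
  std::vector<double> Pa, Pb;
  if (want_grad) { Pa.resize((size_t)nmax * m); Pb.resize((size_t)nmax * m); }

  int ngrad = 2 + 2 * p + 1;
  NumericVector grad(ngrad);
  NumericVector llc(ncl);
  NumericMatrix adapt_out(ncl, 2);
  bool use_fixed = (fixed_adapt.nrow() == ncl && fixed_adapt.ncol() == 2);
  double ll = 0.0;
  const int* py = INTEGER(y);

  for (int i = 0; i < ncl; ++i) {
    int r0 = cl_off[i], r1 = cl_off[i + 1];
    int ni = r1 - r0;
    double zh = 0.0, L = 1.0;
    if (use_fixed) {
      zh = fixed_adapt(i, 0); L = fixed_adapt(i, 1);
    } else if (adaptive) {
      double h2;
      find_mode1(py, e1.data(), e2.data(), r0, r1, phi, &zh, &h2);
      double mm = -h2;
      if (!(mm > 0.0)) mm = 1.0;
      L = std::sqrt(1.0 / mm);
    }
    adapt_out(i, 0) = zh; adapt_out(i, 1) = L;
    for (int q = 0; q < m; ++q) {
      double z = zh + L * gh_t[q];
      BridgeZ b = bridge_at(z, phi, false, want_grad);
      dphiv[q] = b.du_dphi;
      if (want_grad)
        clust_eval_store(py, e1.data(), e2.data(), r0, r1, b.u,
                         &av[q], &suv[q], &Pa[(size_t)q * ni], &Pb[(size_t)q * ni]);
      else {
        double s, ss;
        clust_eval(py, e1.data(), e2.data(), r0, r1, b.u, &av[q], &s, &ss);
      }
      // log dnorm(z) + t^2/2 + log sqrt(2*pi) leaves -(z^2 - t^2)/2
      gq[q] = lw[q] + av[q] - 0.5 * z * z + 0.5 * gh_t[q] * gh_t[q];
    }
    double mxg = gq[0];
    for (int q = 1; q < m; ++q) if (gq[q] > mxg) mxg = gq[q];
    double sme = 0.0;
    for (int q = 0; q < m; ++q) { Pq[q] = std::exp(gq[q] - mxg); sme += Pq[q]; }
    double Li = std::log(L) + mxg + std::log(sme);
    llc[i] = Li;
    ll += Li;

    if (!want_grad) continue;
    for (int q = 0; q < m; ++q) Pq[q] /= sme;

    for (int r = r0; r < r1; ++r) {
      double pbar1 = 0.0, pbar2 = 0.0;
      for (int q = 0; q < m; ++q) {
        pbar1 += Pq[q] * Pa[(size_t)q * ni + (r - r0)];
        pbar2 += Pq[q] * Pb[(size_t)q * ni + (r - r0)];
      }
      int yi = py[r];
      double r1c = (yi == 1 ? 1.0 : 0.0) - pbar1;
      double r2c = (yi == 2 ? 1.0 : 0.0) - pbar2;
      grad[0] += r1c; grad[1] += r2c;
      for (int j = 0; j < p; ++j) {
        grad[2 + j] += X(r, j) * r1c;
        grad[2 + p + j] += X(r, j) * r2c;
      }
    }
    for (int q = 0; q < m; ++q)
      grad[2 + 2 * p] += Pq[q] * suv[q] * dphiv[q];
  }

  List out = List::create(_["loglik"] = ll, _["by_cluster"] = llc,
                          _["adapt"] = adapt_out);
  if (want_grad) out["grad"] = grad;
  return out;
}
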