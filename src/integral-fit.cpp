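// Laplace-approximated marginal likelihood of the integral titer model.
//
// Per donor the model for the k-th titer difference from the first
// measurement is
//   C_k = D t_k + 2B * sum_j A_kj * s(L, T0_j) + eps_k,
// where A_kj is the logistic time envelope of booster j at observation k
// (precomputed in R; 0 for boosters after the observation), T0_j the
// (current, clamped) starting titer of booster j, s(L,T0) = 1/(1+exp(L*T0))
// the saturation term, eps ~ N(0, sigma^2) and (D, L) bivariate normal
// across donors.  The inner mode is found by profiling D (quadratic) and a
// grid + golden-section search over L; the 2x2 Hessian at the mode is
// analytic, so the Laplace term is exact up to the mode-finding tolerance.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct DonorData {
  NumericVector t, C, T0;
  NumericMatrix A;
  int n, m;
  double St2;  // sum t^2
};

struct Prior {
  double muD, muL;
  double p11, p12, p22;  // precision of (D, L)
  double logdet;         // log det of the covariance
};

// residual profile for fixed L: fills G_k, returns profiled D
double profile_D(const DonorData &d, double B, double sig2, const Prior &pr,
                 double L, std::vector<double> &s, std::vector<double> &G) {
  for (int j = 0; j < d.m; ++j) s[j] = 1.0 / (1.0 + std::exp(L * d.T0[j]));
  double StCG = 0.0;
  for (int k = 0; k < d.n; ++k) {
    double g = 0.0;
    for (int j = 0; j < d.m; ++j) g += d.A(k, j) * s[j];
    G[k] = 2.0 * B * g;
    StCG += d.t[k] * (d.C[k] - G[k]);
  }
  double num = StCG / sig2 + pr.p11 * pr.muD - pr.p12 * (L - pr.muL);
  double den = d.St2 / sig2 + pr.p11;
  return num / den;
}

// joint penalized negative log density g(D, L) (up to no constants dropped)
double g_value(const DonorData &d, double B, double sig2, const Prior &pr,
               double D, double L, const std::vector<double> &G) {
  double rss = 0.0;
  for (int k = 0; k < d.n; ++k) {
    double r = d.C[k] - D * d.t[k] - G[k];
    rss += r * r;
  }
  double dD = D - pr.muD, dL = L - pr.muL;
  double quad = pr.p11 * dD * dD + 2.0 * pr.p12 * dD * dL + pr.p22 * dL * dL;
  return 0.5 * rss / sig2 + 0.5 * d.n * std::log(2.0 * M_PI * sig2) +
         0.5 * quad + std::log(2.0 * M_PI) + 0.5 * pr.logdet;
}

// h(L) = g(Dhat(L), L)
double h_value(const DonorData &d, double B, double sig2, const Prior &pr,
               double L, std::vector<double> &s, std::vector<double> &G,
               double &Dhat) {
  Dhat = profile_D(d, B, sig2, pr, L, s, G);
  return g_value(d, B, sig2, pr, Dhat, L, G);
}

}  // namespace

// [[Rcpp::export(name = ".integral_nll_cpp")]]
List integral_nll_cpp(List donors, double B, double muD, double sdD,
                      double muL, double sdL, double rho, double sigma,
                      bool return_modes) {
  const int nd = donors.size();
  const double sig2 = sigma * sigma;

  Prior pr;
  pr.muD = muD; pr.muL = muL;
  double detS = sdD * sdD * sdL * sdL * (1.0 - rho * rho);
  if (detS <= 0) stop("degenerate random-effects covariance");
  pr.logdet = std::log(detS);
  pr.p11 = (sdL * sdL) / detS;
  pr.p22 = (sdD * sdD) / detS;
  pr.p12 = -(rho * sdD * sdL) / detS;

  double nll = 0.0;
  NumericVector Dmode(return_modes ? nd : 0), Lmode(return_modes ? nd : 0);

  for (int i = 0; i < nd; ++i) {
    List di = donors[i];
    DonorData d;
    d.t = di["t"]; d.C = di["C"]; d.T0 = di["T0"];
    d.A = as<NumericMatrix>(di["A"]);
    d.n = d.t.size(); d.m = d.T0.size();
    if (d.n == 0) {  // no differences: donor contributes nothing to the marginal
      if (return_modes) { Dmode[i] = muD; Lmode[i] = muL; }
      continue;
    }
    d.St2 = 0.0;
    for (int k = 0; k < d.n; ++k) d.St2 += d.t[k] * d.t[k];

    std::vector<double> s(d.m), G(d.n);
    double Dhat = muD;

    // bracket for L around the prior mean, expanded while the mode sits on
    // the boundary
    double half = std::max(10.0 * sdL, 1.0);
    double lo = muL - half, hi = muL + half;
    double bestL = muL;
    for (int expand = 0; expand < 8; ++expand) {
      const int ngrid = 25;
      double bestval = R_PosInf;
      int besti = 0;
      for (int gidx = 0; gidx <= ngrid; ++gidx) {
        double L = lo + (hi - lo) * gidx / ngrid;
        double v = h_value(d, B, sig2, pr, L, s, G, Dhat);
        if (v < bestval) { bestval = v; besti = gidx; }
      }
      bestL = lo + (hi - lo) * besti / ngrid;
      double w = hi - lo;
      if (besti == 0)     { hi = lo + w / ngrid; lo -= 2.0 * w; continue; }
      if (besti == ngrid) { lo = hi - w / ngrid; hi += 2.0 * w; continue; }
      // golden-section in the two neighbouring cells
      double a = lo + (hi - lo) * (besti - 1) / ngrid;
      double b = lo + (hi - lo) * (besti + 1) / ngrid;
      const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
      double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
      double f1 = h_value(d, B, sig2, pr, x1, s, G, Dhat);
      double f2 = h_value(d, B, sig2, pr, x2, s, G, Dhat);
      for (int it = 0; it < 80 && (b - a) > 1e-10; ++it) {
        if (f1 < f2) { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a);
                       f1 = h_value(d, B, sig2, pr, x1, s, G, Dhat); }
        else         { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a);
                       f2 = h_value(d, B, sig2, pr, x2, s, G, Dhat); }
      }
      bestL = 0.5 * (a + b);
      break;
    }

    double gmin = h_value(d, B, sig2, pr, bestL, s, G, Dhat);

    // analytic Hessian of g at the mode
    double gDD = d.St2 / sig2 + pr.p11;
    double gDL = pr.p12, gLL = pr.p22;
    for (int k = 0; k < d.n; ++k) {
      double Gp = 0.0, Gpp = 0.0;
      for (int j = 0; j < d.m; ++j) {
        double sj = s[j], T = d.T0[j];
        double sp = -T * sj * (1.0 - sj);
        Gp += d.A(k, j) * sp;
        Gpp += d.A(k, j) * (T * T * sj * (1.0 - sj) * (1.0 - 2.0 * sj));
      }
      Gp *= 2.0 * B; Gpp *= 2.0 * B;
      double r = d.C[k] - Dhat * d.t[k] - G[k];
      gDL += d.t[k] * Gp / sig2;
      gLL += (Gp * Gp - r * Gpp) / sig2;
    }
    double detH = gDD * gLL - gDL * gDL;
    if (detH < 1e-12) detH = 1e-12;  // safeguarded: saddle-free in practice

    nll += gmin + 0.5 * std::log(detH) - std::log(2.0 * M_PI);
    if (return_modes) { Dmode[i] = Dhat; Lmode[i] = bestL; }
  }

  if (return_modes)
    return List::create(_["nll"] = nll, _["D"] = Dmode, _["L"] = Lmode);
  return List::create(_["nll"] = nll);
}
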