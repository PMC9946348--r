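// Core numerics for the dynamic multispecies occupancy model.
//
// Data layout (all arrays column-major, as passed from R):
//   y, mask : integer, dim S x J x K x 2      (species, site, visit, era)
//   Xp      : double,  dim J x K x 2 x Pp     (per-visit detection design)
//   Xpsi    : double,  dim J x Ppsi           (initial-occupancy design)
//   Xphi    : double,  dim J x Pphi           (persistence design)
//   Xgam    : double,  dim J x Pg             (colonization design)
//   coefs   : double,  S x (Pp+Ppsi+Pphi+Pg)  species coefficients, families
//             stored contiguously in the order p, psi1, phi, gamma.
//
// The likelihood marginalizes the latent incidence pair (z1, z2) by exact
// enumeration of the four paths; everything is kept in log space with
// log-sum-exp so that saturated linear predictors do not underflow.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(plogis(x)), stable for large |x|
static inline double log_plogis(double x) {
  return (x < 0.0) ? x - log1p(exp(x)) : -log1p(exp(-x));
}

struct MsomData {
  const int *y, *mask;
  int S, J, K;
  const double *Xp, *Xpsi, *Xphi, *Xgam;
  int Pp, Ppsi, Pphi, Pg;
};

static MsomData make_data(const IntegerVector& y, const IntegerVector& mask,
                          const IntegerVector& dim, const NumericVector& Xp,
                          const NumericVector& Xpsi, const NumericVector& Xphi,
                          const NumericVector& Xgam, const IntegerVector& nterms) {
  MsomData D;
  D.y = INTEGER(y); D.mask = INTEGER(mask);
  D.S = dim[0]; D.J = dim[1]; D.K = dim[2];
  D.Xp = REAL(Xp); D.Xpsi = REAL(Xpsi); D.Xphi = REAL(Xphi); D.Xgam = REAL(Xgam);
  D.Pp = nterms[0]; D.Ppsi = nterms[1]; D.Pphi = nterms[2]; D.Pg = nterms[3];
  return D;
}

// log-probabilities of the four (z1, z2) paths for one species x site,
// each already multiplied by the detection likelihood of that path.
// out order: (1,1), (1,0), (0,1), (0,0)
static void path_logs(const MsomData& D, int s, int j, const double* a,
                      const double* b, const double* d, const double* e,
                      double out[4]) {
  double lldet[2];
  bool anydet[2];
  for (int t = 0; t < 2; ++t) {
    double acc = 0.0;
    bool any = false;
    for (int k = 0; k < D.K; ++k) {
      int yi = s + D.S * (j + D.J * (k + D.K * t));
      if (!D.mask[yi]) continue;
      double lp = 0.0;
      for (int p = 0; p < D.Pp; ++p)
        lp += D.Xp[j + D.J * (k + D.K * (t + 2 * p))] * a[p];
      if (D.y[yi]) { acc += log_plogis(lp); any = true; }
      else           acc += log_plogis(-lp);
    }
    lldet[t] = acc;
    anydet[t] = any;
  }
  double lpsi = 0.0, lphi = 0.0, lgam = 0.0;
  for (int p = 0; p < D.Ppsi; ++p) lpsi += D.Xpsi[j + D.J * p] * b[p];
  for (int p = 0; p < D.Pphi; ++p) lphi += D.Xphi[j + D.J * p] * d[p];
  for (int p = 0; p < D.Pg; ++p)   lgam += D.Xgam[j + D.J * p] * e[p];

  out[0] = log_plogis(lpsi) + log_plogis(lphi) + lldet[0] + lldet[1];
  out[1] = log_plogis(lpsi) + log_plogis(-lphi) + lldet[0] +
           (anydet[1] ? NEG_INF : 0.0);
  out[2] = log_plogis(-lpsi) + log_plogis(lgam) +
           (anydet[0] ? NEG_INF : 0.0) + lldet[1];
  out[3] = log_plogis(-lpsi) + log_plogis(-lgam) +
           (anydet[0] ? NEG_INF : 0.0) + (anydet[1] ? NEG_INF : 0.0);
}

static inline double lse4(const double lp[4]) {
  double m = lp[0];
  for (int i = 1; i < 4; ++i) if (lp[i] > m) m = lp[i];
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int i = 0; i < 4; ++i) s += exp(lp[i] - m);
  return m + log(s);
}

static double unit_ll(const MsomData& D, int s, int j, const double* a,
                      const double* b, const double* d, const double* e) {
  double lp[4];
  path_logs(D, s, j, a, b, d, e, lp);
  return lse4(lp);
}

static double species_ll(const MsomData& D, int s, const double* row) {
  const double* a = row;
  const double* b = a + D.Pp;
  const double* d = b + D.Ppsi;
  const double* e = d + D.Pphi;
  double acc = 0.0;
  for (int j = 0; j < D.J; ++j) acc += unit_ll(D, s, j, a, b, d, e);
  return acc;
}

// [[Rcpp::export]]
NumericMatrix msomLoglikMatrix(IntegerVector y, IntegerVector mask,
                               IntegerVector dim, NumericVector Xp,
                               NumericVector Xpsi, NumericVector Xphi,
                               NumericVector Xgam, NumericMatrix coefs,
                               IntegerVector nterms) {
  MsomData D = make_data(y, mask, dim, Xp, Xpsi, Xphi, Xgam, nterms);
  int Ptot = D.Pp + D.Ppsi + D.Pphi + D.Pg;
  NumericMatrix out(D.S, D.J);
  std::vector<double> row(Ptot);
  for (int s = 0; s < D.S; ++s) {
    for (int p = 0; p < Ptot; ++p) row[p] = coefs(s, p);
    const double* a = row.data();
    const double* b = a + D.Pp;
    const double* d = b + D.Ppsi;
    const double* e = d + D.Pphi;
    for (int j = 0; j < D.J; ++j) out(s, j) = unit_ll(D, s, j, a, b, d, e);
  }
  return out;
}

// Joint posterior probabilities of the four (z1, z2) paths given y and the
// parameter state, one row of 4 per species x site (order 11, 10, 01, 00).
// [[Rcpp::export]]
NumericMatrix msomZPathProbs(IntegerVector y, IntegerVector mask,
                             IntegerVector dim, NumericVector Xp,
                             NumericVector Xpsi, NumericVector Xphi,
                             NumericVector Xgam, NumericMatrix coefs,
                             IntegerVector nterms) {
  MsomData D = make_data(y, mask, dim, Xp, Xpsi, Xphi, Xgam, nterms);
  int Ptot = D.Pp + D.Ppsi + D.Pphi + D.Pg;
  NumericMatrix out(D.S * D.J, 4);
  std::vector<double> row(Ptot);
  double lp[4];
  for (int s = 0; s < D.S; ++s) {
    for (int p = 0; p < Ptot; ++p) row[p] = coefs(s, p);
    const double* a = row.data();
    const double* b = a + D.Pp;
    const double* d = b + D.Ppsi;
    const double* e = d + D.Pphi;
    for (int j = 0; j < D.J; ++j) {
      path_logs(D, s, j, a, b, d, e, lp);
      double tot = lse4(lp);
      for (int q = 0; q < 4; ++q)
        out(s + D.S * j, q) = (lp[q] == NEG_INF) ? 0.0 : exp(lp[q] - tot);
    }
  }
  return out;
}

// Draw (z1, z2) from the exact conditional given y and the parameter state.
// Returns integer array S x J x 2. Uses R's RNG.
// [[Rcpp::export]]
IntegerVector msomDrawZ(IntegerVector y, IntegerVector mask, IntegerVector dim,
                        NumericVector Xp, NumericVector Xpsi,
                        NumericVector Xphi, NumericVector Xgam,
                        NumericMatrix coefs, IntegerVector nterms) {
  MsomData D = make_data(y, mask, dim, Xp, Xpsi, Xphi, Xgam, nterms);
  int Ptot = D.Pp + D.Ppsi + D.Pphi + D.Pg;
  IntegerVector out(D.S * D.J * 2);
  std::vector<double> row(Ptot);
  double lp[4];
  static const int Z1[4] = {1, 1, 0, 0};
  static const int Z2[4] = {1, 0, 1, 0};
  for (int s = 0; s < D.S; ++s) {
    for (int p = 0; p < Ptot; ++p) row[p] = coefs(s, p);
    const double* a = row.data();
    const double* b = a + D.Pp;
    const double* d = b + D.Ppsi;
    const double* e = d + D.Pphi;
    for (int j = 0; j < D.J; ++j) {
      path_logs(D, s, j, a, b, d, e, lp);
      double tot = lse4(lp);
      double u = unif_rand(), acc = 0.0;
      int pick = 3;
      for (int q = 0; q < 4; ++q) {
        acc += (lp[q] == NEG_INF) ? 0.0 : exp(lp[q] - tot);
        if (u <= acc) { pick = q; break; }
      }
      out[s + D.S * j] = Z1[pick];
      out[s + D.S * (j + D.J)] = Z2[pick];
    }
  }
  out.attr("dim") = IntegerVector::create(D.S, D.J, 2);
  return out;
}

static double total_ll(const MsomData& D, const NumericMatrix& coefs,
                       int Ptot) {
  std::vector<double> row(Ptot);
  double acc = 0.0;
  for (int s = 0; s < D.S; ++s) {
    for (int p = 0; p < Ptot; ++p) row[p] = coefs(s, p);
    acc += species_ll(D, s, row.data());
  }
  return acc;
}

// Interleaved non-centered (ancillarity-sufficiency) update of the community
// hyperparameters: per coordinate, a translation move (shift hypermean and
// every species coefficient together, holding the standardized residuals
// fixed) and a scaling move (rescale coefficient spread around the hypermean
// together with the hyper-SD). Both require the full-data likelihood and
// break the centered-parameterization funnel between hyper-SDs and species
// coefficients. coefs/hypermean/hypersd are modified IN PLACE; returns
// acceptance indicators (P x 2: mu move, sigma move).
// [[Rcpp::export]]
IntegerMatrix msomAsisUpdate(NumericMatrix coefs, NumericVector hypermean,
                             NumericVector hypersd, NumericVector stepMu,
                             NumericVector stepSig, LogicalVector freeP,
                             double s0, double hcScale, IntegerVector y,
                             IntegerVector mask, IntegerVector dim,
                             NumericVector Xp, NumericVector Xpsi,
                             NumericVector Xphi, NumericVector Xgam,
                             IntegerVector nterms) {
  MsomData D = make_data(y, mask, dim, Xp, Xpsi, Xphi, Xgam, nterms);
  int Ptot = D.Pp + D.Ppsi + D.Pphi + D.Pg;
  IntegerMatrix acc(Ptot, 2);
  std::vector<double> keep(D.S);
  double llcur = total_ll(D, coefs, Ptot);
  for (int c = 0; c < Ptot; ++c) {
    if (!freeP[c]) continue;
    // translation: mu' = mu + d, coef' = coef + d
    double d = stepMu[c] * norm_rand();
    for (int s = 0; s < D.S; ++s) {
      keep[s] = coefs(s, c);
      coefs(s, c) = keep[s] + d;
    }
    double muP = hypermean[c] + d;
    double llprop = total_ll(D, coefs, Ptot);
    double lr = llprop - llcur + R::dnorm(muP, 0.0, s0, 1) -
                R::dnorm(hypermean[c], 0.0, s0, 1);
    if (log(unif_rand()) < lr) {
      hypermean[c] = muP;
      llcur = llprop;
      acc(c, 0) = 1;
    } else {
      for (int s = 0; s < D.S; ++s) coefs(s, c) = keep[s];
    }
    // scaling: sig' = sig * e, coef' = mu + e (coef - mu)
    double e = exp(stepSig[c] * norm_rand());
    double sigP = hypersd[c] * e;
    for (int s = 0; s < D.S; ++s) {
      keep[s] = coefs(s, c);
      coefs(s, c) = hypermean[c] + e * (keep[s] - hypermean[c]);
    }
    double llprop2 = total_ll(D, coefs, Ptot);
    double lhc = (log(2.0) + R::dcauchy(sigP, 0.0, hcScale, 1)) -
                 (log(2.0) + R::dcauchy(hypersd[c], 0.0, hcScale, 1));
    double lr2 = llprop2 - llcur + lhc + log(sigP) - log(hypersd[c]);
    if (log(unif_rand()) < lr2) {
      hypersd[c] = sigP;
      llcur = llprop2;
      acc(c, 1) = 1;
    } else {
      for (int s = 0; s < D.S; ++s) coefs(s, c) = keep[s];
    }
  }
  return acc;
}

// One Metropolis-within-Gibbs sweep over species x coefficient-family blocks.
// coefs is modified IN PLACE. step is S x 4 proposal SDs; famFree flags which
// of the four families (p, psi1, phi, gamma) are sampled. Returns acceptance
// counts (S x 4). Species-coefficient priors are Normal(hypermean, hypersd).
// [[Rcpp::export]]
IntegerMatrix msomSweep(NumericMatrix coefs, NumericVector hypermean,
                        NumericVector hypersd, NumericMatrix step,
                        LogicalVector famFree, IntegerVector y,
                        IntegerVector mask, IntegerVector dim, NumericVector Xp,
                        NumericVector Xpsi, NumericVector Xphi,
                        NumericVector Xgam, IntegerVector nterms) {
  MsomData D = make_data(y, mask, dim, Xp, Xpsi, Xphi, Xgam, nterms);
  int nt[4] = {D.Pp, D.Ppsi, D.Pphi, D.Pg};
  int off[4] = {0, D.Pp, D.Pp + D.Ppsi, D.Pp + D.Ppsi + D.Pphi};
  int Ptot = off[3] + D.Pg;
  IntegerMatrix acc(D.S, 4);
  std::vector<double> row(Ptot), old(Ptot);
  for (int s = 0; s < D.S; ++s) {
    for (int p = 0; p < Ptot; ++p) row[p] = coefs(s, p);
    double llcur = species_ll(D, s, row.data());
    for (int f = 0; f < 4; ++f) {
      if (!famFree[f]) continue;
      double dprior = 0.0;
      for (int p = 0; p < nt[f]; ++p) {
        int c = off[f] + p;
        old[c] = row[c];
        double prop = old[c] + step(s, f) * norm_rand();
        row[c] = prop;
        dprior += R::dnorm(prop, hypermean[c], hypersd[c], 1) -
                  R::dnorm(old[c], hypermean[c], hypersd[c], 1);
      }
      double llprop = species_ll(D, s, row.data());
      if (log(unif_rand()) < llprop - llcur + dprior) {
        llcur = llprop;
        acc(s, f)++;
      } else {
        for (int p = 0; p < nt[f]; ++p) row[off[f] + p] = old[off[f] + p];
      }
    }
    for (int p = 0; p < Ptot; ++p) coefs(s, p) = row[p];
  }
  return acc;
}
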