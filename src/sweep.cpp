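// Compiled core of the per-iteration MCMC sweep: pseudo-group refresh,
// detection linear predictors and p*, reversible-jump group-count moves,
// latent-covariate resampling, and the truncated-normal probit Gibbs
// update. Parameter blocks (beta, rho, theta, process model) stay in R.
//
// The detection design is flattened: column j of the design equals a
// precomputed static multiplier (observer, species and other unit-level
// terms) times a product of dynamic factors referencing modeled slot
// covariates (numeric value, or a factor-level indicator).

#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------
// bivariate-normal upper-orthant probability P(X > h, Y > k), Genz (2004)

static const double GL6X[3] = {0.9324695142031522, 0.6612093864662647,
                               0.2386191860831970};
static const double GL6W[3] = {0.1713244923791705, 0.3607615730481384,
                               0.4679139345726904};
static const double GL12X[6] = {0.9815606342467191, 0.9041172563704750,
                                0.7699026741943050, 0.5873179542866171,
                                0.3678314989981802, 0.1252334085114692};
static const double GL12W[6] = {0.04717533638651177, 0.1069393259953183,
                                0.1600783285433464, 0.2031674267230659,
                                0.2334925365383547, 0.2491470458134029};
static const double GL20X[10] = {0.9931285991850949, 0.9639719272779138,
                                 0.9122344282513259, 0.8391169718222188,
                                 0.7463319064601508, 0.6360536807265150,
                                 0.5108670019508271, 0.3737060887154196,
                                 0.2277858511416451, 0.07652652113349733};
static const double GL20W[10] = {0.01761400713915212, 0.04060142980038694,
                                 0.06267204833410906, 0.08327674157670475,
                                 0.1019301198172404, 0.1181945319615184,
                                 0.1316886384491766, 0.1420961093183821,
                                 0.1491729864726037, 0.1527533871307259};

static double bvnu(double h, double k, double r) {
  double ar = std::fabs(r);
  double out = 0.0;
  if (ar < 0.925) {
    const double *gx, *gw;
    int ng;
    if (ar < 0.3) { gx = GL6X; gw = GL6W; ng = 3; }
    else if (ar < 0.75) { gx = GL12X; gw = GL12W; ng = 6; }
    else { gx = GL20X; gw = GL20W; ng = 10; }
    double hs = (h * h + k * k) / 2.0, hk = h * k;
    double asr = std::asin(r), bvn = 0.0;
    for (int i = 0; i < ng; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * gx[i] + 1.0) / 2.0);
        bvn += gw[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    out = bvn * asr / (4.0 * M_PI) +
      R::pnorm(-h, 0, 1, 1, 0) * R::pnorm(-k, 0, 1, 1, 0);
  } else {
    double kk = (r < 0) ? -k : k;
    double hk = h * kk;
    double bvn = 0.0;
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - kk) * (h - kk);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0) {
        bvn = a * std::exp(asr) *
          (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
           c * d * as * as / 5.0);
      }
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        double sp = std::sqrt(2.0 * M_PI) * R::pnorm(-b / a, 0, 1, 1, 0);
        bvn -= std::exp(-hk / 2.0) * sp * b *
          (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      double a2 = a / 2.0;
      for (int i = 0; i < 10; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double x2 = a2 * (is * GL20X[i] + 1.0);
          double xs = x2 * x2;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            double sp = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a2 * GL20W[i] * std::exp(asr2) * (ep - sp);
          }
        }
      }
      bvn = -bvn / (2.0 * M_PI);
    }
    if (r > 0) {
      bvn += R::pnorm(-std::max(h, kk), 0, 1, 1, 0);
    } else {
      bvn = -bvn;
      double extra = R::pnorm(kk, 0, 1, 1, 0) - R::pnorm(h, 0, 1, 1, 0);
      if (extra > 0) bvn += extra;
    }
    out = bvn;
  }
  if (out < 0.0) out = 0.0;
  if (out > 1.0) out = 1.0;
  return out;
}

// [[Rcpp::export(name = ".cpp_bvnu")]]
NumericVector cpp_bvnu(NumericVector h, NumericVector k, NumericVector r) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvnu(h[i], k[i], r[i]);
  return out;
}

// ---------------------------------------------------------------------
// helpers

// one-sided truncated normal: positive side if pos, else (-inf, 0].
// Rejection sampling when the truncation region holds decent mass (cheap);
// tail-safe inverse-CDF otherwise.
static double rtnorm0(double m, double s, bool pos) {
  double zb = (0.0 - m) / s;                 // boundary on the z scale
  bool easy = pos ? (zb < 1.0) : (zb > -1.0); // region mass >= ~0.16
  if (easy) {
    for (int i = 0; i < 16; i++) {
      double x = m + s * norm_rand();
      if (pos ? (x > 0.0) : (x <= 0.0)) return x;
    }
  }
  if (pos) {
    double ph = R::pnorm(0.0, m, s, 0, 0);   // P(X > 0)
    double x = R::qnorm(unif_rand() * ph, m, s, 0, 0);
    return x > 0.0 ? x : 1e-300;
  }
  double pl = R::pnorm(0.0, m, s, 1, 0);     // P(X <= 0)
  double x = R::qnorm(unif_rand() * pl, m, s, 1, 0);
  return x <= 0.0 ? x : 0.0;
}

// zero-truncated Poisson by sequential inversion (fast for moderate rates);
// falls back to R's quantile function for large rates
static double rztpois1(double lam) {
  if (lam > 30.0) {
    double f0 = std::exp(-lam);
    double u = f0 + unif_rand() * (1.0 - f0);
    double z = R::qpois(u, lam, 1, 0);
    return z < 1.0 ? 1.0 : z;
  }
  double f0 = std::exp(-lam);
  double u = f0 + unif_rand() * (1.0 - f0);
  double p = f0, cum = f0;
  for (int k = 1; k < 400; k++) {
    p *= lam / k;
    cum += p;
    if (u <= cum) return (double)k;
  }
  return 400.0;
}

// covariate model families (codes shared with R side)
enum Family { FAM_UNIFORM = 0, FAM_CATEGORICAL = 1, FAM_POISSON = 2,
              FAM_POISSON_ZT = 3, FAM_POISSON_OD = 4, FAM_POISSON_ZT_OD = 5 };

struct CovModel {
  int family;
  NumericMatrix par;   // n_sp rows; columns depend on family
};

static void cov_sample(const CovModel &cm, int sp, double &z, double &eps) {
  eps = 0.0;
  switch (cm.family) {
  case FAM_UNIFORM:
    z = cm.par(sp, 0) + unif_rand() * (cm.par(sp, 1) - cm.par(sp, 0));
    break;
  case FAM_CATEGORICAL: {
    double u = unif_rand(), acc = 0.0;
    int K = cm.par.ncol();
    z = K;
    for (int l = 0; l < K; l++) {
      acc += cm.par(sp, l);
      if (u <= acc) { z = l + 1; break; }
    }
    break;
  }
  default: {
    double sigma = (cm.family == FAM_POISSON_OD ||
                    cm.family == FAM_POISSON_ZT_OD) ? cm.par(sp, 1) : 0.0;
    if (sigma > 0.0) eps = norm_rand() * sigma;
    double lam = std::exp(cm.par(sp, 0) + eps);
    if (cm.family == FAM_POISSON_ZT || cm.family == FAM_POISSON_ZT_OD) {
      z = rztpois1(lam);
    } else {
      z = R::rpois(lam);
    }
  }
  }
}

// ---------------------------------------------------------------------
// the sweep

// Arguments, in order: per-slot two-observer flags; per-unit slot offsets,
// observed counts, slot bounds and sampled flags; 0-based species index per
// slot; static design parts S1/S2 and per-column dynamic covariate ids and
// kinds; per-covariate affected columns and in-design flags; distance
// covariate id (-1 if absent) and bin denominator (0 = continuous distance);
// mutable state (covariate values Zl, random effects epsl, detections
// y1/y2, latent probit values ys1/ys2, linear predictors mu1/mu2, p*,
// correlations, design matrices X1/X2, group counts G — all modified in
// place); current parameters (beta, rho, flattened covariate-model
// parameters, jump windows psi, log Poisson means); update switches.
// [[Rcpp::export(name = ".cpp_sweep")]]
List cpp_sweep(
    LogicalVector two,
    IntegerVector offset,
    IntegerVector cvec,
    IntegerVector Gmax,
    LogicalVector sampledU,
    IntegerVector spidx,
    NumericMatrix S1, NumericMatrix S2,
    List dyn_cov, List dyn_kind,
    List affected,
    LogicalVector cov_in_design,
    int distance_cov,
    double bin_denom,
    List Zl, List epsl,
    IntegerVector y1, IntegerVector y2,
    NumericVector ys1, NumericVector ys2,
    NumericVector mu1, NumericVector mu2,
    NumericVector pstar, NumericVector corr,
    NumericMatrix X1, NumericMatrix X2,
    IntegerVector G,
    NumericVector beta, double rho,
    List covpar,
    IntegerVector psi, NumericVector log_lamA,
    bool upd_G, bool upd_latent, bool any_two) {

  RNGScope scope;
  int n_units = offset.size();
  int p = beta.size();
  int n_cov = Zl.size();

  std::vector<CovModel> cms(n_cov);
  for (int c = 0; c < n_cov; c++) {
    List e = covpar[c];
    cms[c].family = as<int>(e[0]);
    cms[c].par = as<NumericMatrix>(e[1]);
  }
  if (n_cov > 64) stop("too many covariate models");

  // evaluate design row for slot i, observer side (0 or 1), column j;
  // raw column-major pointers for speed
  int n_slots = two.size();
  double *S1p = REAL(S1), *S2p = REAL(S2);
  double *X1p = REAL(X1), *X2p = REAL(X2);
  double *Zp[64], *EPp[64];
  for (int c = 0; c < n_cov; c++) { Zp[c] = REAL(Zl[c]); EPp[c] = REAL(epsl[c]); }
  double *betap = REAL(beta);
  std::vector<std::vector<int> > dc(p), dk(p);
  for (int j = 0; j < p; j++) {
    IntegerVector a = as<IntegerVector>(dyn_cov[j]);
    IntegerVector b2 = as<IntegerVector>(dyn_kind[j]);
    dc[j].assign(a.begin(), a.end());
    dk[j].assign(b2.begin(), b2.end());
  }
  auto col_val = [&](int i, int side, int j) -> double {
    double v = side == 0 ? S1p[i + j * n_slots] : S2p[i + j * n_slots];
    if (v == 0.0) return 0.0;
    const std::vector<int> &cj = dc[j], &kj = dk[j];
    for (size_t m = 0; m < cj.size(); m++) {
      double z = Zp[cj[m]][i];
      if (kj[m] < 0) v *= z;
      else if ((int)z != kj[m]) return 0.0;
    }
    return v;
  };
  auto slot_mu = [&](int i, int side) -> double {
    double s = 0.0;
    double *Xp = side == 0 ? X1p : X2p;
    for (int j = 0; j < p; j++) {
      double x = col_val(i, side, j);
      Xp[i + j * n_slots] = x;
      s += betap[j] * x;
    }
    return s;
  };
  auto cscale_of = [&](double d) -> double {
    if (distance_cov < 0) return 0.0;
    return bin_denom > 0.0 ? (d - 1.0) / bin_denom : d;
  };
  auto pstar_of = [&](int i, double m1, double m2, double r) -> double {
    if (two[i]) return 1.0 - bvnu(m1, m2, r);
    return R::pnorm(m1, 0, 1, 1, 0);
  };

  int acc_G = 0, n_G = 0, acc_lat = 0, n_lat = 0, saturated = 0;

  // (0) refresh reachable pseudo-groups, (1) mu / p* over the working set
  for (int u = 0; u < n_units; u++) {
    int reach = std::min(G[u] + psi[u], Gmax[u]);
    for (int s = offset[u]; s < offset[u] + reach; s++) {
      if (s >= offset[u] + G[u]) {          // pseudo slot: fresh covariates
        for (int c = 0; c < n_cov; c++) {
          double z, e;
          cov_sample(cms[c], spidx[s], z, e);
          Zp[c][s] = z; EPp[c][s] = e;
        }
      }
      double m1 = slot_mu(s, 0);
      mu1[s] = m1;
      double m2 = 0.0;
      if (two[s]) { m2 = slot_mu(s, 1); mu2[s] = m2; }
      double r = 0.0;
      if (two[s] && distance_cov >= 0) {
        r = rho * cscale_of(Zp[distance_cov][s]);
      }
      corr[s] = r;
      pstar[s] = pstar_of(s, m1, m2, r);
    }
  }

  // (2) reversible jump on each sampled unit's count
  if (upd_G) {
    for (int u = 0; u < n_units; u++) {
      if (!sampledU[u] || Gmax[u] == 0) continue;
      n_G++;
      int Gu = G[u], cu = cvec[u];
      int d = 1 + (int)std::floor(unif_rand() * (2 * psi[u]));
      if (d > 2 * psi[u]) d = 2 * psi[u];
      int Gp = Gu + (d <= psi[u] ? d - psi[u] - 1 : d - psi[u]);
      if (Gp < cu || Gp > Gmax[u]) continue;
      double s_rng = 0.0;
      int lo = std::min(Gu, Gp), hi = std::max(Gu, Gp);
      for (int s = offset[u] + lo; s < offset[u] + hi; s++) {
        double ps = pstar[s];
        if (ps > 1.0 - 1e-15) ps = 1.0 - 1e-15;
        s_rng += std::log1p(-ps);
      }
      double lr = (Gp - Gu) * log_lamA[u] +
        (Gp > Gu ? s_rng : -s_rng) -
        (R::lgammafn(Gp - cu + 1.0) - R::lgammafn(Gu - cu + 1.0));
      if (std::log(unif_rand()) < lr) {
        if (Gp > Gu) {
          // exact latent pairs for the added all-zero groups
          for (int s = offset[u] + Gu; s < offset[u] + Gp; s++) {
            if (two[s]) {
              double r = corr[s], sr = std::sqrt(1.0 - r * r);
              bool done = false;
              for (int tries = 0; tries < 50 && !done; tries++) {
                double z1 = norm_rand();
                double z2 = r * z1 + sr * norm_rand();
                double a = mu1[s] + z1, b = mu2[s] + z2;
                if (a <= 0.0 && b <= 0.0) {
                  ys1[s] = a; ys2[s] = b; done = true;
                }
              }
              if (!done) {   // near-certain detection: Gibbs scans
                ys1[s] = rtnorm0(mu1[s], 1.0, false);
                ys2[s] = rtnorm0(mu2[s], 1.0, false);
                for (int it = 0; it < 10; it++) {
                  ys1[s] = rtnorm0(mu1[s] + r * (ys2[s] - mu2[s]), sr, false);
                  ys2[s] = rtnorm0(mu2[s] + r * (ys1[s] - mu1[s]), sr, false);
                }
              }
            } else {
              ys1[s] = rtnorm0(mu1[s], 1.0, false);
            }
          }
        }
        G[u] = Gp;
        acc_G++;
      }
    }
    for (int u = 0; u < n_units; u++) {
      if (sampledU[u] && Gmax[u] > 0 && G[u] == Gmax[u]) { saturated = 1; break; }
    }
  }

  // (3) latent-covariate resampling: target (1 - p*(z)) g(z|theta),
  // proposals from g cancel, leaving the ratio (1 - p*') / (1 - p*)
  if (upd_latent) {
    for (int c = 0; c < n_cov; c++) {
      bool in_design = cov_in_design[c];
      IntegerVector aff = as<IntegerVector>(affected[c]);
      for (int u = 0; u < n_units; u++) {
        for (int s = offset[u] + cvec[u]; s < offset[u] + G[u]; s++) {
          double zc, ec;
          cov_sample(cms[c], spidx[s], zc, ec);
          n_lat++;
          bool corr_changes = (c == distance_cov) && two[s] && rho != 0.0;
          if (!in_design && !corr_changes) {
            Zp[c][s] = zc; EPp[c][s] = ec;   // ratio is exactly 1
            acc_lat++;
            continue;
          }
          double zold = Zp[c][s];
          double m1 = mu1[s], m2 = mu2[s];
          Zp[c][s] = zc;
          if (in_design) {
            for (int m = 0; m < aff.size(); m++) {
              int j = aff[m];
              double xo = X1p[s + j * n_slots], xn = col_val(s, 0, j);
              m1 += beta[j] * (xn - xo);
              if (two[s]) {
                double xo2 = X2p[s + j * n_slots], xn2 = col_val(s, 1, j);
                m2 += beta[j] * (xn2 - xo2);
              }
            }
          }
          double r = corr[s];
          if (c == distance_cov && two[s]) r = rho * cscale_of(zc);
          double pnew = pstar_of(s, m1, m2, r);
          double pold = pstar[s];
          if (pold > 1.0 - 1e-15) pold = 1.0 - 1e-15;
          double pn = pnew > 1.0 - 1e-15 ? 1.0 - 1e-15 : pnew;
          if (std::log(unif_rand()) < std::log1p(-pn) - std::log1p(-pold)) {
            EPp[c][s] = ec;
            mu1[s] = m1;
            if (two[s]) mu2[s] = m2;
            corr[s] = r;
            pstar[s] = pnew;
            if (in_design) {
              for (int m = 0; m < aff.size(); m++) {
                int j = aff[m];
                X1p[s + j * n_slots] = col_val(s, 0, j);
                if (two[s]) X2p[s + j * n_slots] = col_val(s, 1, j);
              }
            }
            acc_lat++;
          } else {
            Zp[c][s] = zold;                // reject: restore
          }
        }
      }
    }
  }

  // (4) latent probit Gibbs over active slots (observed + latent groups),
  // accumulating the whitened cross-products for the beta full conditional
  // (rows x1 and (x2 - r x1)/sqrt(1-r^2) with matching responses)
  NumericMatrix A(p, p);
  NumericVector b(p);
  std::vector<double> x1(p), x2(p);
  for (int u = 0; u < n_units; u++) {
    for (int s = offset[u]; s < offset[u] + G[u]; s++) {
      bool obs = s < offset[u] + cvec[u];
      bool d1 = obs && y1[s] == 1;
      double w1 = 0.0, w2 = 0.0;
      bool has2 = two[s];
      if (has2) {
        bool d2 = obs && y2[s] == 1;
        double r = corr[s], sr = std::sqrt(1.0 - r * r);
        ys1[s] = rtnorm0(mu1[s] + r * (ys2[s] - mu2[s]), sr, d1);
        ys2[s] = rtnorm0(mu2[s] + r * (ys1[s] - mu1[s]), sr, d2);
        for (int j = 0; j < p; j++) {
          x1[j] = X1p[s + j * n_slots];
          x2[j] = (X2p[s + j * n_slots] - r * x1[j]) / sr;
        }
        w1 = ys1[s];
        w2 = (ys2[s] - r * ys1[s]) / sr;
      } else {
        ys1[s] = rtnorm0(mu1[s], 1.0, d1);
        for (int j = 0; j < p; j++) x1[j] = X1p[s + j * n_slots];
        w1 = ys1[s];
      }
      for (int j = 0; j < p; j++) {
        b[j] += x1[j] * w1;
        if (has2) b[j] += x2[j] * w2;
        for (int l = j; l < p; l++) {
          A(j, l) += x1[j] * x1[l];
          if (has2) A(j, l) += x2[j] * x2[l];
        }
      }
    }
  }
  for (int j = 0; j < p; j++) {
    for (int l = j + 1; l < p; l++) A(l, j) = A(j, l);
  }

  return List::create(_["acc_G"] = acc_G, _["n_G"] = n_G,
                      _["acc_lat"] = acc_lat, _["n_lat"] = n_lat,
                      _["saturated"] = saturated,
                      _["xtx"] = A, _["xty"] = b);
}
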