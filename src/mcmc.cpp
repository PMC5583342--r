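// Metropolis-within-Gibbs sampler for the joint hierarchical model:
// latent occupancy dynamics (two-state CTMC over unequal intervals),
// dispersal-kernel connectivity, record-level detection, Gaussian path
// regressions with cell random effects, and spike-and-slab variable
// selection with a globally adapted slab.
//
// Conventions: cell-period arrays are period-major (index s + S*t);
// rates enter on the log scale (log r_phi = X beta_phi, log r_gamma =
// lambda * connectivity + gamma0). All randomness uses R's RNG so runs
// are reproducible from R seeds.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NPAR = 41;

// Transition terms of the 2-state CTMC over an interval dt, from log
// rates. Returns log pGamma, log(1-pGamma), log pPhi, log(1-pPhi),
// numerically safe for extreme rate ratios and large dt.
static inline void transTerms(double lphi, double lgam, double dt,
                              double &lpg, double &l1mpg,
                              double &lpp, double &l1mpp) {
  double m = std::max(lphi, lgam);
  double ephi = std::exp(lphi - m), egam = std::exp(lgam - m);
  double rsum = ephi + egam;
  double rdt = std::exp(m) * rsum * dt;   // may overflow to inf
  if (rdt < 1e-12) {                       // first-order Taylor regime
    double pg = std::exp(lgam) * dt, pp = std::exp(lphi) * dt;
    lpg = std::log(pg); l1mpg = std::log1p(-pg);
    lpp = std::log(pp); l1mpp = std::log1p(-pp);
    return;
  }
  double E = (std::isinf(rdt)) ? 0.0 : std::exp(-rdt);
  double grow = (std::isinf(rdt)) ? 1.0 : -std::expm1(-rdt);
  lpg = std::log(egam / rsum * grow);
  l1mpg = std::log((ephi + egam * E) / rsum);
  lpp = std::log(ephi / rsum * grow);
  l1mpp = std::log((egam + ephi * E) / rsum);
}

struct State {
  std::vector<double> bphi;     // 5: intercept, lu, npp, wt, ele
  std::vector<double> bp;       // 8: intercept, log-NSP, 6 type offsets
  double alpha, psi1;
  std::vector<double> path;     // 9: wt0, wt_ele, npp0, npp_wt, npp_ele,
                                //    lu0, lu_npp, lu_wt, lu_ele
  std::vector<double> tau;      // 3 residual precisions (wt, npp, lu)
  std::vector<double> tauCell;  // 3 cell-effect precisions
  std::vector<double> ce;       // 3*S cell effects (wt, npp, lu blocks)
  double slabSd;
  std::vector<int> I;           // 10 inclusion indicators
  std::vector<int> z;           // S*T occupancy
  std::vector<int> rtype;       // per-record site type (0..6)
};

class Sampler {
public:
  int S, T, nrec, nsrc;
  std::vector<double> dt;
  NumericMatrix X;              // (S*T) x 4: lu, npp, wt, ele
  NumericMatrix D;
  NumericMatrix srcD;           // S x nsrc
  std::vector<int> rcell, rper, ry;
  std::vector<double> rlogn;
  NumericMatrix typeFreq;       // 7 x T
  std::vector<int> perfect;     // length T
  std::vector<int> pinned;      // S*T: -1 free, else 0/1
  std::vector<int> unknownType; // record indices with unknown type

  // config
  double spikeSd, slabMax, priorInc, alphaShape, alphaRate, coefSd;
  double gamma0, lambda;
  bool ssvs;

  State st;

  // adaptive block proposals (running moments of the draws)
  double bSum[5], bProd[5][5];
  long bCount;
  double blockScale;
  double pSum[8], pProd[8][8];
  long pCount;
  double pScale;

  // caches
  std::vector<double> K;        // S*S kernel exp(-alpha d)
  std::vector<double> srcC;     // S source contribution
  std::vector<double> Sc;       // S*(T-1) connectivity (incl. sources)
  std::vector<double> xb;       // S*T log extinction rate
  std::vector<double> rec0;     // S*T sum of log(1-p) over y=0 records
  double curTrans, curDet;

  // adaptive MH step sizes: 5 bphi, 8 bp, alpha, slab  (15)
  std::vector<double> step;
  std::vector<int> accN, accA;

  Sampler(List data, List cfg, List init) {
    S = as<int>(data["S"]); T = as<int>(data["T"]);
    dt = as<std::vector<double> >(data["dt"]);
    X = as<NumericMatrix>(data["X"]);
    D = as<NumericMatrix>(data["D"]);
    srcD = as<NumericMatrix>(data["srcD"]);
    nsrc = srcD.ncol();
    rcell = as<std::vector<int> >(data["rcell"]);
    rper = as<std::vector<int> >(data["rper"]);
    ry = as<std::vector<int> >(data["ry"]);
    rlogn = as<std::vector<double> >(data["rlogn"]);
    nrec = rcell.size();
    typeFreq = as<NumericMatrix>(data["typeFreq"]);
    perfect = as<std::vector<int> >(data["perfect"]);
    pinned = as<std::vector<int> >(data["pinned"]);
    unknownType = as<std::vector<int> >(data["unknownType"]);

    spikeSd = as<double>(cfg["spikeSd"]);
    slabMax = as<double>(cfg["slabMax"]);
    priorInc = as<double>(cfg["priorInclusion"]);
    alphaShape = as<double>(cfg["alphaShape"]);
    alphaRate = as<double>(cfg["alphaRate"]);
    coefSd = as<double>(cfg["coefSd"]);
    gamma0 = as<double>(cfg["gamma0"]);
    lambda = as<double>(cfg["lambda"]);
    ssvs = as<bool>(cfg["ssvs"]);

    st.bphi = as<std::vector<double> >(init["betaPhi"]);
    st.bp = as<std::vector<double> >(init["betaP"]);
    st.alpha = as<double>(init["alpha"]);
    st.psi1 = as<double>(init["psi1"]);
    st.path = as<std::vector<double> >(init["pathCoef"]);
    st.tau = as<std::vector<double> >(init["tau"]);
    st.tauCell = as<std::vector<double> >(init["tauCell"]);
    NumericMatrix cem = as<NumericMatrix>(init["cellEff"]);
    st.ce.assign(3 * S, 0.0);
    for (int k = 0; k < 3; ++k)
      for (int s = 0; s < S; ++s) st.ce[k * S + s] = cem(s, k);
    st.slabSd = as<double>(init["slabSd"]);
    st.I = as<std::vector<int> >(init["I"]);
    IntegerMatrix zm = as<IntegerMatrix>(init["z"]);
    st.z.assign(S * T, 0);
    for (int t = 0; t < T; ++t)
      for (int s = 0; s < S; ++s) st.z[s + S * t] = zm(s, t);
    st.rtype = as<std::vector<int> >(init["rtype"]);

    step.assign(17, 0.1);
    step[13] = 0.3;   // alpha (log scale)
    step[14] = 1.0;   // slab sd
    step[15] = 1.0;   // beta_phi block-proposal scale multiplier
    step[16] = 1.0;   // beta_p block-proposal scale multiplier
    accN.assign(17, 0); accA.assign(17, 0);
    for (int i = 0; i < 5; ++i) {
      bSum[i] = 0.0;
      for (int j = 0; j < 5; ++j) bProd[i][j] = 0.0;
    }
    bCount = 0; blockScale = 1.0;
    for (int i = 0; i < 8; ++i) {
      pSum[i] = 0.0;
      for (int j = 0; j < 8; ++j) pProd[i][j] = 0.0;
    }
    pCount = 0; pScale = 1.0;

    K.assign((size_t)S * S, 0.0);
    srcC.assign(S, 0.0);
    Sc.assign((size_t)S * std::max(T - 1, 1), 0.0);
    xb.assign((size_t)S * T, 0.0);
    rec0.assign((size_t)S * T, 0.0);
    rebuildKernel(); rebuildXb(); rebuildRec0();
    curTrans = transLogLik();
    curDet = detLogLik();
  }

  void rebuildKernel() {
    for (int j = 0; j < S; ++j)
      for (int i = 0; i < S; ++i) {
        double d = D(i, j);
        K[(size_t)i + (size_t)S * j] =
          (i == j || !std::isfinite(d)) ? 0.0 : std::exp(-st.alpha * d);
      }
    for (int i = 0; i < S; ++i) {
      double a = 0.0;
      for (int k = 0; k < nsrc; ++k) a += std::exp(-st.alpha * srcD(i, k));
      srcC[i] = a;
    }
    rebuildConn();
  }

  void rebuildConn() {
    for (int t = 0; t < T - 1; ++t) {
      for (int i = 0; i < S; ++i) {
        double a = srcC[i];
        for (int j = 0; j < S; ++j)
          if (st.z[j + S * t]) a += K[(size_t)i + (size_t)S * j];
        Sc[i + S * t] = a;
      }
    }
  }

  void rebuildXb() {
    for (int idx = 0; idx < S * T; ++idx)
      xb[idx] = st.bphi[0] + st.bphi[1] * X(idx, 0) + st.bphi[2] * X(idx, 1)
              + st.bphi[3] * X(idx, 2) + st.bphi[4] * X(idx, 3);
  }

  inline double detP(int i) const {
    double lp = st.bp[0] + st.bp[1] * rlogn[i];
    int ty = st.rtype[i];
    if (ty > 0) lp += st.bp[1 + ty];   // offsets for types 1..6; type 0 ref
    return 1.0 / (1.0 + std::exp(-lp));
  }

  void rebuildRec0() {
    std::fill(rec0.begin(), rec0.end(), 0.0);
    for (int i = 0; i < nrec; ++i)
      if (ry[i] == 0)
        rec0[rcell[i] + S * rper[i]] += std::log1p(-detP(i));
  }

  // log-rate of colonization from connectivity
  inline double lgam(int s, int t) const {
    return gamma0 + lambda * Sc[s + S * t];
  }

  double transLogLik() {
    double ll = 0.0, lpg, l1pg, lpp, l1pp;
    for (int t = 0; t < T - 1; ++t)
      for (int s = 0; s < S; ++s) {
        transTerms(xb[s + S * t], lgam(s, t), dt[t], lpg, l1pg, lpp, l1pp);
        int z0 = st.z[s + S * t], z1 = st.z[s + S * (t + 1)];
        ll += z0 ? (z1 ? l1pp : lpp) : (z1 ? lpg : l1pg);
      }
    return ll;
  }

  // as transLogLik but with perturbed log extinction rate xb + db * xcol
  double transLogLikPhi(int j, double db) {
    double ll = 0.0, lpg, l1pg, lpp, l1pp;
    for (int t = 0; t < T - 1; ++t)
      for (int s = 0; s < S; ++s) {
        int idx = s + S * t;
        double l = xb[idx] + (j == 0 ? db : db * X(idx, j - 1));
        transTerms(l, lgam(s, t), dt[t], lpg, l1pg, lpp, l1pp);
        int z0 = st.z[idx], z1 = st.z[s + S * (t + 1)];
        ll += z0 ? (z1 ? l1pp : lpp) : (z1 ? lpg : l1pg);
      }
    return ll;
  }

  double detLogLik() {
    double ll = 0.0;
    for (int i = 0; i < nrec; ++i) {
      if (!st.z[rcell[i] + S * rper[i]]) continue;  // z=0: y must be 0
      double p = detP(i);
      ll += ry[i] ? std::log(p) : std::log1p(-p);
    }
    return ll;
  }

  // ---- latent occupancy: single-site Gibbs sweep -----------------------
  void updateZ() {
    double lpg, l1pg, lpp, l1pp;
    for (int t = 0; t < T; ++t) {
      for (int s = 0; s < S; ++s) {
        if (pinned[s + S * t] >= 0) continue;
        double delta = 0.0;
        if (t == 0)
          delta += std::log(st.psi1) - std::log1p(-st.psi1);
        else {
          int zp = st.z[s + S * (t - 1)];
          transTerms(xb[s + S * (t - 1)], lgam(s, t - 1), dt[t - 1],
                     lpg, l1pg, lpp, l1pp);
          delta += zp ? (l1pp - lpp) : (lpg - l1pg);
        }
        if (t < T - 1) {
          int zn = st.z[s + S * (t + 1)];
          transTerms(xb[s + S * t], lgam(s, t), dt[t],
                     lpg, l1pg, lpp, l1pp);
          delta += zn ? (l1pp - lpg) : (lpp - l1pg);
          // connectivity feedback on all cells empty at t
          int zcur = st.z[s + S * t];
          for (int s2 = 0; s2 < S; ++s2) {
            if (s2 == s || st.z[s2 + S * t]) continue;
            double k = K[(size_t)s2 + (size_t)S * s];
            if (k < 1e-14) continue;
            double base = Sc[s2 + S * t];
            double S1 = base + (zcur ? 0.0 : k);
            double S0 = base - (zcur ? k : 0.0);
            double g1, h1, g0, h0, du;
            transTerms(xb[s2 + S * t], gamma0 + lambda * S1, dt[t],
                       g1, h1, du, du);
            transTerms(xb[s2 + S * t], gamma0 + lambda * S0, dt[t],
                       g0, h0, du, du);
            delta += st.z[s2 + S * (t + 1)] ? (g1 - g0) : (h1 - h0);
          }
        }
        if (!perfect[t]) delta += rec0[s + S * t];  // y=0 records if z=1
        double p1 = 1.0 / (1.0 + std::exp(-delta));
        int znew = (unif_rand() < p1) ? 1 : 0;
        int zold = st.z[s + S * t];
        if (znew != zold) {
          st.z[s + S * t] = znew;
          if (t < T - 1) {
            double sgn = znew ? 1.0 : -1.0;
            for (int s2 = 0; s2 < S; ++s2)
              Sc[s2 + S * t] += sgn * K[(size_t)s2 + (size_t)S * s];
            Sc[s + S * t] -= sgn * K[(size_t)s + (size_t)S * s]; // 0 anyway
          }
        }
      }
    }
    curTrans = transLogLik();
    curDet = detLogLik();
  }

  // ---- psi1: conjugate Beta under Uniform(0,1) prior -------------------
  void updatePsi1() {
    int n1 = 0;
    for (int s = 0; s < S; ++s) n1 += st.z[s];
    st.psi1 = R::rbeta(1.0 + n1, 1.0 + S - n1);
  }

  // ---- site-type imputation (full conditional) -------------------------
  void updateTypes() {
    if (unknownType.empty()) return;
    for (size_t u = 0; u < unknownType.size(); ++u) {
      int i = unknownType[u];
      int t = rper[i];
      double w[7], tot = 0.0;
      bool occ = st.z[rcell[i] + S * t] == 1;
      for (int k = 0; k < 7; ++k) {
        double f = typeFreq(k, t);
        if (f <= 0) { w[k] = 0; continue; }
        if (occ) {
          double lp = st.bp[0] + st.bp[1] * rlogn[i];
          if (k > 0) lp += st.bp[1 + k];
          double p = 1.0 / (1.0 + std::exp(-lp));
          f *= ry[i] ? p : (1.0 - p);
        }
        w[k] = f; tot += f;
      }
      double u01 = unif_rand() * tot, acc = 0.0;
      int pick = 6;
      for (int k = 0; k < 7; ++k) { acc += w[k]; if (u01 <= acc) { pick = k; break; } }
      st.rtype[i] = pick;
    }
    rebuildRec0();
    curDet = detLogLik();
  }

  // ---- detection coefficients: adaptive RW Metropolis ------------------
  void updateBetaP(bool adapt) {
    for (int j = 0; j < 8; ++j) {
      int sj = 5 + j;
      double old = st.bp[j];
      double prop = old + norm_rand() * step[sj];
      st.bp[j] = prop;
      double newDet = detLogLik();
      double lr = newDet - curDet
        + R::dnorm(prop, 0.0, coefSd, 1) - R::dnorm(old, 0.0, coefSd, 1);
      accN[sj]++;
      if (std::log(unif_rand()) < lr) { curDet = newDet; accA[sj]++; }
      else st.bp[j] = old;
    }
    rebuildRec0();
    if (adapt) adaptSteps(5, 12);
    updateBetaPBlock(adapt);
  }

  // ---- extinction-rate coefficients: adaptive RW Metropolis ------------
  void updateBetaPhi(bool adapt) {
    for (int j = 0; j < 5; ++j) {
      double old = st.bphi[j];
      double db = norm_rand() * step[j];
      double prop = old + db;
      double newTrans = transLogLikPhi(j, db);
      double lpri;
      if (j == 0 || !ssvs) {
        lpri = R::dnorm(prop, 0.0, coefSd, 1) - R::dnorm(old, 0.0, coefSd, 1);
      } else {
        double sd = st.I[j - 1] ? st.slabSd : spikeSd;
        lpri = R::dnorm(prop, 0.0, sd, 1) - R::dnorm(old, 0.0, sd, 1);
      }
      double lr = newTrans - curTrans + lpri;
      accN[j]++;
      if (std::log(unif_rand()) < lr) {
        st.bphi[j] = prop; curTrans = newTrans; accA[j]++;
        for (int idx = 0; idx < S * T; ++idx)
          xb[idx] += (j == 0 ? db : db * X(idx, j - 1));
      }
    }
    if (adapt) adaptSteps(0, 4);
    updateBetaPhiBlock(adapt);
  }

  // Joint proposal over all five extinction coefficients along the
  // adapted posterior covariance: the causal structure of the covariates
  // (LU driven by WT and NPP) correlates the slopes, and coordinate-wise
  // walks mix poorly along the resulting ridge.
  double transLogLikPhiVec(const double *db) {
    double ll = 0.0, lpg, l1pg, lpp, l1pp;
    for (int t = 0; t < T - 1; ++t)
      for (int s = 0; s < S; ++s) {
        int idx = s + S * t;
        double l = xb[idx] + db[0] + db[1] * X(idx, 0) + db[2] * X(idx, 1)
                 + db[3] * X(idx, 2) + db[4] * X(idx, 3);
        transTerms(l, lgam(s, t), dt[t], lpg, l1pg, lpp, l1pp);
        int z0 = st.z[idx], z1 = st.z[s + S * (t + 1)];
        ll += z0 ? (z1 ? l1pp : lpp) : (z1 ? lpg : l1pg);
      }
    return ll;
  }

  double lPriorPhi(const std::vector<double> &b) {
    double lp = R::dnorm(b[0], 0.0, coefSd, 1);
    for (int j = 1; j < 5; ++j) {
      double sd = (!ssvs) ? coefSd : (st.I[j - 1] ? st.slabSd : spikeSd);
      lp += R::dnorm(b[j], 0.0, sd, 1);
    }
    return lp;
  }

  // multivariate step along the adapted covariance (Haario-style);
  // returns false while the moment buffer is still warming up
  static bool blockStep(int n, const double *sum, const double *prod,
                        long count, double scale, double *db) {
    if (count < 100) return false;
    std::vector<double> C((size_t)n * n), L((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double c = (prod[i * n + j] - sum[i] * sum[j] / count) / (count - 1);
        c *= 2.38 * 2.38 / n * scale * scale;
        if (i == j) c += 1e-8;
        C[i * n + j] = c;
      }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j <= i; ++j) {
        double s = C[i * n + j];
        for (int k = 0; k < j; ++k) s -= L[i * n + k] * L[j * n + k];
        if (i == j) {
          if (s <= 0) return false;      // degenerate; skip this move
          L[i * n + i] = std::sqrt(s);
        } else L[i * n + j] = s / L[j * n + j];
      }
    std::vector<double> eps(n);
    for (int i = 0; i < n; ++i) eps[i] = norm_rand();
    for (int i = 0; i < n; ++i) {
      db[i] = 0.0;
      for (int j = 0; j <= i; ++j) db[i] += L[i * n + j] * eps[j];
    }
    return true;
  }

  void updateBetaPhiBlock(bool adapt) {
    // accumulate running moments during adaptation
    if (adapt) {
      ++bCount;
      for (int i = 0; i < 5; ++i) {
        bSum[i] += st.bphi[i];
        for (int j = 0; j < 5; ++j) bProd[i][j] += st.bphi[i] * st.bphi[j];
      }
    }
    double db[5];
    if (!blockStep(5, bSum, &bProd[0][0], bCount, blockScale, db)) return;
    std::vector<double> prop(5);
    for (int i = 0; i < 5; ++i) prop[i] = st.bphi[i] + db[i];
    double newTrans = transLogLikPhiVec(db);
    double lr = newTrans - curTrans + lPriorPhi(prop) - lPriorPhi(st.bphi);
    accN[15]++;
    if (std::log(unif_rand()) < lr) {
      accA[15]++;
      curTrans = newTrans;
      for (int idx = 0; idx < S * T; ++idx)
        xb[idx] += db[0] + db[1] * X(idx, 0) + db[2] * X(idx, 1)
                 + db[3] * X(idx, 2) + db[4] * X(idx, 3);
      st.bphi = prop;
    }
    if (adapt && accN[15] >= 50) {
      double rate = (double)accA[15] / accN[15];
      if (rate > 0.4) blockScale *= 1.25;
      else if (rate < 0.2) blockScale /= 1.25;
      accN[15] = 0; accA[15] = 0;
    }
  }

  // adapted joint proposal over the eight detection coefficients (the
  // intercept and type offsets are strongly correlated a posteriori)
  void updateBetaPBlock(bool adapt) {
    if (adapt) {
      ++pCount;
      for (int i = 0; i < 8; ++i) {
        pSum[i] += st.bp[i];
        for (int j = 0; j < 8; ++j) pProd[i][j] += st.bp[i] * st.bp[j];
      }
    }
    double db[8];
    if (!blockStep(8, pSum, &pProd[0][0], pCount, pScale, db)) return;
    std::vector<double> old = st.bp;
    double lr = 0.0;
    for (int i = 0; i < 8; ++i) {
      st.bp[i] += db[i];
      lr += R::dnorm(st.bp[i], 0.0, coefSd, 1)
          - R::dnorm(old[i], 0.0, coefSd, 1);
    }
    double newDet = detLogLik();
    lr += newDet - curDet;
    accN[16]++;
    if (std::log(unif_rand()) < lr) {
      curDet = newDet; accA[16]++;
      rebuildRec0();
    } else st.bp = old;
    if (adapt && accN[16] >= 50) {
      double rate = (double)accA[16] / accN[16];
      if (rate > 0.4) pScale *= 1.25;
      else if (rate < 0.2) pScale /= 1.25;
      accN[16] = 0; accA[16] = 0;
    }
  }

  // ---- dispersal parameter alpha: log-scale RW Metropolis --------------
  void updateAlpha(bool adapt) {
    double old = st.alpha;
    double prop = old * std::exp(norm_rand() * step[13]);
    std::vector<double> Kold = K, srcOld = srcC, ScOld = Sc;
    st.alpha = prop;
    rebuildKernel();
    double newTrans = transLogLik();
    double lr = newTrans - curTrans
      + R::dgamma(prop, alphaShape, 1.0 / alphaRate, 1)
      - R::dgamma(old, alphaShape, 1.0 / alphaRate, 1)
      + std::log(prop) - std::log(old);      // Jacobian of log-scale walk
    accN[13]++;
    if (std::log(unif_rand()) < lr) { curTrans = newTrans; accA[13]++; }
    else { st.alpha = old; K = Kold; srcC = srcOld; Sc = ScOld; }
    if (adapt) adaptSteps(13, 13);
  }

  // ---- Gaussian path regressions: conjugate updates --------------------
  // regression r: response column resp, predictors preds (indices into X
  // columns), coefficient offsets into st.path, cell-effect block b.
  void pathRegression(int resp, const std::vector<int> &preds,
                      int coef0, int b, const std::vector<int> &Iidx) {
    int n = S * T;
    double tau = st.tau[b], tauC = st.tauCell[b];
    // current residual
    std::vector<double> res(n);
    for (int idx = 0; idx < n; ++idx) {
      double mu = st.path[coef0] + st.ce[b * S + idx % S];
      for (size_t q = 0; q < preds.size(); ++q)
        mu += st.path[coef0 + 1 + q] * X(idx, preds[q]);
      res[idx] = X(idx, resp) - mu;
    }
    // intercept, diffuse N(0, coefSd^2)
    {
      double sum = 0.0;
      for (int idx = 0; idx < n; ++idx) sum += res[idx] + st.path[coef0];
      double v = 1.0 / (tau * n + 1.0 / (coefSd * coefSd));
      double m = v * tau * sum;
      double neu = m + norm_rand() * std::sqrt(v);
      double d = neu - st.path[coef0];
      st.path[coef0] = neu;
      for (int idx = 0; idx < n; ++idx) res[idx] -= d;
    }
    // slopes, spike-slab (or diffuse) prior
    for (size_t q = 0; q < preds.size(); ++q) {
      int cj = coef0 + 1 + q;
      double pv;
      if (!ssvs) pv = coefSd * coefSd;
      else {
        double sd = st.I[Iidx[q]] ? st.slabSd : spikeSd;
        pv = sd * sd;
      }
      double sxx = 0.0, sxr = 0.0;
      for (int idx = 0; idx < n; ++idx) {
        double x = X(idx, preds[q]);
        sxx += x * x;
        sxr += x * (res[idx] + st.path[cj] * x);
      }
      double v = 1.0 / (tau * sxx + 1.0 / pv);
      double m = v * tau * sxr;
      double neu = m + norm_rand() * std::sqrt(v);
      double d = neu - st.path[cj];
      st.path[cj] = neu;
      for (int idx = 0; idx < n; ++idx) res[idx] -= d * X(idx, preds[q]);
    }
    // cell effects, prior N(0, 1/tauC)
    for (int s = 0; s < S; ++s) {
      double sum = 0.0;
      for (int t = 0; t < T; ++t) sum += res[s + S * t] + st.ce[b * S + s];
      double v = 1.0 / (tau * T + tauC);
      double m = v * tau * sum;
      double neu = m + norm_rand() * std::sqrt(v);
      double d = neu - st.ce[b * S + s];
      st.ce[b * S + s] = neu;
      for (int t = 0; t < T; ++t) res[s + S * t] -= d;
    }
    // precisions, Gamma(0.1, 0.1) priors
    double sse = 0.0;
    for (int idx = 0; idx < n; ++idx) sse += res[idx] * res[idx];
    st.tau[b] = R::rgamma(0.1 + 0.5 * n, 1.0 / (0.1 + 0.5 * sse));
    double ssc = 0.0;
    for (int s = 0; s < S; ++s) ssc += st.ce[b * S + s] * st.ce[b * S + s];
    st.tauCell[b] = R::rgamma(0.1 + 0.5 * S, 1.0 / (0.1 + 0.5 * ssc));
  }

  void updatePath() {
    std::vector<int> pr, Ii;
    pr = {3};            Ii = {4};          pathRegression(2, pr, 0, 0, Ii);
    pr = {2, 3};         Ii = {5, 6};       pathRegression(1, pr, 2, 1, Ii);
    pr = {1, 2, 3};      Ii = {7, 8, 9};    pathRegression(0, pr, 5, 2, Ii);
  }

  // ---- SSVS indicators and global slab adaptation ----------------------
  double slopeForIndicator(int j) const {
    switch (j) {
      case 0: return st.bphi[1]; case 1: return st.bphi[2];
      case 2: return st.bphi[3]; case 3: return st.bphi[4];
      case 4: return st.path[1];                 // wt_ele
      case 5: return st.path[3];                 // npp_wt
      case 6: return st.path[4];                 // npp_ele
      case 7: return st.path[6];                 // lu_npp
      case 8: return st.path[7];                 // lu_wt
      default: return st.path[8];                // lu_ele
    }
  }

  // Joint (beta_j, I_j) flip for the Metropolis-updated extinction
  // slopes: propose the opposite indicator with a fresh coefficient from
  // the corresponding prior component. The proposal densities cancel the
  // prior terms exactly, so acceptance is the transition-likelihood
  // ratio — an exact MH move that restores mixing across the spike/slab
  // modes (the conjugate path slopes do not need it: their Gibbs draw
  // already resamples the coefficient each sweep).
  void indicatorJumpMoves() {
    for (int j = 0; j < 4; ++j) {           // extinction slopes only
      int iNew = 1 - st.I[j];
      double sdNew = iNew ? st.slabSd : spikeSd;
      double bNew = norm_rand() * sdNew;
      double db = bNew - st.bphi[j + 1];
      double newTrans = transLogLikPhi(j + 1, db);
      if (std::log(unif_rand()) < newTrans - curTrans) {
        st.I[j] = iNew;
        st.bphi[j + 1] = bNew;
        curTrans = newTrans;
        for (int idx = 0; idx < S * T; ++idx)
          xb[idx] += db * X(idx, j);
      }
    }
  }

  void updateIndicators(bool adapt) {
    if (!ssvs) return;
    indicatorJumpMoves();
    for (int j = 0; j < 10; ++j) {
      double b = slopeForIndicator(j);
      double lS = R::dnorm(b, 0.0, st.slabSd, 1) + std::log(priorInc);
      double lP = R::dnorm(b, 0.0, spikeSd, 1) + std::log1p(-priorInc);
      double p1 = 1.0 / (1.0 + std::exp(lP - lS));
      st.I[j] = (unif_rand() < p1) ? 1 : 0;
    }
    // shared slab sd: reflected RW-MH under Uniform(0, slabMax)
    double old = st.slabSd;
    double prop = old + norm_rand() * step[14];
    if (prop < 0) prop = -prop;
    if (prop > slabMax) prop = 2 * slabMax - prop;
    if (prop > 0 && prop <= slabMax) {
      double lr = 0.0;
      for (int j = 0; j < 10; ++j)
        if (st.I[j]) {
          double b = slopeForIndicator(j);
          lr += R::dnorm(b, 0.0, prop, 1) - R::dnorm(b, 0.0, old, 1);
        }
      accN[14]++;
      if (std::log(unif_rand()) < lr) { st.slabSd = prop; accA[14]++; }
    }
    if (adapt) adaptSteps(14, 14);
  }

  void adaptSteps(int from, int to) {
    for (int j = from; j <= to; ++j) {
      if (accN[j] >= 50) {
        double rate = (double)accA[j] / accN[j];
        if (rate > 0.4) step[j] *= 1.25;
        else if (rate < 0.2) step[j] /= 1.25;
        accN[j] = 0; accA[j] = 0;
      }
    }
  }

  void writeRow(NumericMatrix &draws, int row) {
    int c = 0;
    for (int j = 0; j < 5; ++j) draws(row, c++) = st.bphi[j];
    for (int j = 0; j < 8; ++j) draws(row, c++) = st.bp[j];
    draws(row, c++) = st.alpha; draws(row, c++) = st.psi1;
    for (int j = 0; j < 9; ++j) draws(row, c++) = st.path[j];
    for (int j = 0; j < 3; ++j) draws(row, c++) = st.tau[j];
    for (int j = 0; j < 3; ++j) draws(row, c++) = st.tauCell[j];
    draws(row, c++) = st.slabSd;
    for (int j = 0; j < 10; ++j) draws(row, c++) = (double)st.I[j];
  }
};

// [[Rcpp::export(name = ".mcmc_chain")]]
List mcmc_chain(List data, List cfg, List init) {
  Sampler smp(data, cfg, init);
  int nIter = as<int>(cfg["nIter"]), burnIn = as<int>(cfg["burnIn"]),
      thin = as<int>(cfg["thin"]);
  List upd = cfg["update"];
  bool uZ = as<bool>(upd["z"]), uPhi = as<bool>(upd["betaPhi"]),
       uP = as<bool>(upd["betaP"]), uA = as<bool>(upd["alpha"]),
       uPsi = as<bool>(upd["psi1"]), uPath = as<bool>(upd["path"]),
       uI = as<bool>(upd["indicators"]), uTy = as<bool>(upd["types"]);
  bool retainZ = as<bool>(cfg["retainZ"]);

  int nKeep = (nIter - burnIn) / thin;
  NumericMatrix draws(nKeep, NPAR);
  IntegerVector zdraws(retainZ ? nKeep * smp.S * smp.T : 0);
  IntegerVector iters(nKeep);

  RNGScope scope;
  int row = 0;
  for (int it = 1; it <= nIter; ++it) {
    bool adapt = it <= burnIn;
    if (uTy) smp.updateTypes();
    if (uZ) smp.updateZ();
    if (uPsi) smp.updatePsi1();
    if (uP) smp.updateBetaP(adapt);
    if (uPhi) smp.updateBetaPhi(adapt);
    if (uA) smp.updateAlpha(adapt);
    if (uPath) smp.updatePath();
    if (uI) smp.updateIndicators(adapt);
    if (it > burnIn && (it - burnIn) % thin == 0 && row < nKeep) {
      smp.writeRow(draws, row);
      iters[row] = it;
      if (retainZ)
        for (int t = 0; t < smp.T; ++t)
          for (int s = 0; s < smp.S; ++s)
            zdraws[row + nKeep * (s + smp.S * t)] = smp.st.z[s + smp.S * t];
      ++row;
    }
  }
  NumericVector acc(17);
  for (int j = 0; j < 17; ++j)
    acc[j] = smp.accN[j] > 0 ? (double)smp.accA[j] / smp.accN[j] : NA_REAL;
  return List::create(_["draws"] = draws, _["iters"] = iters,
                      _["z"] = zdraws, _["accept"] = acc,
                      _["step"] = NumericVector(smp.step.begin(),
                                                smp.step.end()));
}
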