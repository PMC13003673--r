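#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the bivariate inbreeding-load animal model
//   y = X b + f d (+ t c) + W h + Z u + K i (+ L p) + e
// X holds the dense fixed-effect columns (intercept, factor contrasts,
// the inbreeding covariate d and the centered age covariate c, all with
// flat priors); HYS and permanent-environment levels enter through
// integer index vectors and are sampled from their N(0, sigma_h2) /
// N(0, sigma_p2) priors; (u, i) ~ N(0, V (x) H); e ~ N(0, I sigma_e2).
//
// Flat variance priors are implemented as the limiting conjugate forms:
//   sigma_e2 | .  =  SSE / chisq(n - 2)
//   sigma_h2 | .  =  h'h / chisq(q_h - 2)        (same for sigma_p2)
//   V | .         ~  InvWishart(q - 3 + dfAdjust, S),
//                    S = [u'H^-1 u, u'H^-1 i; ., i'H^-1 i]
// Scalar effects are updated single-site; (u_j, i_j) as a joint 2-block
// per animal, which is required for mixing under a strong sigma_ui.
// All randomness comes from R's RNG (reproducible under set.seed()).

static inline void inv2x2(double a, double b, double d,
                          double &ia, double &ib, double &id) {
  const double det = a * d - b * b;
  ia = d / det; ib = -b / det; id = a / det;
}

// record index lists per level of a 1-based factor (0 = no level)
static void levelLists(const IntegerVector &idx, int q,
                       std::vector<int> &start, std::vector<int> &items) {
  const int n = idx.size();
  start.assign(q + 2, 0);
  items.assign(n, 0);
  if (q == 0) return;
  std::vector<int> cnt(q + 1, 0);
  for (int r = 0; r < n; ++r) if (idx[r] > 0) cnt[idx[r]] += 1;
  for (int j = 1; j <= q; ++j) start[j + 1] = start[j] + cnt[j];
  std::vector<int> pos(start.begin() + 1, start.end() - 1);
  for (int r = 0; r < n; ++r) if (idx[r] > 0) items[pos[idx[r] - 1]++] = r;
}

// [[Rcpp::export(name = ".gibbs_load_core")]]
List gibbs_load_core(NumericVector y,
                     NumericMatrix X,
                     IntegerVector zidx,
                     IntegerVector hysIdx, int nHys,
                     IntegerVector peIdx, int nPe,
                     IntegerVector Kp, IntegerVector Ki, NumericVector Kx,
                     IntegerVector Hp, IntegerVector Hi, NumericVector Hx,
                     int q,
                     int niter, int burnin, int thin,
                     NumericVector vstart, double sh2s, double sp2s, double se2s,
                     bool updateVar, bool keepEffects, double dfAdjust) {
  const int n = y.size();
  const int p = X.ncol();
  if (burnin >= niter) stop("burnin must be smaller than niter");

  // state
  std::vector<double> theta(p, 0.0), hEff(nHys, 0.0), pEff(nPe, 0.0);
  std::vector<double> u(q, 0.0), iv(q, 0.0), e(y.begin(), y.end());
  double v11 = vstart[0], v12 = vstart[1], v22 = vstart[2];
  double sh2 = sh2s, sp2 = sp2s, se2 = se2s;

  // precomputations
  std::vector<double> xtx(p, 0.0);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int r = 0; r < n; ++r) s += X(r, k) * X(r, k);
    xtx[k] = s;
  }
  std::vector<int> hStart, hItems, pStart, pItems, recStart, recItems;
  levelLists(hysIdx, nHys, hStart, hItems);
  levelLists(peIdx, nPe, pStart, pItems);
  levelLists(zidx, q, recStart, recItems);

  std::vector<double> zz(q, 0.0), kk(q, 0.0), zk(q, 0.0);
  for (int j = 0; j < q; ++j) {
    zz[j] = (double)(recStart[j + 2] - recStart[j + 1]);
    double s2 = 0.0, sx = 0.0;
    for (int t = Kp[j]; t < Kp[j + 1]; ++t) {
      s2 += Kx[t] * Kx[t];
      if (zidx[Ki[t]] - 1 == j) sx += Kx[t];
    }
    kk[j] = s2; zk[j] = sx;
  }

  // storage
  const int nsave = (niter - burnin - 1) / thin + 1;
  const int ncolS = 6 + p;
  NumericMatrix samples(nsave, ncolS);
  NumericMatrix uKeep, iKeep;
  if (keepEffects) { uKeep = NumericMatrix(nsave, q); iKeep = NumericMatrix(nsave, q); }
  std::vector<double> uM(q, 0.0), uS(q, 0.0), iM(q, 0.0), iS(q, 0.0);
  int saved = 0;

  for (int it = 0; it < niter; ++it) {
    // ---- dense fixed-effect columns (flat priors, single site) ----
    for (int k = 0; k < p; ++k) {
      if (xtx[k] <= 0.0) continue;
      double dot = 0.0;
      for (int r = 0; r < n; ++r) dot += X(r, k) * e[r];
      const double mean = (dot + xtx[k] * theta[k]) / xtx[k];
      const double neu = mean + norm_rand() * std::sqrt(se2 / xtx[k]);
      const double del = theta[k] - neu;
      if (del != 0.0) for (int r = 0; r < n; ++r) e[r] += X(r, k) * del;
      theta[k] = neu;
    }
    // ---- HYS levels: N(0, sigma_h2) prior ----
    for (int l = 0; l < nHys; ++l) {
      const int a = hStart[l + 1], b = hStart[l + 2];
      const double cnt = (double)(b - a);
      if (cnt == 0.0) { hEff[l] = norm_rand() * std::sqrt(sh2); continue; }
      double dot = 0.0;
      for (int t = a; t < b; ++t) dot += e[hItems[t]];
      const double prec = cnt / se2 + 1.0 / sh2;
      const double mean = (dot + cnt * hEff[l]) / se2 / prec;
      const double neu = mean + norm_rand() / std::sqrt(prec);
      const double del = hEff[l] - neu;
      for (int t = a; t < b; ++t) e[hItems[t]] += del;
      hEff[l] = neu;
    }
    // ---- permanent-environment levels: N(0, sigma_p2) prior ----
    for (int l = 0; l < nPe; ++l) {
      const int a = pStart[l + 1], b = pStart[l + 2];
      const double cnt = (double)(b - a);
      if (cnt == 0.0) { pEff[l] = norm_rand() * std::sqrt(sp2); continue; }
      double dot = 0.0;
      for (int t = a; t < b; ++t) dot += e[pItems[t]];
      const double prec = cnt / se2 + 1.0 / sp2;
      const double mean = (dot + cnt * pEff[l]) / se2 / prec;
      const double neu = mean + norm_rand() / std::sqrt(prec);
      const double del = pEff[l] - neu;
      for (int t = a; t < b; ++t) e[pItems[t]] += del;
      pEff[l] = neu;
    }

    // ---- (u_j, i_j) joint 2-blocks ----
    double iv11, iv12, iv22;
    inv2x2(v11, v12, v22, iv11, iv12, iv22);
    for (int j = 0; j < q; ++j) {
      double ru = zz[j] * u[j] + zk[j] * iv[j];
      for (int t = recStart[j + 1]; t < recStart[j + 2]; ++t) ru += e[recItems[t]];
      double ri = zk[j] * u[j] + kk[j] * iv[j];
      for (int t = Kp[j]; t < Kp[j + 1]; ++t) ri += Kx[t] * e[Ki[t]];
      double hu = 0.0, hi = 0.0, hjj = 0.0;
      for (int t = Hp[j]; t < Hp[j + 1]; ++t) {
        const int r = Hi[t];
        hu += Hx[t] * u[r]; hi += Hx[t] * iv[r];
        if (r == j) hjj = Hx[t];
      }
      const double au = hu - hjj * u[j];
      const double ai = hi - hjj * iv[j];
      const double c11 = zz[j] / se2 + hjj * iv11;
      const double c12 = zk[j] / se2 + hjj * iv12;
      const double c22 = kk[j] / se2 + hjj * iv22;
      const double r1 = ru / se2 - (iv11 * au + iv12 * ai);
      const double r2 = ri / se2 - (iv12 * au + iv22 * ai);
      double s11, s12, s22;
      inv2x2(c11, c12, c22, s11, s12, s22);
      const double m1 = s11 * r1 + s12 * r2;
      const double m2 = s12 * r1 + s22 * r2;
      const double l11 = std::sqrt(s11);
      const double l21 = s12 / l11;
      const double l22 = std::sqrt(s22 - l21 * l21);
      const double z1 = norm_rand(), z2 = norm_rand();
      const double nu = m1 + l11 * z1;
      const double ni = m2 + l21 * z1 + l22 * z2;
      const double du = u[j] - nu, di = iv[j] - ni;
      if (du != 0.0)
        for (int t = recStart[j + 1]; t < recStart[j + 2]; ++t) e[recItems[t]] += du;
      if (di != 0.0)
        for (int t = Kp[j]; t < Kp[j + 1]; ++t) e[Ki[t]] += Kx[t] * di;
      u[j] = nu; iv[j] = ni;
    }

    // ---- variance components ----
    if (updateVar) {
      if (nHys > 2) {
        double ss = 0.0;
        for (int l = 0; l < nHys; ++l) ss += hEff[l] * hEff[l];
        sh2 = ss / Rf_rchisq((double)(nHys - 2));
      }
      if (nPe > 2) {
        double ss = 0.0;
        for (int l = 0; l < nPe; ++l) ss += pEff[l] * pEff[l];
        sp2 = ss / Rf_rchisq((double)(nPe - 2));
      }
      if (q > 4) {
        double suu = 0.0, sui = 0.0, sii = 0.0;
        for (int j = 0; j < q; ++j) {
          double t1 = 0.0, t2 = 0.0;
          for (int t = Hp[j]; t < Hp[j + 1]; ++t) {
            t1 += Hx[t] * u[Hi[t]];
            t2 += Hx[t] * iv[Hi[t]];
          }
          suu += u[j] * t1; sui += u[j] * t2; sii += iv[j] * t2;
        }
        const double df = (double)q - 3.0 + dfAdjust;
        // V ~ IW(df, S): draw W ~ Wishart(df, S^-1) by Bartlett, V = W^-1
        double si11, si12, si22;
        inv2x2(suu, sui, sii, si11, si12, si22);
        const double L11 = std::sqrt(si11);
        const double L21 = si12 / L11;
        const double L22 = std::sqrt(si22 - L21 * L21);
        const double a11 = std::sqrt(Rf_rchisq(df));
        const double a21 = norm_rand();
        const double a22 = std::sqrt(Rf_rchisq(df - 1.0));
        const double b11 = L11 * a11;
        const double b21 = L21 * a11 + L22 * a21;
        const double b22 = L22 * a22;
        const double w11 = b11 * b11;
        const double w12 = b11 * b21;
        const double w22 = b21 * b21 + b22 * b22;
        inv2x2(w11, w12, w22, v11, v12, v22);
        if (!std::isfinite(v11) || !std::isfinite(v22) || v11 <= 0.0 || v22 <= 0.0 ||
            v11 * v22 - v12 * v12 <= 0.0) {
          stop("non-positive-definite V draw at iteration %d; check model information", it + 1);
        }
      }
      double sse = 0.0;
      for (int r = 0; r < n; ++r) sse += e[r] * e[r];
      se2 = sse / Rf_rchisq((double)(n - 2));
      if (!std::isfinite(se2) || se2 > 1e14) {
        stop("sampler diverged (residual variance overflow) at iteration %d", it + 1);
      }
    }

    // ---- periodic residual refresh against drift ----
    if ((it + 1) % 500 == 0) {
      for (int r = 0; r < n; ++r) {
        double f = 0.0;
        for (int k = 0; k < p; ++k) f += X(r, k) * theta[k];
        if (nHys > 0 && hysIdx[r] > 0) f += hEff[hysIdx[r] - 1];
        if (nPe > 0 && peIdx[r] > 0) f += pEff[peIdx[r] - 1];
        e[r] = y[r] - f - (q > 0 ? u[zidx[r] - 1] : 0.0);
      }
      for (int j = 0; j < q; ++j)
        for (int t = Kp[j]; t < Kp[j + 1]; ++t) e[Ki[t]] -= Kx[t] * iv[j];
    }

    // ---- save ----
    if (it >= burnin && (it - burnin) % thin == 0) {
      samples(saved, 0) = v11; samples(saved, 1) = v12; samples(saved, 2) = v22;
      samples(saved, 3) = sh2; samples(saved, 4) = sp2; samples(saved, 5) = se2;
      for (int k = 0; k < p; ++k) samples(saved, 6 + k) = theta[k];
      const double cnt = saved + 1.0;
      for (int j = 0; j < q; ++j) {
        double d1 = u[j] - uM[j]; uM[j] += d1 / cnt; uS[j] += d1 * (u[j] - uM[j]);
        double d2 = iv[j] - iM[j]; iM[j] += d2 / cnt; iS[j] += d2 * (iv[j] - iM[j]);
      }
      if (keepEffects) {
        for (int j = 0; j < q; ++j) { uKeep(saved, j) = u[j]; iKeep(saved, j) = iv[j]; }
      }
      ++saved;
    }
  }

  NumericVector uMean(q), uPSD(q), iMean(q), iPSD(q);
  for (int j = 0; j < q; ++j) {
    uMean[j] = uM[j]; iMean[j] = iM[j];
    uPSD[j] = saved > 1 ? std::sqrt(uS[j] / (saved - 1)) : NA_REAL;
    iPSD[j] = saved > 1 ? std::sqrt(iS[j] / (saved - 1)) : NA_REAL;
  }
  List out = List::create(
    _["samples"] = samples, _["nSaved"] = saved,
    _["uMean"] = uMean, _["uPSD"] = uPSD,
    _["iMean"] = iMean, _["iPSD"] = iPSD);
  if (keepEffects) { out["uSamples"] = uKeep; out["iSamples"] = iKeep; }
  return out;
}
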