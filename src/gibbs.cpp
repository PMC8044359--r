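#include <Rcpp.h>
using namespace Rcpp;

// Scaled inverse chi-square draw: df * scale / chisq(df)
static inline double rinvchisq(double df, double scale) {
  double x = df * scale / R::rchisq(df);
  return x < 1e-10 ? 1e-10 : x; // variance floor
}

// Inverse-Gaussian (Wald) draw, Michael-Schucany-Haas
static inline double rinvgauss(double mu, double lambda) {
  double z = R::norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static inline double dotcol(const NumericMatrix& W, int p, const NumericVector& e) {
  double s = 0.0;
  int n = W.nrow();
  const double* wp = &W(0, p);
  for (int i = 0; i < n; ++i) s += wp[i] * e[i];
  return s;
}

static inline void axpycol(const NumericMatrix& W, int p, double alpha, NumericVector& e) {
  int n = W.nrow();
  const double* wp = &W(0, p);
  for (int i = 0; i < n; ++i) e[i] += alpha * wp[i];
}

// Single-site Gibbs sampler for whole-genome regression under the five
// Bayesian-alphabet priors. method: 1=BRR, 2=BayesA, 3=BayesB, 4=BayesCpi,
// 5=BL (Park-Casella). pi parameterized as P(point mass at zero).
// [[Rcpp::export]]
List wgr_gibbs_cpp(NumericVector y, NumericMatrix W, int method,
                   int niter, int burnin, int thin,
                   double dfMarker, double scaleMarker,
                   double dfE, double scaleE,
                   double piA, double piB,
                   bool fixVarE, double varEFix,
                   bool fixVarMarker, double varMarkerFix,
                   double blShape, double blRate,
                   bool keepChain) {
  int n = y.size(), P = W.ncol();
  NumericVector css(P);
  for (int p = 0; p < P; ++p) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, p) * W(i, p);
    css[p] = s;
  }

  double mu = mean(y);
  NumericVector a(P, 0.0);
  NumericVector e = clone(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;

  double varE = fixVarE ? varEFix : scaleE;
  if (varE <= 0) varE = var(y) / 2.0;
  double varA = fixVarMarker ? varMarkerFix : scaleMarker;
  NumericVector sig2p(P, scaleMarker);          // BayesA/B per-marker variances
  NumericVector tau2(P, 1.0);                   // BL local scales
  double lambda2 = blShape / blRate;            // BL global shrinkage, prior mean
  if (!R_finite(lambda2) || lambda2 <= 0) lambda2 = 1.0;
  LogicalVector incl(P, true);
  double pi0 = 0.5;                             // P(effect == 0)

  // accumulators
  NumericVector postA(P, 0.0), postIncl(P, 0.0);
  double postMu = 0, postVarE = 0, postPi = 0, postVarA = 0;
  int nKeep = 0;
  int nChain = keepChain ? ((niter - burnin) / thin + 1) : 0;
  NumericMatrix chainVarE(nChain, keepChain ? 1 : 0);

  for (int it = 1; it <= niter; ++it) {
    // intercept, flat prior
    double mbar = mean(e);
    double muNew = R::rnorm(mu + mbar, std::sqrt(varE / n));
    for (int i = 0; i < n; ++i) e[i] -= (muNew - mu);
    mu = muNew;

    int nIncl = 0;
    double ssIncl = 0.0; // sum a^2 over markers carrying an effect (BRR/Cpi)
    for (int p = 0; p < P; ++p) {
      double aOld = a[p];
      double xe = dotcol(W, p, e) + css[p] * aOld; // w_p' (y - all other terms)
      double v; // conditional prior variance of a_p
      switch (method) {
      case 1: v = varA; break;
      case 2: v = sig2p[p]; break;
      case 3: v = sig2p[p]; break;
      case 4: v = varA; break;
      default: v = tau2[p] * varE; break;
      }
      bool in = true;
      if (method == 3 || method == 4) {
        double u = v / varE;
        double logLR = -0.5 * std::log1p(u * css[p]) +
          0.5 * xe * xe * u / (varE * (1.0 + u * css[p]));
        double logOdds = std::log(1.0 - pi0) - std::log(pi0) + logLR;
        double pIn = 1.0 / (1.0 + std::exp(-logOdds));
        in = (R::unif_rand() < pIn);
      }
      double aNew = 0.0;
      if (in) {
        double C = css[p] + varE / v;
        aNew = R::rnorm(xe / C, std::sqrt(varE / C));
        ++nIncl;
        ssIncl += aNew * aNew;
      }
      if (aNew != aOld) axpycol(W, p, aOld - aNew, e);
      a[p] = aNew;
      incl[p] = in;

      // per-marker variance updates
      if (method == 2) {
        sig2p[p] = rinvchisq(dfMarker + 1.0,
                             (aNew * aNew + dfMarker * scaleMarker) / (dfMarker + 1.0));
      } else if (method == 3) {
        if (in) {
          sig2p[p] = rinvchisq(dfMarker + 1.0,
                               (aNew * aNew + dfMarker * scaleMarker) / (dfMarker + 1.0));
        } else {
          sig2p[p] = rinvchisq(dfMarker, scaleMarker); // prior draw
        }
      } else if (method == 5) {
        double a2 = aNew * aNew;
        if (a2 < 1e-12) a2 = 1e-12;
        double muIG = std::sqrt(lambda2 * varE / a2);
        if (muIG > 1e8) muIG = 1e8;
        double invTau2 = rinvgauss(muIG, lambda2);
        tau2[p] = 1.0 / std::max(invTau2, 1e-10);
      }
    }

    // hyper-parameters
    if (method == 1 && !fixVarMarker) {
      double ss = 0.0;
      for (int p = 0; p < P; ++p) ss += a[p] * a[p];
      varA = rinvchisq(dfMarker + P, (ss + dfMarker * scaleMarker) / (dfMarker + P));
    } else if (method == 4 && !fixVarMarker) {
      varA = rinvchisq(dfMarker + nIncl,
                       (ssIncl + dfMarker * scaleMarker) / (dfMarker + nIncl));
    }
    if (method == 3 || method == 4) {
      pi0 = R::rbeta(piA + (P - nIncl), piB + nIncl);
    }
    if (method == 5) {
      double st = 0.0;
      for (int p = 0; p < P; ++p) st += tau2[p];
      lambda2 = R::rgamma(P + blShape, 1.0 / (0.5 * st + blRate));
      if (lambda2 < 1e-10) lambda2 = 1e-10;
    }
    if (!fixVarE) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      if (method == 5) {
        // a_p | varE prior contributes P extra df
        double sa = 0.0;
        for (int p = 0; p < P; ++p) sa += a[p] * a[p] / tau2[p];
        varE = rinvchisq(n + P + dfE, (sse + sa + dfE * scaleE) / (n + P + dfE));
      } else {
        varE = rinvchisq(n + dfE, (sse + dfE * scaleE) / (n + dfE));
      }
    }

    if (it > burnin && ((it - burnin) % thin == 0)) {
      ++nKeep;
      for (int p = 0; p < P; ++p) {
        postA[p] += a[p];
        postIncl[p] += incl[p] ? 1.0 : 0.0;
      }
      postMu += mu;
      postVarE += varE;
      postPi += pi0;
      postVarA += varA;
      if (keepChain && nKeep <= nChain) chainVarE(nKeep - 1, 0) = varE;
    }
  }

  for (int p = 0; p < P; ++p) { postA[p] /= nKeep; postIncl[p] /= nKeep; }
  List out = List::create(
    _["effects"] = postA,
    _["mu"] = postMu / nKeep,
    _["varE"] = postVarE / nKeep,
    _["varMarker"] = postVarA / nKeep,
    _["pi"] = postPi / nKeep,
    _["inclusionProb"] = postIncl,
    _["nSamples"] = nKeep);
  if (keepChain) out["chainVarE"] = chainVarE;
  return out;
}

// Single-site Gibbs for linear mixed kernels in the eigenbasis.
// B: n_obs x M design; group[j]: 0 => flat-prior fixed effect column,
// g in 1..T => random column with prior var sigma2[g] * lam[j].
// [[Rcpp::export]]
List kernel_gibbs_cpp(NumericVector y, NumericMatrix B, IntegerVector group,
                      NumericVector lam, int nGroups,
                      double df, NumericVector scaleG,
                      double dfE, double scaleE,
                      int niter, int burnin, int thin,
                      bool fixVarE, double varEFix,
                      LogicalVector fixVarG, NumericVector varGFix) {
  int n = y.size(), M = B.ncol();
  NumericVector css(M);
  for (int j = 0; j < M; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += B(i, j) * B(i, j);
    css[j] = s;
  }
  NumericVector g(M, 0.0);
  NumericVector e = clone(y);
  double varE = fixVarE ? varEFix : scaleE;
  if (varE <= 0) varE = var(y) / 2.0;
  NumericVector sig2(nGroups);
  for (int t = 0; t < nGroups; ++t)
    sig2[t] = fixVarG[t] ? varGFix[t] : scaleG[t];

  NumericVector postG(M, 0.0), postSig2(nGroups, 0.0);
  double postVarE = 0.0;
  int nKeep = 0;

  IntegerVector mG(nGroups, 0);
  for (int j = 0; j < M; ++j) if (group[j] > 0) mG[group[j] - 1]++;

  for (int it = 1; it <= niter; ++it) {
    for (int j = 0; j < M; ++j) {
      if (css[j] <= 0) continue;
      double gOld = g[j];
      double xe = dotcol(B, j, e) + css[j] * gOld;
      double C, gNew;
      if (group[j] == 0) {
        C = css[j]; // flat prior
      } else {
        double v = sig2[group[j] - 1] * lam[j];
        if (v < 1e-12) v = 1e-12;
        C = css[j] + varE / v;
      }
      gNew = R::rnorm(xe / C, std::sqrt(varE / C));
      if (gNew != gOld) axpycol(B, j, gOld - gNew, e);
      g[j] = gNew;
    }
    for (int t = 0; t < nGroups; ++t) {
      if (fixVarG[t] || mG[t] == 0) continue;
      double ss = 0.0;
      for (int j = 0; j < M; ++j)
        if (group[j] == t + 1 && lam[j] > 1e-12) ss += g[j] * g[j] / lam[j];
      sig2[t] = rinvchisq(df + mG[t], (ss + df * scaleG[t]) / (df + mG[t]));
    }
    if (!fixVarE) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      varE = rinvchisq(n + dfE, (sse + dfE * scaleE) / (n + dfE));
    }
    if (it > burnin && ((it - burnin) % thin == 0)) {
      ++nKeep;
      for (int j = 0; j < M; ++j) postG[j] += g[j];
      for (int t = 0; t < nGroups; ++t) postSig2[t] += sig2[t];
      postVarE += varE;
    }
  }
  for (int j = 0; j < M; ++j) postG[j] /= nKeep;
  for (int t = 0; t < nGroups; ++t) postSig2[t] /= nKeep;
  return List::create(
    _["coef"] = postG,
    _["sigma2"] = postSig2,
    _["varE"] = postVarE / nKeep,
    _["nSamples"] = nKeep);
}
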