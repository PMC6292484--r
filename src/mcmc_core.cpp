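// Core MCMC loop for Brownian-motion-with-trend trait evolution on trees
// with fossil tips: birth-death model search over rate/trend shifts,
// Metropolis-Hastings updates for continuous parameters, conjugate Gibbs
// sweeps for ancestral states. Mirrors the R-level operations exactly; the
// R implementations are the reference used in the test suite.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LN2PI = 1.8378770664093454836;

struct Chain {
  int M, N, root;
  std::vector<int> parent, child1, child2, postorder;
  std::vector<double> blen;
  std::vector<bool> observed;
  std::vector<double> state;

  // shift configuration
  double rateBg, trendBg;
  std::vector<int> rAnch, tAnch;       // anchor nodes (0-based)
  std::vector<double> rVal, tVal;
  std::vector<bool> isRAnch, isTAnch;
  // per-branch resolved parameters (indexed by child node)
  std::vector<double> rateVal, trendVal;
  std::vector<int> rateAnc, trendAnc;  // -1 = background

  bool priorOnly, trendEnabled, stephens;
  double ratePriorRate, trendPriorSD, trendProposalSD, poissonRate;
  double lambdaMult, wRoot, wTrend;
  int maxEvents;

  void resolve() {
    // preorder = reverse postorder; parent resolved before child
    rateVal[root] = rateBg; trendVal[root] = trendBg;
    rateAnc[root] = -1; trendAnc[root] = -1;
    for (int k = (int)postorder.size() - 1; k >= 0; --k) {
      int i = postorder[k];
      if (i == root) continue;
      int p = parent[i];
      if (isRAnch[i]) {
        for (size_t j = 0; j < rAnch.size(); ++j)
          if (rAnch[j] == i) { rateVal[i] = rVal[j]; break; }
        rateAnc[i] = i;
      } else { rateVal[i] = rateVal[p]; rateAnc[i] = rateAnc[p]; }
      if (isTAnch[i]) {
        for (size_t j = 0; j < tAnch.size(); ++j)
          if (tAnch[j] == i) { trendVal[i] = tVal[j]; break; }
        trendAnc[i] = i;
      } else { trendVal[i] = trendVal[p]; trendAnc[i] = trendAnc[p]; }
    }
  }

  // log-density of the branch above node i, with explicit parameters
  inline double bllWith(int i, double s2, double mu) const {
    double t = blen[i];
    double d = state[i] - state[parent[i]] - mu * t;
    double v = s2 * t;
    return -0.5 * (LN2PI + std::log(v) + d * d / v);
  }
  inline bool hasBranch(int i) const { return i != root && blen[i] > 0.0; }
  inline double bll(int i) const { return bllWith(i, rateVal[i], trendVal[i]); }

  double totalLogLik() const {
    if (priorOnly) return 0.0;
    double s = 0.0;
    for (int i = 0; i < M; ++i) if (hasBranch(i)) s += bll(i);
    return s;
  }

  double logPrior() const {
    double lp = R::dexp(rateBg, 1.0 / ratePriorRate, 1);
    for (size_t j = 0; j < rVal.size(); ++j)
      lp += R::dexp(rVal[j], 1.0 / ratePriorRate, 1);
    if (trendEnabled) {
      lp += R::dnorm(trendBg, 0.0, trendPriorSD, 1);
      for (size_t j = 0; j < tVal.size(); ++j)
        lp += R::dnorm(tVal[j], 0.0, trendPriorSD, 1);
    }
    lp += R::dpois((double)(rVal.size() + tVal.size()), poissonRate, 1);
    return lp;
  }

  // ---- MH updates -------------------------------------------------------
  int rateProp = 0, rateAcc = 0, trendProp = 0, trendAcc = 0,
      rootProp = 0, rootAcc = 0;

  void updateRateClass(int anchor, double &value) {
    // anchor = -1 for the background class
    double m = std::exp(lambdaMult * (unif_rand() - 0.5));
    double prop = value * m;
    double dll = 0.0;
    if (!priorOnly) {
      // only the variance scale changes: dll collapses to a count and a
      // quadratic sum, with a single log
      int nb = 0; double q = 0.0;
      for (int i = 0; i < M; ++i)
        if (hasBranch(i) && rateAnc[i] == anchor) {
          double t = blen[i];
          double d = state[i] - state[parent[i]] - trendVal[i] * t;
          q += d * d / t; ++nb;
        }
      dll = -0.5 * (nb * std::log(prop / value) +
                    q * (1.0 / prop - 1.0 / value));
    }
    double dlp = -ratePriorRate * (prop - value);
    double la = dll + dlp + std::log(m);
    ++rateProp;
    if (la >= 0 || std::log(unif_rand()) < la) {
      ++rateAcc;
      value = prop;
      for (int i = 0; i < M; ++i) if (rateAnc[i] == anchor) rateVal[i] = prop;
      if (anchor == -1) rateVal[root] = prop;
    }
  }

  void updateTrendClass(int anchor, double &value) {
    double prop = value + (unif_rand() - 0.5) * wTrend;
    double dll = 0.0;
    if (!priorOnly)
      for (int i = 0; i < M; ++i)
        if (hasBranch(i) && trendAnc[i] == anchor) {
          double t = blen[i], v = rateVal[i] * t;
          double d = state[i] - state[parent[i]] - value * t;
          double dn = d - (prop - value) * t;
          dll += -0.5 * (dn * dn - d * d) / v;  // variance unchanged
        }
    double dlp = -(prop * prop - value * value) / (2.0 * trendPriorSD * trendPriorSD);
    double la = dll + dlp;
    ++trendProp;
    if (la >= 0 || std::log(unif_rand()) < la) {
      ++trendAcc;
      value = prop;
      for (int i = 0; i < M; ++i) if (trendAnc[i] == anchor) trendVal[i] = prop;
      if (anchor == -1) trendVal[root] = prop;
    }
  }

  void updateRoot() {
    if (observed[root]) return;
    double prop = state[root] + (unif_rand() - 0.5) * wRoot;
    double dll = 0.0;
    if (!priorOnly) {
      double old = state[root];
      int kids[2] = { child1[root], child2[root] };
      for (int k = 0; k < 2; ++k) {
        int c = kids[k];
        if (c < 0 || blen[c] <= 0) continue;
        double t = blen[c], v = rateVal[c] * t;
        double dNew = state[c] - prop - trendVal[c] * t;
        double dOld = state[c] - old - trendVal[c] * t;
        dll += -0.5 * (dNew * dNew - dOld * dOld) / v;
      }
    }
    ++rootProp;
    if (dll >= 0 || std::log(unif_rand()) < dll) { ++rootAcc; state[root] = prop; }
  }

  // ---- Gibbs sweep over ancestral states --------------------------------
  void gibbsSweep() {
    for (size_t k = 0; k < postorder.size(); ++k) {
      int i = postorder[k];
      if (i == root || child1[i] < 0 || observed[i]) continue;
      double prec = 0.0, wsum = 0.0;
      if (blen[i] > 0) {
        double v = rateVal[i] * blen[i];
        prec += 1.0 / v;
        wsum += (state[parent[i]] + trendVal[i] * blen[i]) / v;
      }
      int kids[2] = { child1[i], child2[i] };
      for (int c = 0; c < 2; ++c) {
        int j = kids[c];
        if (j < 0 || blen[j] <= 0) continue;
        double v = rateVal[j] * blen[j];
        prec += 1.0 / v;
        wsum += (state[j] - trendVal[j] * blen[j]) / v;
      }
      if (prec <= 0) continue;
      state[i] = wsum / prec + norm_rand() / std::sqrt(prec);
    }
  }

  // ---- birth-death model search -----------------------------------------
  double deathRateOf(bool isRate, int j) {
    int a = isRate ? rAnch[j] : tAnch[j];
    double v = isRate ? rVal[j] : tVal[j];
    int p = parent[a];
    double pv = isRate ? rateVal[p] : trendVal[p];
    double logd = 0.0;
    if (!priorOnly) {
      if (isRate) {
        int nb = 0; double q = 0.0;
        for (int i = 0; i < M; ++i)
          if (hasBranch(i) && rateAnc[i] == a) {
            double t = blen[i];
            double d = state[i] - state[parent[i]] - trendVal[i] * t;
            q += d * d / t; ++nb;
          }
        logd = -0.5 * (nb * std::log(pv / v) + q * (1.0 / pv - 1.0 / v));
      } else {
        for (int i = 0; i < M; ++i)
          if (hasBranch(i) && trendAnc[i] == a) {
            double t = blen[i], var = rateVal[i] * t;
            double d = state[i] - state[parent[i]] - v * t;
            double dn = d + (v - pv) * t;
            logd += -0.5 * (dn * dn - d * d) / var;
          }
      }
    }
    if (stephens) {
      if (isRate)
        logd += R::dexp(v, rateBg, 1) - R::dexp(v, 1.0 / ratePriorRate, 1);
      else
        logd += R::dnorm(v, 0.0, trendProposalSD, 1) -
                R::dnorm(v, 0.0, trendPriorSD, 1);
    }
    if (logd > 50.0) logd = 50.0;
    return std::exp(logd);
  }

  bool birth() {
    bool isRate = !(trendEnabled && unif_rand() < 0.5);
    std::vector<bool> &taken = isRate ? isRAnch : isTAnch;
    int K = 0;
    for (int i = 0; i < M; ++i) if (i != root && !taken[i]) ++K;
    if (K == 0) return false;
    int pick = (int)(unif_rand() * K);
    if (pick >= K) pick = K - 1;
    int a = -1;
    for (int i = 0; i < M; ++i) {
      if (i == root || taken[i]) continue;
      if (pick-- == 0) { a = i; break; }
    }
    double v = isRate ? exp_rand() * rateBg : norm_rand() * trendProposalSD;
    if (isRate) { rAnch.push_back(a); rVal.push_back(v); isRAnch[a] = true; }
    else        { tAnch.push_back(a); tVal.push_back(v); isTAnch[a] = true; }
    resolve();
    return true;
  }

  void kill(bool isRate, int j) {
    if (isRate) {
      isRAnch[rAnch[j]] = false;
      rAnch.erase(rAnch.begin() + j); rVal.erase(rVal.begin() + j);
    } else {
      isTAnch[tAnch[j]] = false;
      tAnch.erase(tAnch.begin() + j); tVal.erase(tVal.begin() + j);
    }
    resolve();
  }

  bool bdStep() {
    double tAcc = 0.0;
    int nEvents = 0;
    std::vector<double> dr, dt;
    for (;;) {
      int kr = (int)rAnch.size(), kt = (int)tAnch.size();
      dr.resize(kr); dt.resize(kt);
      double sum = 0.0;
      for (int j = 0; j < kr; ++j) { dr[j] = deathRateOf(true, j); sum += dr[j]; }
      for (int j = 0; j < kt; ++j) { dt[j] = deathRateOf(false, j); sum += dt[j]; }
      double R = 1.0 + sum;
      tAcc += exp_rand() / R;
      if (tAcc > 1.0) return true;
      if (++nEvents > maxEvents) return false;
      double u = unif_rand() * R;
      if (u < 1.0) { birth(); continue; }
      u -= 1.0;
      int j = 0; bool isRate = true;
      for (j = 0; j < kr; ++j) { if (u < dr[j]) break; u -= dr[j]; }
      if (j == kr) { isRate = false; for (j = 0; j < kt; ++j) { if (u < dt[j]) break; u -= dt[j]; } if (j == kt) j = kt - 1; }
      kill(isRate, j);
    }
  }
};

// [[Rcpp::export]]
List chain_mcmc_cpp(int N, int root1,
                    IntegerVector parent1, IntegerVector child1a,
                    IntegerVector child2a, NumericVector blen,
                    IntegerVector postorder1, LogicalVector observed,
                    NumericVector initStates,
                    double sigma2Init, bool trendEnabled, bool priorOnly,
                    bool stephens, double ratePriorRate, double trendPriorSD,
                    double trendProposalSD, double poissonRate,
                    double dMult, double wRoot, double wTrend,
                    int iterations, int sampleEvery, int maxEvents) {
  Chain ch;
  ch.M = initStates.size(); ch.N = N; ch.root = root1 - 1;
  ch.parent.resize(ch.M); ch.child1.resize(ch.M); ch.child2.resize(ch.M);
  ch.blen.resize(ch.M); ch.observed.resize(ch.M); ch.state.resize(ch.M);
  for (int i = 0; i < ch.M; ++i) {
    ch.parent[i] = parent1[i] == NA_INTEGER ? -1 : parent1[i] - 1;
    ch.child1[i] = child1a[i] == NA_INTEGER ? -1 : child1a[i] - 1;
    ch.child2[i] = child2a[i] == NA_INTEGER ? -1 : child2a[i] - 1;
    ch.blen[i] = NumericVector::is_na(blen[i]) ? 0.0 : blen[i];
    ch.observed[i] = observed[i];
    ch.state[i] = initStates[i];
  }
  ch.postorder.resize(ch.M);
  for (int i = 0; i < ch.M; ++i) ch.postorder[i] = postorder1[i] - 1;
  ch.rateBg = sigma2Init; ch.trendBg = 0.0;
  ch.isRAnch.assign(ch.M, false); ch.isTAnch.assign(ch.M, false);
  ch.rateVal.assign(ch.M, ch.rateBg); ch.trendVal.assign(ch.M, 0.0);
  ch.rateAnc.assign(ch.M, -1); ch.trendAnc.assign(ch.M, -1);
  ch.priorOnly = priorOnly; ch.trendEnabled = trendEnabled;
  ch.stephens = stephens; ch.ratePriorRate = ratePriorRate;
  ch.trendPriorSD = trendPriorSD; ch.trendProposalSD = trendProposalSD;
  ch.poissonRate = poissonRate;
  ch.lambdaMult = 2.0 * std::log(dMult); ch.wRoot = wRoot; ch.wTrend = wTrend;
  ch.maxEvents = maxEvents;
  ch.resolve();

  int nS = iterations / sampleEvery;
  NumericMatrix trace(nS, 8), states(nS, ch.M);
  List shifts(nS);
  int s = 0, nAborted = 0;

  for (int iter = 1; iter <= iterations; ++iter) {
    if (!ch.bdStep()) ++nAborted;
    ch.updateRateClass(-1, ch.rateBg);
    for (size_t j = 0; j < ch.rAnch.size(); ++j) ch.updateRateClass(ch.rAnch[j], ch.rVal[j]);
    // keep resolved background entries in sync after a background change
    if (trendEnabled) {
      ch.updateTrendClass(-1, ch.trendBg);
      for (size_t j = 0; j < ch.tAnch.size(); ++j) ch.updateTrendClass(ch.tAnch[j], ch.tVal[j]);
    }
    ch.updateRoot();
    ch.gibbsSweep();

    if (iter % sampleEvery == 0) {
      trace(s, 0) = iter;
      trace(s, 1) = ch.totalLogLik();
      trace(s, 2) = ch.logPrior();
      trace(s, 3) = (double)ch.rAnch.size();
      trace(s, 4) = (double)ch.tAnch.size();
      trace(s, 5) = ch.rateBg;
      trace(s, 6) = ch.trendBg;
      trace(s, 7) = ch.state[ch.root];
      for (int i = 0; i < ch.M; ++i) states(s, i) = ch.state[i];
      int k = (int)(ch.rAnch.size() + ch.tAnch.size());
      NumericMatrix sh(k, 3);
      int r = 0;
      for (size_t j = 0; j < ch.rAnch.size(); ++j, ++r) {
        sh(r, 0) = 0; sh(r, 1) = ch.rAnch[j] + 1; sh(r, 2) = ch.rVal[j];
      }
      for (size_t j = 0; j < ch.tAnch.size(); ++j, ++r) {
        sh(r, 0) = 1; sh(r, 1) = ch.tAnch[j] + 1; sh(r, 2) = ch.tVal[j];
      }
      shifts[s] = sh;
      ++s;
    }
  }

  return List::create(
    _["trace"] = trace, _["states"] = states, _["shifts"] = shifts,
    _["accept"] = NumericVector::create(
      _["rateProp"] = ch.rateProp, _["rateAcc"] = ch.rateAcc,
      _["trendProp"] = ch.trendProp, _["trendAcc"] = ch.trendAcc,
      _["rootProp"] = ch.rootProp, _["rootAcc"] = ch.rootAcc),
    _["abortedSweeps"] = nAborted);
}
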