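// Core numerical kernels: K80/F84 transition probabilities, Felsenstein
// pruning over compressed site patterns, and Metropolis-Hastings sweeps on
// (Theta, lambda, genealogy) used by both the tempered SMC sampler and the
// MCMC baseline. All randomness goes through R's RNG so set.seed() in R
// governs reproducibility.
//
// Nucleotide order throughout: A=0, C=1, G=2, T=3.
// Transitions: A<->G (purines), C<->T (pyrimidines).
//
// kappa convention (both models): expected transition/transversion ratio
// E[ts]/E[tv] under the stationary distribution. For K80 this gives
// per-unit rates alpha = kappa/(kappa+1) (transition) and
// beta = 1/(2*kappa+2) (each transversion), normalized so the expected
// number of substitutions per unit branch length is 1. For F84 the
// internal shape parameter kF is solved from (kappa, pi) in closed form;
// branch lengths are expected substitutions per site in both models.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Substitution models
// ---------------------------------------------------------------------------

// Fill P (row-major 4x4) with K80 transition probabilities for branch t.
static void k80_pmat(double kappa, double t, double *P) {
  // rates normalized to one expected substitution per unit time
  double beta = 1.0 / (2.0 * kappa + 2.0);
  double alpha = kappa / (kappa + 1.0);
  double e1 = std::exp(-4.0 * beta * t);
  double e2 = std::exp(-2.0 * (alpha + beta) * t);
  double psame = 0.25 + 0.25 * e1 + 0.5 * e2;
  double pts   = 0.25 + 0.25 * e1 - 0.5 * e2;
  double ptv   = 0.25 - 0.25 * e1;
  for (int i = 0; i < 16; i++) P[i] = ptv;
  P[0*4+0] = P[1*4+1] = P[2*4+2] = P[3*4+3] = psame;
  P[0*4+2] = P[2*4+0] = pts; // A<->G
  P[1*4+3] = P[3*4+1] = pts; // C<->T
}

// Solve the F84 shape parameter kF from the expected ts/tv ratio kappa.
// Returns false when the implied transition rates would be negative,
// i.e. (kappa, pi) lies outside the model's support.
static bool f84_shape(double kappa, const double *pi, double &kF) {
  double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
  if (piR <= 0.0 || piY <= 0.0) return false;
  double pAG = pi[0] * pi[2], pCT = pi[1] * pi[3];
  double denom = pAG / piR + pCT / piY;
  if (denom <= 0.0) return false;
  kF = (kappa * piR * piY - pAG - pCT) / denom;
  // transition rates carry factors (1 + kF/piR), (1 + kF/piY)
  if (1.0 + kF / piR <= 0.0 || 1.0 + kF / piY <= 0.0) return false;
  return true;
}

// F84 transition probabilities (a TN93 special case) for branch t.
// Returns false when (kappa, pi) is outside the support.
static bool f84_pmat(double kappa, const double *pi, double t, double *P) {
  double kF;
  if (!f84_shape(kappa, pi, kF)) return false;
  double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
  double aR0 = 1.0 + kF / piR, aY0 = 1.0 + kF / piY;
  // normalization: expected rate one substitution per unit time
  double mu = 2.0 * (pi[0] * pi[2] * aR0 + pi[1] * pi[3] * aY0 + piR * piY);
  double b = 1.0 / mu;
  double alphaR = b * aR0, alphaY = b * aY0, beta = b;
  double eB = std::exp(-beta * t);
  double eR = std::exp(-(piR * alphaR + piY * beta) * t);
  double eY = std::exp(-(piY * alphaY + piR * beta) * t);
  const bool purine[4] = {true, false, true, false};
  for (int i = 0; i < 4; i++) {
    bool iR = purine[i];
    double piC = iR ? piR : piY;      // class frequency of i
    double piO = iR ? piY : piR;      // other class
    double eC = iR ? eR : eY;         // class eigen-term
    for (int j = 0; j < 4; j++) {
      if (purine[j] != iR) {
        P[i*4+j] = pi[j] * (1.0 - eB); // transversion
      } else if (i == j) {
        double piPartner = piC - pi[i]; // the other base in i's class
        P[i*4+j] = pi[i] + pi[i] * (piO / piC) * eB + (piPartner / piC) * eC;
      } else {
        P[i*4+j] = pi[j] + pi[j] * (piO / piC) * eB - (pi[j] / piC) * eC;
      }
    }
  }
  return true;
}

// model: 0 = K80, 1 = F84
static bool pmat(int model, double kappa, const double *pi, double t,
                 double *P) {
  if (model == 0) { k80_pmat(kappa, t, P); return true; }
  return f84_pmat(kappa, pi, t, P);
}

//' @noRd
// [[Rcpp::export(name = ".transition_matrix_cpp")]]
NumericMatrix transition_matrix_cpp(int model, double kappa,
                                    NumericVector pi, double t) {
  if (t < 0) stop("branch length must be nonnegative");
  double P[16];
  double pivec[4] = {pi[0], pi[1], pi[2], pi[3]};
  if (!pmat(model, kappa, pivec, t, P))
    stop("(kappa, pi) outside the F84 support: implied transition rate negative");
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; i++)
    for (int j = 0; j < 4; j++) out(i, j) = P[i*4+j];
  return out;
}

// ---------------------------------------------------------------------------
// Pruning likelihood
// ---------------------------------------------------------------------------

// Generic rooted-tree pruning over compressed site patterns with per-node,
// per-pattern scaling. Nodes are 0-based; tips are 0..m-1; parent[root] < 0.
// tipLik is a 4 x m x npat array (column-major as passed from R).
// Edge length of node v is edgelen[v] (ignored for the root).
// Returns -Inf when (kappa, pi) is outside the model support.
static double pruning_core(int m, const std::vector<int> &parent,
                           const std::vector<double> &edgelen,
                           const double *tipLik, int npat,
                           const double *patCounts,
                           int model, double kappa, const double *pi) {
  int nnode = (int)parent.size();
  if (npat == 0) return 0.0;
  int root = -1;
  std::vector<int> child(2 * nnode, -1), nchild(nnode, 0);
  for (int v = 0; v < nnode; v++) {
    int p = parent[v];
    if (p < 0) { root = v; continue; }
    child[2 * p + nchild[p]++] = v;
  }
  // postorder via explicit stack
  std::vector<int> order; order.reserve(nnode);
  std::vector<int> stack; stack.reserve(nnode);
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    if (nchild[v] == 2) { stack.push_back(child[2*v]); stack.push_back(child[2*v+1]); }
  }
  std::reverse(order.begin(), order.end());

  std::vector<double> partial((size_t)nnode * 4 * npat);
  std::vector<double> logscale(npat, 0.0);
  double P1[16], P2[16];

  for (int oi = 0; oi < nnode; oi++) {
    int v = order[oi];
    double *Lv = &partial[(size_t)v * 4 * npat];
    if (nchild[v] == 0) {
      // tip: copy leaf partials (tips are 0..m-1 by construction)
      for (int p = 0; p < npat; p++)
        for (int x = 0; x < 4; x++)
          Lv[4 * p + x] = tipLik[4 * ((size_t)p * m + v) + x];
      continue;
    }
    int c1 = child[2*v], c2 = child[2*v+1];
    if (!pmat(model, kappa, pi, edgelen[c1], P1)) return NEG_INF;
    if (!pmat(model, kappa, pi, edgelen[c2], P2)) return NEG_INF;
    const double *L1 = &partial[(size_t)c1 * 4 * npat];
    const double *L2 = &partial[(size_t)c2 * 4 * npat];
    for (int p = 0; p < npat; p++) {
      const double *a = &L1[4*p], *b = &L2[4*p];
      double mx = 0.0;
      double *out = &Lv[4*p];
      for (int x = 0; x < 4; x++) {
        double s1 = P1[x*4+0]*a[0] + P1[x*4+1]*a[1] + P1[x*4+2]*a[2] + P1[x*4+3]*a[3];
        double s2 = P2[x*4+0]*b[0] + P2[x*4+1]*b[1] + P2[x*4+2]*b[2] + P2[x*4+3]*b[3];
        out[x] = s1 * s2;
        if (out[x] > mx) mx = out[x];
      }
      if (mx <= 0.0) return NEG_INF; // impossible pattern
      for (int x = 0; x < 4; x++) out[x] /= mx;
      logscale[p] += std::log(mx);
    }
  }
  // root: sum over states weighted by stationary distribution
  const double *Lr = &partial[(size_t)root * 4 * npat];
  double statpi[4];
  if (model == 0) { statpi[0]=statpi[1]=statpi[2]=statpi[3]=0.25; }
  else { statpi[0]=pi[0]; statpi[1]=pi[1]; statpi[2]=pi[2]; statpi[3]=pi[3]; }
  double ll = 0.0;
  for (int p = 0; p < npat; p++) {
    double s = statpi[0]*Lr[4*p] + statpi[1]*Lr[4*p+1] +
               statpi[2]*Lr[4*p+2] + statpi[3]*Lr[4*p+3];
    if (s <= 0.0) return NEG_INF;
    ll += patCounts[p] * (std::log(s) + logscale[p]);
  }
  return ll;
}

//' @noRd
// [[Rcpp::export(name = ".pruning_loglik_cpp")]]
double pruning_loglik_cpp(IntegerVector parent, NumericVector edgelen,
                          NumericVector tipLik, NumericVector patCounts,
                          int m, int model, double kappa, NumericVector pi) {
  int nnode = parent.size();
  std::vector<int> par(nnode);
  std::vector<double> el(nnode);
  for (int v = 0; v < nnode; v++) { par[v] = parent[v]; el[v] = edgelen[v]; }
  double pivec[4] = {pi[0], pi[1], pi[2], pi[3]};
  int npat = patCounts.size();
  return pruning_core(m, par, el, REAL(tipLik), npat, REAL(patCounts),
                      model, kappa, pivec);
}

// ---------------------------------------------------------------------------
// Coalescent prior
// ---------------------------------------------------------------------------

// log p(genealogy | theta) from node times (tips at 0), standard exponential
// density per epoch: sum_k [ log(k(k-1)/theta) - k(k-1) d_k / theta ].
static double coal_log_prior(int m, const std::vector<double> &inttimes,
                             double theta) {
  // inttimes: m-1 internal node times, any order
  std::vector<double> t(inttimes);
  std::sort(t.begin(), t.end());
  double lp = 0.0, prev = 0.0;
  for (int i = 0; i < m - 1; i++) {
    double k = (double)(m - i);
    double rate = k * (k - 1.0) / theta;
    double d = t[i] - prev;
    lp += std::log(rate) - rate * d;
    prev = t[i];
  }
  return lp;
}

// ---------------------------------------------------------------------------
// MH sweep machinery
// ---------------------------------------------------------------------------

struct TreeState {
  int m, nnode, root;
  std::vector<int> parent;          // -1 at root
  std::vector<int> child;           // 2 per node, -1 for tips
  std::vector<double> times;        // 0 at tips
  std::vector<double> edgelen;      // times[parent] - times
  std::vector<int> internals;       // internal node indices

  void rebuild_children() {
    std::fill(child.begin(), child.end(), -1);
    root = -1;
    for (int v = 0; v < nnode; v++) {
      int p = parent[v];
      if (p < 0) { root = v; continue; }
      if (child[2*p] < 0) child[2*p] = v; else child[2*p+1] = v;
    }
  }
  void rebuild_edges() {
    for (int v = 0; v < nnode; v++)
      edgelen[v] = parent[v] < 0 ? 0.0 : times[parent[v]] - times[v];
  }
  std::vector<double> internal_times() const {
    std::vector<double> t; t.reserve(m - 1);
    for (int v : internals) t.push_back(times[v]);
    return t;
  }
};

struct ModelParams {
  int model; // 0 K80, 1 F84
  double theta, kappa;
  double pi[4];
};

struct Priors {
  double thetaMax, kappaMax;
  double alpha[4];
};

struct Scales {
  double thetaScale, kappaScale, piConc;
  int rTree;
  bool updateTheta, updateKappa, updatePi;
};

struct AcceptCounts {
  long propTheta = 0, accTheta = 0;
  long propKappa = 0, accKappa = 0;
  long propPi = 0, accPi = 0;
  long propSlide = 0, accSlide = 0;
  long propExch = 0, accExch = 0;
};

static double ldirichlet(const double *x, const double *a) {
  double s = 0.0, sa = 0.0;
  for (int i = 0; i < 4; i++) {
    if (x[i] <= 0.0) return NEG_INF;
    s += (a[i] - 1.0) * std::log(x[i]) - R::lgammafn(a[i]);
    sa += a[i];
  }
  return s + R::lgammafn(sa);
}

static double loglik_of(const TreeState &tr, const ModelParams &mp,
                        const double *tipLik, int npat,
                        const double *patCounts) {
  return pruning_core(tr.m, tr.parent, tr.edgelen, tipLik, npat, patCounts,
                      mp.model, mp.kappa, mp.pi);
}

// One full MH sweep at tempering power eps. Updates state in place,
// keeping loglik/logCoalPrior caches current.
static void mh_sweep(TreeState &tr, ModelParams &mp, double &loglik,
                     double &logCoal, double eps,
                     const double *tipLik, int npat, const double *patCounts,
                     const Priors &pr, const Scales &sc, AcceptCounts &ac) {
  // --- Theta: multiplicative lognormal walk; likelihood does not involve
  // Theta, only the coalescent prior and the uniform bound do.
  if (sc.updateTheta) {
    ac.propTheta++;
    double thetaNew = mp.theta * std::exp(sc.thetaScale * R::norm_rand());
    if (thetaNew > 0.0 && thetaNew < pr.thetaMax) {
      double lcNew = coal_log_prior(tr.m, tr.internal_times(), thetaNew);
      double logr = lcNew - logCoal + std::log(thetaNew / mp.theta);
      if (std::log(R::unif_rand()) < logr) {
        mp.theta = thetaNew; logCoal = lcNew; ac.accTheta++;
      }
    }
  }
  // --- kappa: multiplicative lognormal walk against lik^eps
  if (sc.updateKappa) {
    ac.propKappa++;
    double kNew = mp.kappa * std::exp(sc.kappaScale * R::norm_rand());
    if (kNew > 0.0 && kNew < pr.kappaMax) {
      double kF;
      bool ok = (mp.model == 0) || f84_shape(kNew, mp.pi, kF);
      if (ok) {
        ModelParams cand = mp; cand.kappa = kNew;
        double llNew = (eps > 0.0)
          ? loglik_of(tr, cand, tipLik, npat, patCounts) : loglik;
        double logr = eps * (llNew - loglik) + std::log(kNew / mp.kappa);
        if (llNew > NEG_INF && std::log(R::unif_rand()) < logr) {
          if (eps == 0.0) llNew = loglik_of(tr, cand, tipLik, npat, patCounts);
          mp.kappa = kNew; loglik = llNew; ac.accKappa++;
        }
      }
    }
  }
  // --- pi (F84): Dirichlet proposal centered at current value
  if (sc.updatePi && mp.model == 1) {
    ac.propPi++;
    double prop[4], conc[4], sum = 0.0;
    bool ok = true;
    for (int i = 0; i < 4; i++) conc[i] = sc.piConc * mp.pi[i];
    for (int i = 0; i < 4; i++) {
      prop[i] = R::rgamma(conc[i], 1.0);
      sum += prop[i];
    }
    if (sum <= 0.0) ok = false;
    if (ok) for (int i = 0; i < 4; i++) {
      prop[i] /= sum;
      if (prop[i] < 1e-8) ok = false;
    }
    double kF;
    if (ok) ok = f84_shape(mp.kappa, prop, kF);
    if (ok) {
      double concBack[4];
      for (int i = 0; i < 4; i++) concBack[i] = sc.piConc * prop[i];
      double lqFwd = ldirichlet(prop, conc);
      double lqBack = ldirichlet(mp.pi, concBack);
      double lprNew = ldirichlet(prop, pr.alpha);
      double lprOld = ldirichlet(mp.pi, pr.alpha);
      ModelParams cand = mp;
      for (int i = 0; i < 4; i++) cand.pi[i] = prop[i];
      double llNew = (eps > 0.0)
        ? loglik_of(tr, cand, tipLik, npat, patCounts) : loglik;
      double logr = eps * (llNew - loglik) + (lprNew - lprOld)
                  + (lqBack - lqFwd);
      if (llNew > NEG_INF && R_FINITE(logr) &&
          std::log(R::unif_rand()) < logr) {
        if (eps == 0.0) llNew = loglik_of(tr, cand, tipLik, npat, patCounts);
        for (int i = 0; i < 4; i++) mp.pi[i] = prop[i];
        loglik = llNew; ac.accPi++;
      }
    }
  }
  // --- genealogy moves
  int nInternal = tr.m - 1;
  for (int r = 0; r < sc.rTree; r++) {
    bool doExchange = (tr.nnode > 3) && (R::unif_rand() < 0.5);
    if (!doExchange) {
      // node-time slide; for the root an exponential tail proposal matching
      // the conditional coalescent rate 2/theta
      ac.propSlide++;
      int v = tr.internals[(int)std::floor(R::unif_rand() * nInternal)];
      double lo = std::max(tr.times[tr.child[2*v]], tr.times[tr.child[2*v+1]]);
      double tOld = tr.times[v], tNew, lqDiff = 0.0;
      if (tr.parent[v] < 0) {
        double rate = 2.0 / mp.theta;
        tNew = lo + R::exp_rand() / rate;
        // log q(old|new) - log q(new|old); the rate terms cancel
        lqDiff = -rate * (tOld - lo) + rate * (tNew - lo);
        if (tNew <= lo) continue; // degenerate rounding: reject
      } else {
        double hi = tr.times[tr.parent[v]];
        if (hi <= lo) continue;
        tNew = lo + R::unif_rand() * (hi - lo);
        if (tNew <= lo || tNew >= hi) continue; // boundary rounding: reject
      }
      tr.times[v] = tNew;
      tr.rebuild_edges();
      double lcNew = coal_log_prior(tr.m, tr.internal_times(), mp.theta);
      double llNew = (eps > 0.0)
        ? loglik_of(tr, mp, tipLik, npat, patCounts) : loglik;
      double logr = eps * (llNew - loglik) + (lcNew - logCoal) + lqDiff;
      if (llNew > NEG_INF && std::log(R::unif_rand()) < logr) {
        if (eps == 0.0) llNew = loglik_of(tr, mp, tipLik, npat, patCounts);
        loglik = llNew; logCoal = lcNew; ac.accSlide++;
      } else {
        tr.times[v] = tOld;
        tr.rebuild_edges();
      }
    } else {
      // narrow exchange (ranked NNI): swap a node with its parent's sibling;
      // uniform choice over nodes with a grandparent is symmetric
      ac.propExch++;
      int c = -1;
      // candidates: any node whose parent is not the root
      int tries = 0;
      do {
        c = (int)std::floor(R::unif_rand() * tr.nnode);
        tries++;
      } while ((tr.parent[c] < 0 || tr.parent[tr.parent[c]] < 0) && tries < 1000);
      if (tr.parent[c] < 0 || tr.parent[tr.parent[c]] < 0) continue;
      int p = tr.parent[c], g = tr.parent[p];
      int s = (tr.child[2*g] == p) ? tr.child[2*g+1] : tr.child[2*g];
      if (tr.times[s] >= tr.times[p]) continue; // invalid: reject
      // swap attachments: c -> child of g, s -> child of p
      tr.parent[c] = g; tr.parent[s] = p;
      if (tr.child[2*g] == p) tr.child[2*g+1] = c; else tr.child[2*g] = c;
      // replace c in p's children with s
      if (tr.child[2*p] == c) tr.child[2*p] = s; else tr.child[2*p+1] = s;
      tr.rebuild_edges();
      // interval structure unchanged -> coalescent prior unchanged
      double llNew = (eps > 0.0)
        ? loglik_of(tr, mp, tipLik, npat, patCounts) : loglik;
      double logr = eps * (llNew - loglik);
      if (llNew > NEG_INF && std::log(R::unif_rand()) < logr) {
        if (eps == 0.0) llNew = loglik_of(tr, mp, tipLik, npat, patCounts);
        loglik = llNew; ac.accExch++;
      } else {
        // undo: restore s under g and c under p
        tr.parent[c] = p; tr.parent[s] = g;
        if (tr.child[2*g] == c) tr.child[2*g] = s; else tr.child[2*g+1] = s;
        if (tr.child[2*p] == s) tr.child[2*p] = c; else tr.child[2*p+1] = c;
        tr.rebuild_edges();
      }
    }
  }
}

static TreeState tree_from_columns(int m, const IntegerMatrix &parent,
                                   const NumericMatrix &times, int col) {
  TreeState tr;
  tr.m = m;
  tr.nnode = parent.nrow();
  tr.parent.resize(tr.nnode);
  tr.times.resize(tr.nnode);
  tr.child.assign(2 * tr.nnode, -1);
  tr.edgelen.resize(tr.nnode);
  for (int v = 0; v < tr.nnode; v++) {
    tr.parent[v] = parent(v, col);
    tr.times[v] = times(v, col);
  }
  tr.rebuild_children();
  tr.rebuild_edges();
  for (int v = 0; v < tr.nnode; v++)
    if (tr.child[2*v] >= 0) tr.internals.push_back(v);
  return tr;
}

static Priors priors_from(double thetaMax, double kappaMax,
                          NumericVector alpha) {
  Priors pr;
  pr.thetaMax = thetaMax; pr.kappaMax = kappaMax;
  for (int i = 0; i < 4; i++) pr.alpha[i] = alpha[i];
  return pr;
}

static List accept_list(const AcceptCounts &ac) {
  return List::create(
    _["theta"] = NumericVector::create((double)ac.accTheta, (double)ac.propTheta),
    _["kappa"] = NumericVector::create((double)ac.accKappa, (double)ac.propKappa),
    _["pi"]    = NumericVector::create((double)ac.accPi, (double)ac.propPi),
    _["slide"] = NumericVector::create((double)ac.accSlide, (double)ac.propSlide),
    _["exchange"] = NumericVector::create((double)ac.accExch, (double)ac.propExch));
}

// One SMC mutation pass: nSweeps MH sweeps at power eps for every particle.
// parent/times are nnode x N matrices (0-based parents, -1 at root).
//' @noRd
// [[Rcpp::export(name = ".smc_pass_cpp")]]
List smc_pass_cpp(NumericVector theta, NumericVector kappa, NumericMatrix pi,
                  IntegerMatrix parent, NumericMatrix times,
                  NumericVector loglik, NumericVector logCoal,
                  NumericVector tipLik, NumericVector patCounts, int m,
                  int model, double eps, int nSweeps,
                  double thetaMax, double kappaMax, NumericVector alpha,
                  double thetaScale, double kappaScale, double piConc,
                  int rTree, bool updateTheta, bool updateKappa,
                  bool updatePi) {
  int N = theta.size();
  int npat = patCounts.size();
  NumericVector thetaOut = clone(theta), kappaOut = clone(kappa);
  NumericVector llOut = clone(loglik), lcOut = clone(logCoal);
  NumericMatrix piOut = clone(pi);
  IntegerMatrix parentOut = clone(parent);
  NumericMatrix timesOut = clone(times);
  Priors pr = priors_from(thetaMax, kappaMax, alpha);
  Scales sc;
  sc.thetaScale = thetaScale; sc.kappaScale = kappaScale; sc.piConc = piConc;
  sc.rTree = rTree;
  sc.updateTheta = updateTheta; sc.updateKappa = updateKappa;
  sc.updatePi = updatePi;
  AcceptCounts ac;
  const double *tl = REAL(tipLik);
  const double *pc = REAL(patCounts);

  for (int n = 0; n < N; n++) {
    TreeState tr = tree_from_columns(m, parentOut, timesOut, n);
    ModelParams mp;
    mp.model = model; mp.theta = thetaOut[n]; mp.kappa = kappaOut[n];
    for (int i = 0; i < 4; i++) mp.pi[i] = piOut(n, i);
    double ll = llOut[n], lc = lcOut[n];
    for (int s = 0; s < nSweeps; s++)
      mh_sweep(tr, mp, ll, lc, eps, tl, npat, pc, pr, sc, ac);
    thetaOut[n] = mp.theta; kappaOut[n] = mp.kappa;
    for (int i = 0; i < 4; i++) piOut(n, i) = mp.pi[i];
    for (int v = 0; v < tr.nnode; v++) {
      parentOut(v, n) = tr.parent[v];
      timesOut(v, n) = tr.times[v];
    }
    llOut[n] = ll; lcOut[n] = lc;
  }
  return List::create(
    _["theta"] = thetaOut, _["kappa"] = kappaOut, _["pi"] = piOut,
    _["parent"] = parentOut, _["times"] = timesOut,
    _["loglik"] = llOut, _["logCoal"] = lcOut,
    _["accept"] = accept_list(ac));
}

// Full MH-MCMC chain at eps = 1 (or any fixed power), recording
// (theta, kappa, pi, loglik) every `thin` iterations after burnin.
//' @noRd
// [[Rcpp::export(name = ".mcmc_chain_cpp")]]
List mcmc_chain_cpp(double theta, double kappa, NumericVector pi,
                    IntegerVector parent, NumericVector times,
                    NumericVector tipLik, NumericVector patCounts, int m,
                    int model, double eps, int burnin, int chainLength,
                    int thin,
                    double thetaMax, double kappaMax, NumericVector alpha,
                    double thetaScale, double kappaScale, double piConc,
                    int rTree, bool updateTheta, bool updateKappa,
                    bool updatePi) {
  int nnode = parent.size();
  TreeState tr;
  tr.m = m; tr.nnode = nnode;
  tr.parent.resize(nnode); tr.times.resize(nnode);
  tr.child.assign(2 * nnode, -1); tr.edgelen.resize(nnode);
  for (int v = 0; v < nnode; v++) { tr.parent[v] = parent[v]; tr.times[v] = times[v]; }
  tr.rebuild_children(); tr.rebuild_edges();
  for (int v = 0; v < nnode; v++)
    if (tr.child[2*v] >= 0) tr.internals.push_back(v);

  ModelParams mp;
  mp.model = model; mp.theta = theta; mp.kappa = kappa;
  for (int i = 0; i < 4; i++) mp.pi[i] = pi[i];

  int npat = patCounts.size();
  const double *tl = REAL(tipLik);
  const double *pc = REAL(patCounts);
  double ll = pruning_core(m, tr.parent, tr.edgelen, tl, npat, pc,
                           mp.model, mp.kappa, mp.pi);
  if (ll == NEG_INF) stop("initial state has zero likelihood");
  double lc = coal_log_prior(m, tr.internal_times(), mp.theta);

  Priors pr = priors_from(thetaMax, kappaMax, alpha);
  Scales sc;
  sc.thetaScale = thetaScale; sc.kappaScale = kappaScale; sc.piConc = piConc;
  sc.rTree = rTree;
  sc.updateTheta = updateTheta; sc.updateKappa = updateKappa;
  sc.updatePi = updatePi;
  AcceptCounts ac;

  NumericVector thetaS(chainLength), kappaS(chainLength), llS(chainLength);
  NumericMatrix piS(chainLength, 4);
  long total = (long)burnin + (long)chainLength * thin;
  int kept = 0;
  for (long it = 0; it < total; it++) {
    mh_sweep(tr, mp, ll, lc, eps, tl, npat, pc, pr, sc, ac);
    if (it >= burnin && ((it - burnin + 1) % thin == 0) && kept < chainLength) {
      thetaS[kept] = mp.theta; kappaS[kept] = mp.kappa; llS[kept] = ll;
      for (int i = 0; i < 4; i++) piS(kept, i) = mp.pi[i];
      kept++;
    }
  }
  IntegerVector parentOut(nnode); NumericVector timesOut(nnode);
  for (int v = 0; v < nnode; v++) { parentOut[v] = tr.parent[v]; timesOut[v] = tr.times[v]; }
  return List::create(
    _["theta"] = thetaS, _["kappa"] = kappaS, _["pi"] = piS,
    _["loglik"] = llS, _["finalParent"] = parentOut,
    _["finalTimes"] = timesOut, _["accept"] = accept_list(ac));
}

//' @noRd
// [[Rcpp::export(name = ".coal_log_prior_cpp")]]
double coal_log_prior_cpp(NumericVector internalTimes, int m, double theta) {
  std::vector<double> t(internalTimes.begin(), internalTimes.end());
  return coal_log_prior(m, t, theta);
}
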