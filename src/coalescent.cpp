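#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

// Structured coalescent with piecewise epochs. Time runs backwards in
// generations from the present. Within an epoch, deme d has diploid size
// N_d(t) = N0_d * exp(g_d * (t - t0)), a backward migration rate matrix
// (lineage in deme i hops to deme j at rate mig[i][j] per generation), and a
// relabel map applied to lineage deme labels when the epoch is entered.
// Haploid lineages in deme d coalesce pairwise at rate 1 / (2 N_d(t)).
//
// Event times are drawn by thinning: the total event rate is bounded on the
// remaining epoch using the minimum deme size over that interval, candidate
// times drawn at the bound rate and accepted with probability actual/bound.

namespace {

struct Epoch {
  double t0, t1;                 // [t0, t1); last epoch has t1 = Inf
  std::vector<double> N0, g;     // per deme
  std::vector<std::vector<double> > mig;
  std::vector<double> migTot;
  std::vector<int> relabel;      // old deme label -> new label at entry
  int D;
};

std::vector<Epoch> parseEpochs(const List& epochList) {
  std::vector<Epoch> eps;
  int nE = epochList.size();
  for (int e = 0; e < nE; ++e) {
    List el = epochList[e];
    Epoch ep;
    ep.t0 = as<double>(el["t0"]);
    NumericVector N0 = el["N0"], g = el["g"];
    ep.D = N0.size();
    ep.N0.assign(N0.begin(), N0.end());
    ep.g.assign(g.begin(), g.end());
    NumericMatrix m = el["mig"];
    ep.mig.assign(ep.D, std::vector<double>(ep.D, 0.0));
    ep.migTot.assign(ep.D, 0.0);
    for (int i = 0; i < ep.D; ++i)
      for (int j = 0; j < ep.D; ++j)
        if (i != j) { ep.mig[i][j] = m(i, j); ep.migTot[i] += m(i, j); }
    IntegerVector rl = el["relabel"];
    ep.relabel.assign(rl.begin(), rl.end());
    ep.t1 = R_PosInf;
    eps.push_back(ep);
  }
  for (int e = 0; e + 1 < nE; ++e) eps[e].t1 = eps[e + 1].t0;
  return eps;
}

struct Tree {
  std::vector<int> parent, left, right;
  std::vector<double> time;
  int root, ntips;
};

Tree simulateTree(const std::vector<Epoch>& eps,
                  const std::vector<int>& demeOfTip, XRng& rng) {
  int ntips = demeOfTip.size();
  Tree tr;
  int maxNodes = 2 * ntips - 1;
  tr.parent.assign(maxNodes, -1);
  tr.left.assign(maxNodes, -1);
  tr.right.assign(maxNodes, -1);
  tr.time.assign(maxNodes, 0.0);
  tr.ntips = ntips;

  size_t eIdx = 0;
  int maxD = 0;
  for (size_t e = 0; e < eps.size(); ++e) maxD = std::max(maxD, eps[e].D);
  for (size_t i = 0; i < demeOfTip.size(); ++i)
    maxD = std::max(maxD, demeOfTip[i] + 1);
  std::vector<std::vector<int> > active(maxD);
  for (int i = 0; i < ntips; ++i) active[demeOfTip[i]].push_back(i);

  double t = 0.0;
  int nextNode = ntips;
  int nActive = ntips;

  auto applyRelabel = [&](const Epoch& ep) {
    std::vector<std::vector<int> > na(maxD);
    for (int d = 0; d < maxD; ++d)
      for (size_t i = 0; i < active[d].size(); ++i) {
        int nd = (d < (int)ep.relabel.size()) ? ep.relabel[d] : d;
        na[nd].push_back(active[d][i]);
      }
    active.swap(na);
  };
  applyRelabel(eps[0]);

  while (nActive > 1) {
    const Epoch& ep = eps[eIdx];
    // bound total rate over [t, t1)
    double lamMax = 0.0;
    for (int d = 0; d < ep.D; ++d) {
      double k = active[d].size();
      if (k >= 2) {
        double Nstart = ep.N0[d] * std::exp(ep.g[d] * (t - ep.t0));
        double Nmin = Nstart;
        if (ep.g[d] < 0 && R_finite(ep.t1))
          Nmin = std::min(Nstart, ep.N0[d] * std::exp(ep.g[d] * (ep.t1 - ep.t0)));
        else if (ep.g[d] < 0)
          stop("size must not shrink without bound in the terminal epoch");
        lamMax += k * (k - 1) / 2.0 / (2.0 * Nmin);
      }
      lamMax += active[d].size() * ep.migTot[d];
    }
    if (lamMax <= 0.0) {
      if (!R_finite(ep.t1))
        stop("coalescent cannot complete: isolated lineages in terminal epoch");
      t = ep.t1; ++eIdx; applyRelabel(eps[eIdx]);
      continue;
    }
    double dt = rng.rexp() / lamMax;
    if (t + dt >= ep.t1) {
      t = ep.t1; ++eIdx; applyRelabel(eps[eIdx]);
      continue;
    }
    t += dt;
    // actual rates at t
    double lam = 0.0;
    std::vector<double> coalR(ep.D, 0.0), migR(ep.D, 0.0);
    for (int d = 0; d < ep.D; ++d) {
      double k = active[d].size();
      if (k >= 2) {
        double N = ep.N0[d] * std::exp(ep.g[d] * (t - ep.t0));
        coalR[d] = k * (k - 1) / 2.0 / (2.0 * N);
      }
      migR[d] = active[d].size() * ep.migTot[d];
      lam += coalR[d] + migR[d];
    }
    if (rng.unif() * lamMax > lam) continue;  // thinned
    double u = rng.unif() * lam;
    int d = 0; bool isCoal = true;
    for (d = 0; d < ep.D; ++d) {
      if (u < coalR[d]) { isCoal = true; break; }
      u -= coalR[d];
      if (u < migR[d]) { isCoal = false; break; }
      u -= migR[d];
    }
    if (d >= ep.D) d = ep.D - 1;  // numerical guard
    if (isCoal) {
      int k = active[d].size();
      int i = rng.runifInt(k), j = rng.runifInt(k - 1);
      if (j >= i) ++j;
      int a = active[d][i], b = active[d][j];
      int m = nextNode++;
      tr.parent[a] = m; tr.parent[b] = m;
      tr.left[m] = a; tr.right[m] = b;
      tr.time[m] = t;
      if (i > j) std::swap(i, j);
      active[d][i] = m;
      active[d].erase(active[d].begin() + j);
      --nActive;
    } else {
      int k = active[d].size();
      int i = rng.runifInt(k);
      int lin = active[d][i];
      // destination
      double v = rng.unif() * ep.migTot[d];
      int dest = -1;
      for (int j = 0; j < ep.D; ++j) {
        if (j == d) continue;
        if (v < ep.mig[d][j]) { dest = j; break; }
        v -= ep.mig[d][j];
      }
      if (dest < 0) { for (int j = ep.D - 1; j >= 0; --j) if (j != d && ep.mig[d][j] > 0) { dest = j; break; } }
      active[d].erase(active[d].begin() + i);
      active[dest].push_back(lin);
    }
  }
  tr.root = nextNode - 1;
  return tr;
}

void collectTips(const Tree& tr, int v, std::vector<int>& out) {
  std::vector<int> stack;
  stack.push_back(v);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    if (u < tr.ntips) out.push_back(u);
    else { stack.push_back(tr.left[u]); stack.push_back(tr.right[u]); }
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_coalescent")]]
List sim_coalescent(IntegerVector nPerDeme, List epochList, double mu,
                    int chunkLen, int nChunks, double seed) {
  std::vector<Epoch> eps = parseEpochs(epochList);
  XRng rng((uint64_t)seed);
  int ntips = 0;
  std::vector<int> demeOfTip;
  for (int d = 0; d < nPerDeme.size(); ++d) {
    ntips += nPerDeme[d];
    for (int i = 0; i < nPerDeme[d]; ++i) demeOfTip.push_back(d);
  }
  if (ntips < 2) stop("need at least 2 haploid samples");

  std::vector<double> positions;
  std::vector<std::vector<unsigned char> > rows;  // site x tips
  std::vector<double> treeLens; treeLens.reserve(nChunks);

  for (int c = 0; c < nChunks; ++c) {
    Tree tr = simulateTree(eps, demeOfTip, rng);
    double tlen = 0.0;
    for (int v = 0; v < 2 * ntips - 1; ++v)
      if (tr.parent[v] >= 0) tlen += tr.time[tr.parent[v]] - tr.time[v];
    treeLens.push_back(tlen);
    if (mu <= 0) continue;
    std::set<int> used;
    // one pass per branch; infinite-sites on integer positions within chunk
    for (int v = 0; v < 2 * ntips - 1; ++v) {
      if (tr.parent[v] < 0) continue;
      double bl = tr.time[tr.parent[v]] - tr.time[v];
      int nm = rng.rpois(mu * chunkLen * bl);
      if (nm == 0) continue;
      std::vector<int> tips;
      collectTips(tr, v, tips);
      if ((int)tips.size() == ntips) continue;  // would be monomorphic derived
      for (int m = 0; m < nm; ++m) {
        int pos = rng.runifInt(chunkLen);
        int guard = 0;
        while (used.count(pos) && guard++ < 1000) pos = rng.runifInt(chunkLen);
        if (used.count(pos)) continue;  // chunk saturated; drop
        used.insert(pos);
        std::vector<unsigned char> row(ntips, 0);
        for (size_t k = 0; k < tips.size(); ++k) row[tips[k]] = 1;
        positions.push_back((double)c * chunkLen + pos + 1.0);  // 1-based bp
        rows.push_back(row);
      }
    }
  }

  // sort by position
  int S = positions.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return positions[a] < positions[b];
  });
  NumericVector pos(S);
  IntegerMatrix M(S, ntips);
  for (int i = 0; i < S; ++i) {
    pos[i] = positions[ord[i]];
    for (int j = 0; j < ntips; ++j) M(i, j) = rows[ord[i]][j];
  }
  return List::create(_["pos"] = pos, _["hap"] = M,
                      _["tree_length"] = NumericVector(treeLens.begin(), treeLens.end()));
}
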