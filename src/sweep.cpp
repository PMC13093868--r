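#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

// Forward-in-time Wright-Fisher simulation of a selected region.
//
// The population is initialised from externally supplied neutral haplotypes
// (a coalescent draw of 2N haplotypes at mutation-drift equilibrium), the
// beneficial mutation is injected at frequency f0 and the population evolves
// with selection, recombination and new mutation until the beneficial allele
// fixes; runs in which it is lost are restarted. Haplotypes are sparse sorted
// lists of derived-allele positions; the selected site is tracked separately.

namespace {

typedef std::vector<int> Hap;

// gamete from a diploid parent (haplotypes a and b) with crossovers
void makeGamete(const Hap& a, const Hap& b, bool selA, bool selB,
                int L, double rrate, int selPos, XRng& rng,
                Hap& out, bool& selOut) {
  int k = rng.rpois(rrate * L);
  if (k == 0) {
    if (rng.unif() < 0.5) { out = a; selOut = selA; }
    else { out = b; selOut = selB; }
    return;
  }
  std::vector<int> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = 1 + rng.runifInt(L);
  std::sort(bp.begin(), bp.end());
  bp.push_back(L + 1);
  out.clear();
  bool fromA = rng.unif() < 0.5;
  int lo = 1;
  selOut = false;
  for (size_t seg = 0; seg < bp.size(); ++seg) {
    int hi = bp[seg];  // segment [lo, hi)
    const Hap& src = fromA ? a : b;
    Hap::const_iterator it = std::lower_bound(src.begin(), src.end(), lo);
    Hap::const_iterator en = std::lower_bound(src.begin(), src.end(), hi);
    out.insert(out.end(), it, en);
    if (selPos >= lo && selPos < hi) selOut = fromA ? selA : selB;
    lo = hi;
    fromA = !fromA;
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_sweep_forward")]]
List sim_sweep_forward(IntegerMatrix initHap, NumericVector initPos,
                       int L, int N, double mu, double rrate,
                       double s, double h, int f0count, int selPos,
                       int tauAfterFix, int nSampleDip,
                       int maxRestarts, int maxGens, double seed) {
  XRng rng((uint64_t)seed);
  int H = initHap.ncol();
  if (H != 2 * N) stop("initial haplotype count must equal 2N");
  if (nSampleDip > N) stop("cannot sample more diploids than the population holds");

  std::vector<Hap> initPop(H);
  int S0 = initHap.nrow();
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < S0; ++i)
      if (initHap(i, j)) initPop[j].push_back((int)initPos[i]);

  bool neutral = (s <= 0.0 || f0count <= 0);

  std::vector<Hap> pop, nxt(H);
  std::vector<unsigned char> sel(H, 0), selNxt(H, 0);
  int restarts = -1, fixGen = -1, gen = 0;
  std::vector<double> wCum(N);

  // initialise (and re-initialise after loss)
  auto reset = [&]() {
    pop = initPop;
    std::fill(sel.begin(), sel.end(), 0);
    if (!neutral) {
      // place f0count copies on distinct random haplotypes
      std::vector<int> idx(H);
      for (int i = 0; i < H; ++i) idx[i] = i;
      for (int c = 0; c < f0count; ++c) {
        int j = c + rng.runifInt(H - c);
        std::swap(idx[c], idx[j]);
        sel[idx[c]] = 1;
      }
    }
    fixGen = -1;
    gen = 0;
    ++restarts;
  };
  reset();

  while (true) {
    if (gen > maxGens) stop("sweep simulation exceeded the generation cap");
    int selCount = 0;
    for (int i = 0; i < H; ++i) selCount += sel[i];
    if (!neutral) {
      if (selCount == 0) {
        if (restarts >= maxRestarts) stop("beneficial allele lost in every attempt");
        reset();
        continue;
      }
      if (selCount == H && fixGen < 0) fixGen = gen;
    } else if (fixGen < 0) {
      fixGen = 0;  // neutral: no conditioning, sample after tau generations
    }
    if (fixGen >= 0 && gen >= fixGen + tauAfterFix) break;

    // parent sampling weights (additive selection: 1, 1+hs, 1+s)
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int c = sel[2 * i] + sel[2 * i + 1];
      double w = (c == 0) ? 1.0 : (c == 1 ? 1.0 + h * s : 1.0 + s);
      acc += w;
      wCum[i] = acc;
    }
    for (int i = 0; i < N; ++i) {
      for (int g = 0; g < 2; ++g) {
        double u = rng.unif() * acc;
        int p = (int)(std::lower_bound(wCum.begin(), wCum.end(), u) - wCum.begin());
        if (p >= N) p = N - 1;
        int j = 2 * i + g;
        bool so;
        makeGamete(pop[2 * p], pop[2 * p + 1], sel[2 * p] != 0, sel[2 * p + 1] != 0,
                   L, rrate, selPos, rng, nxt[j], so);
        selNxt[j] = so ? 1 : 0;
        int nm = rng.rpois(mu * L);
        for (int m = 0; m < nm; ++m) {
          int posn = 1 + rng.runifInt(L);
          Hap::iterator it = std::lower_bound(nxt[j].begin(), nxt[j].end(), posn);
          if (it == nxt[j].end() || *it != posn) nxt[j].insert(it, posn);
        }
      }
    }
    pop.swap(nxt);
    sel.swap(selNxt);
    ++gen;
  }

  // sample diploids without replacement
  std::vector<int> dip(N);
  for (int i = 0; i < N; ++i) dip[i] = i;
  for (int c = 0; c < nSampleDip; ++c) {
    int j = c + rng.runifInt(N - c);
    std::swap(dip[c], dip[j]);
  }
  int nh = 2 * nSampleDip;
  std::vector<const Hap*> samp(nh);
  for (int c = 0; c < nSampleDip; ++c) {
    samp[2 * c] = &pop[2 * dip[c]];
    samp[2 * c + 1] = &pop[2 * dip[c] + 1];
  }
  // union of derived positions, keep polymorphic sites only
  std::vector<int> allPos;
  for (int j = 0; j < nh; ++j)
    allPos.insert(allPos.end(), samp[j]->begin(), samp[j]->end());
  std::sort(allPos.begin(), allPos.end());
  allPos.erase(std::unique(allPos.begin(), allPos.end()), allPos.end());

  std::vector<int> keep;
  std::vector<std::vector<unsigned char> > rows;
  for (size_t i = 0; i < allPos.size(); ++i) {
    int p = allPos[i], cnt = 0;
    std::vector<unsigned char> row(nh, 0);
    for (int j = 0; j < nh; ++j) {
      if (std::binary_search(samp[j]->begin(), samp[j]->end(), p)) {
        row[j] = 1; ++cnt;
      }
    }
    if (cnt > 0 && cnt < nh) { keep.push_back(p); rows.push_back(row); }
  }
  int S = keep.size();
  NumericVector pos(S);
  IntegerMatrix M(S, nh);
  for (int i = 0; i < S; ++i) {
    pos[i] = keep[i];
    for (int j = 0; j < nh; ++j) M(i, j) = rows[i][j];
  }
  return List::create(_["pos"] = pos, _["hap"] = M,
                      _["restarts"] = restarts,
                      _["generations"] = gen,
                      _["fix_gen"] = fixGen);
}
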