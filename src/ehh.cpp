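#include <Rcpp.h>
#include <vector>
#include <map>

using namespace Rcpp;

// Extended haplotype homozygosity. Haplotypes are a sites x haplotypes 0/1
// matrix with sorted 1-based positions. EHHS at distance x from a core site
// is the probability that two randomly drawn haplotypes are identical at
// every site from the core out to x, normalised to 1 at the core; the curve
// is truncated when it falls below `floorVal` or when the gap between
// adjacent sites exceeds `maxgap` bp. iES integrates the curve over bp by
// the trapezoid rule, summing the left and right arms.

namespace {

// walk outward from core, splitting haplotype groups at each site.
// Returns curve (positions, ehh values) including the core point.
void ehhArm(const IntegerMatrix& hap, const NumericVector& pos,
            int core, int step, const std::vector<int>& members,
            double maxgap, double floorVal,
            std::vector<double>& outPos, std::vector<double>& outVal) {
  int S = hap.nrow();
  int n = members.size();
  if (n < 2) return;
  double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> grp(n, 0);
  int nGrp = 1;
  double prev = 1.0;
  outPos.push_back(pos[core]);
  outVal.push_back(1.0);
  int i = core + step;
  double lastPos = pos[core];
  while (i >= 0 && i < S) {
    if (std::abs(pos[i] - lastPos) > maxgap) break;
    // split groups by allele at site i
    std::map<std::pair<int, int>, int> newId;
    std::vector<int> ng(n);
    int cnt = 0;
    for (int k = 0; k < n; ++k) {
      std::pair<int, int> key(grp[k], hap(i, members[k]));
      std::map<std::pair<int, int>, int>::iterator it = newId.find(key);
      if (it == newId.end()) { newId[key] = cnt; ng[k] = cnt; ++cnt; }
      else ng[k] = it->second;
    }
    grp = ng; nGrp = cnt;
    std::vector<int> sz(nGrp, 0);
    for (int k = 0; k < n; ++k) ++sz[grp[k]];
    double hom = 0.0;
    for (int g = 0; g < nGrp; ++g) hom += (double)sz[g] * (sz[g] - 1) / 2.0;
    double e = hom / denom;
    outPos.push_back(pos[i]);
    outVal.push_back(e);
    lastPos = pos[i];
    if (e < floorVal) break;
    prev = e;
    i += step;
  }
  (void)prev;
}

double trapz(const std::vector<double>& x, const std::vector<double>& y) {
  double a = 0.0;
  for (size_t i = 1; i < x.size(); ++i)
    a += std::abs(x[i] - x[i - 1]) * (y[i] + y[i - 1]) / 2.0;
  return a;
}

} // namespace

// [[Rcpp::export(name = ".ehh_site")]]
List ehh_site(IntegerMatrix hap, NumericVector pos, int core,
              double maxgap, double floorVal, bool byAllele) {
  int n = hap.ncol();
  std::vector<int> all(n);
  for (int j = 0; j < n; ++j) all[j] = j;

  List out;
  if (byAllele) {
    // allele-specific EHH among carriers of each core allele
    for (int a = 0; a <= 1; ++a) {
      std::vector<int> mem;
      for (int j = 0; j < n; ++j) if (hap(core, j) == a) mem.push_back(j);
      std::vector<double> lp, lv, rp, rv;
      ehhArm(hap, pos, core, -1, mem, maxgap, floorVal, lp, lv);
      ehhArm(hap, pos, core, +1, mem, maxgap, floorVal, rp, rv);
      double ie = trapz(lp, lv) + trapz(rp, rv);
      out.push_back(List::create(
        _["allele"] = a, _["n"] = (int)mem.size(),
        _["pos_left"] = NumericVector(lp.begin(), lp.end()),
        _["ehh_left"] = NumericVector(lv.begin(), lv.end()),
        _["pos_right"] = NumericVector(rp.begin(), rp.end()),
        _["ehh_right"] = NumericVector(rv.begin(), rv.end()),
        _["ihh"] = ie));
    }
  } else {
    std::vector<double> lp, lv, rp, rv;
    ehhArm(hap, pos, core, -1, all, maxgap, floorVal, lp, lv);
    ehhArm(hap, pos, core, +1, all, maxgap, floorVal, rp, rv);
    double ie = trapz(lp, lv) + trapz(rp, rv);
    out = List::create(
      _["pos_left"] = NumericVector(lp.begin(), lp.end()),
      _["ehh_left"] = NumericVector(lv.begin(), lv.end()),
      _["pos_right"] = NumericVector(rp.begin(), rp.end()),
      _["ehh_right"] = NumericVector(rv.begin(), rv.end()),
      _["ies"] = ie);
  }
  return out;
}

// [[Rcpp::export(name = ".ies_scan")]]
NumericVector ies_scan(IntegerMatrix hap, NumericVector pos,
                       double maxgap, double floorVal) {
  int S = hap.nrow(), n = hap.ncol();
  std::vector<int> all(n);
  for (int j = 0; j < n; ++j) all[j] = j;
  NumericVector ies(S);
  for (int c = 0; c < S; ++c) {
    std::vector<double> lp, lv, rp, rv;
    ehhArm(hap, pos, c, -1, all, maxgap, floorVal, lp, lv);
    ehhArm(hap, pos, c, +1, all, maxgap, floorVal, rp, rv);
    ies[c] = trapz(lp, lv) + trapz(rp, rv);
  }
  return ies;
}
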