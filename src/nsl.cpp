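// Unstandardised nS_L: at a focal biallelic site, haplotypes split into
// ancestral (allele 0) and derived (allele 1) carriers; for each pair within
// a class, L = number of consecutive segregating sites, in the maximal run
// containing the focal site, at which the pair is identical (runs truncated
// at the window edges).  The statistic is ln(mean L ancestral / mean L
// derived).  Pair sums are accumulated by partition refinement: extending
// site-by-site away from the focal site, pairs still identical after d
// steps are exactly the within-group pairs of the refined partition.
// Groups that shrink to one haplotype can never contribute another pair and
// are dropped, so the per-step cost tracks the still-identical haplotypes.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// sum over within-class pairs of the extension length in one direction
double ext_sum(const int *Hp, int nrow, int ncol, const std::vector<int> &rows,
               int focal, int dir) {
  const int m = (int)rows.size();
  std::vector<int> grp(rows);
  std::vector<int> bnd; bnd.reserve(m + 1);
  bnd.push_back(0); bnd.push_back(m);
  std::vector<int> tmp(m);
  std::vector<int> nbnd; nbnd.reserve(m + 1);
  double total = 0.0;
  for (int d = focal + dir; d >= 0 && d < ncol; d += dir) {
    const int *col = Hp + (size_t)d * nrow;
    nbnd.clear(); nbnd.push_back(0);
    int w = 0;
    for (size_t g = 0; g + 1 < bnd.size(); ++g) {
      const int lo = bnd[g], hi = bnd[g + 1];
      int n0 = 0;
      for (int i = lo; i < hi; ++i) n0 += (col[grp[i]] == 0);
      const int n1 = hi - lo - n0;
      if (n0 >= 2) {
        for (int i = lo; i < hi; ++i) if (col[grp[i]] == 0) tmp[w++] = grp[i];
        nbnd.push_back(w);
      }
      if (n1 >= 2) {
        for (int i = lo; i < hi; ++i) if (col[grp[i]] != 0) tmp[w++] = grp[i];
        nbnd.push_back(w);
      }
    }
    grp.swap(tmp); bnd.swap(nbnd);
    double pairs = 0.0;
    for (size_t g = 0; g + 1 < bnd.size(); ++g) {
      const double sz = bnd[g + 1] - bnd[g];
      pairs += sz * (sz - 1) / 2.0;
    }
    if (pairs == 0.0) break;
    total += pairs;
  }
  return total;
}

double mean_tract(const int *Hp, int nrow, int ncol,
                  const std::vector<int> &rows, int focal) {
  const double m = (double)rows.size();
  const double npairs = m * (m - 1) / 2.0;
  // the focal site itself counts once for every within-class pair
  double total = npairs;
  total += ext_sum(Hp, nrow, ncol, rows, focal, +1);
  total += ext_sum(Hp, nrow, ncol, rows, focal, -1);
  return total / npairs;
}

double nsl_one(const int *Hp, int nrow, int ncol, int focal) {
  std::vector<int> anc, der;
  anc.reserve(nrow); der.reserve(nrow);
  const int *col = Hp + (size_t)focal * nrow;
  for (int r = 0; r < nrow; ++r)
    (col[r] == 1 ? der : anc).push_back(r);
  if (anc.size() < 2 || der.size() < 2) return NA_REAL;
  return std::log(mean_tract(Hp, nrow, ncol, anc, focal) /
                  mean_tract(Hp, nrow, ncol, der, focal));
}

}  // namespace

// [[Rcpp::export]]
double nsl_site_cpp(const IntegerMatrix &H, int focal) {
  return nsl_one(H.begin(), H.nrow(), H.ncol(), focal);
}

// per-focal-site nS_L over every column of H (NA where a class has < 2 carriers)
// [[Rcpp::export]]
NumericVector nsl_all_sites_cpp(const IntegerMatrix &H) {
  const int S = H.ncol();
  NumericVector out(S);
  for (int s = 0; s < S; ++s) out[s] = nsl_one(H.begin(), H.nrow(), H.ncol(), s);
  return out;
}
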