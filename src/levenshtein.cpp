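#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost Levenshtein distance between two integer-coded symbol sequences.
// Two-row dynamic programme; O(len(a) * len(b)) time, O(len(b)) space.
static int lev_core(const std::vector<int> &a, const std::vector<int> &b,
                    std::vector<int> &prev, std::vector<int> &cur) {
  const int na = (int)a.size(), nb = (int)b.size();
  if (na == 0) return nb;
  if (nb == 0) return na;
  prev.resize(nb + 1);
  cur.resize(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export(name = ".lev_int")]]
int lev_int(IntegerVector a, IntegerVector b) {
  std::vector<int> va(a.begin(), a.end()), vb(b.begin(), b.end());
  std::vector<int> prev, cur;
  return lev_core(va, vb, prev, cur);
}

// Fisher-Yates shuffle driven by R's RNG so results follow set.seed().
static void shuffle_r(std::vector<int> &x) {
  for (int i = (int)x.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i; // guard against unif_rand() == 1.0
    std::swap(x[i], x[j]);
  }
}

// Null distribution of Levenshtein distances under random symbol-order
// permutation. When both = true each iteration independently permutes both
// sequences; otherwise only the second.
// [[Rcpp::export(name = ".lev_null")]]
IntegerVector lev_null(IntegerVector a, IntegerVector b, int n_shuffles,
                       bool both = true) {
  std::vector<int> va(a.begin(), a.end()), vb(b.begin(), b.end());
  std::vector<int> prev, cur;
  IntegerVector out(n_shuffles);
  for (int k = 0; k < n_shuffles; ++k) {
    if (both) shuffle_r(va);
    shuffle_r(vb);
    out[k] = lev_core(va, vb, prev, cur);
  }
  return out;
}
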