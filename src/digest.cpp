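#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right pairing of opposed nicks into double-strand breaks.
// Input arrays must be sorted by (gid, pos); strand is 0 (top) / 1 (bottom).
// Within each molecule (gid), scanning left to right, each unused nick is
// paired with the first unused nick on the opposite strand no more than
// maxOffset bp to its right; each nick is used at most once. The break
// position is the midpoint rounded down.
// [[Rcpp::export]]
List cpp_pair_breaks(IntegerVector gid, NumericVector pos,
                     IntegerVector strand, double maxOffset) {
  int n = gid.size();
  std::vector<bool> used(n, false);
  std::vector<int> out_gid;
  std::vector<double> out_brk;
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (gid[j] != gid[i] || pos[j] - pos[i] > maxOffset) break;
      if (used[j] || strand[j] == strand[i]) continue;
      used[i] = used[j] = true;
      out_gid.push_back(gid[i]);
      out_brk.push_back(std::floor((pos[i] + pos[j]) / 2.0));
      break;
    }
  }
  return List::create(_["gid"] = wrap(out_gid), _["brk"] = wrap(out_brk));
}

// Unweighted running-sum enrichment score. The walk is accumulated in
// integers (hits add N-k, misses subtract k; the true score is the
// extreme divided by k*(N-k)) so extremes and magnitude ties are exact:
// ties in magnitude resolve to the positive extreme.
static double es_walk(const std::vector<bool>& m, int n, int k) {
  long long step_hit = n - k, step_miss = k;
  long long s = 0, mx = 0, mn = 0;
  for (int i = 0; i < n; ++i) {
    if (m[i]) s += step_hit; else s -= step_miss;
    if (s > mx) mx = s;
    if (s < mn) mn = s;
  }
  double scale = (double)k * (double)(n - k);
  return (mx >= -mn) ? mx / scale : mn / scale;
}

// [[Rcpp::export]]
double cpp_es(LogicalVector member) {
  int n = member.size(), k = 0;
  std::vector<bool> m(n);
  for (int i = 0; i < n; ++i) { m[i] = member[i]; if (m[i]) ++k; }
  return es_walk(m, n, k);
}

// Null distribution of the enrichment score: B label permutations of the
// membership vector, using R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector cpp_es_perm(LogicalVector member, int B) {
  int n = member.size(), k = 0;
  for (int i = 0; i < n; ++i) if (member[i]) ++k;
  NumericVector out(B);
  std::vector<int> idx(n);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::vector<bool> m(n, false);
    int remaining = n;
    for (int d = 0; d < k; ++d) {
      int j = (int)std::floor(unif_rand() * remaining);
      if (j >= remaining) j = remaining - 1;
      m[idx[j]] = true;
      idx[j] = idx[--remaining];
    }
    out[b] = es_walk(m, n, k);
  }
  return out;
}
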