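#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Restriction-fragment alignment of one contig (internal fragments only)
// against an ordered optical map.
//
// A "move" matches 1..max_merge consecutive map fragments against
// 1..max_merge consecutive contig fragments; the block is feasible when the
// two sums agree within the relative sizing tolerance, and costs
// |sum_map - sum_contig| / sum_contig. Up to max_skip leading/trailing
// contig fragments may be left unmatched (a contig-boundary site that
// vanished from the map) at skip_penalty each; each merged fragment beyond
// one per side costs merge_penalty (a missed restriction site), so unforced
// merging never beats matching fragments one-to-one. For every feasible map
// start
// the best-scoring completion is reported with its block decomposition.
// Indices in the returned records are 0-based half-open; map indices may
// run past the fragment count on circular maps (reduce modulo N in R).
// [[Rcpp::export]]
List align_dp_cpp(NumericVector map_frags, NumericVector contig_frags,
                  double tol, int max_merge, int min_matched,
                  int max_skip, double skip_penalty, double merge_penalty,
                  bool circular) {
  const int N = map_frags.size(), M = contig_frags.size();
  List out;
  if (N == 0 || M == 0) return out;
  const double INF = 1e300;

  std::vector<double> cpre(M + 1, 0.0);
  for (int j = 0; j < M; ++j) cpre[j + 1] = cpre[j] + contig_frags[j];

  for (int a = 0; a < N; ++a) {
    const int Imax = std::min(max_merge * M, circular ? N : (N - a));
    if (Imax <= 0) continue;
    std::vector<std::vector<double> > D(Imax + 1, std::vector<double>(M + 1, INF));
    std::vector<std::vector<int> > PU(Imax + 1, std::vector<int>(M + 1, -1));
    std::vector<std::vector<int> > PV(Imax + 1, std::vector<int>(M + 1, -1));
    for (int cs = 0; cs <= max_skip && M - cs >= min_matched; ++cs)
      D[0][cs] = cs * skip_penalty;

    std::vector<double> mpre(Imax + 1, 0.0);
    for (int i = 0; i < Imax; ++i)
      mpre[i + 1] = mpre[i] + map_frags[(a + i) % N];

    for (int i = 0; i < Imax; ++i) {
      for (int j = 0; j < M; ++j) {
        const double d = D[i][j];
        if (d >= INF) continue;
        for (int u = 1; u <= max_merge && i + u <= Imax; ++u) {
          const double sm = mpre[i + u] - mpre[i];
          for (int v = 1; v <= max_merge && j + v <= M; ++v) {
            const double sc = cpre[j + v] - cpre[j];
            const double diff = std::fabs(sm - sc);
            if (diff > tol * std::max(sm, sc)) continue;
            const double nd = d + diff / sc + merge_penalty * (u - 1 + v - 1);
            if (nd < D[i + u][j + v]) {
              D[i + u][j + v] = nd;
              PU[i + u][j + v] = u;
              PV[i + u][j + v] = v;
            }
          }
        }
      }
    }

    double best = INF;
    int bi = -1, bj = -1;
    const int jlo = std::max(min_matched, M - max_skip);
    for (int i = 1; i <= Imax; ++i)
      for (int je = jlo; je <= M; ++je) {
        if (D[i][je] >= INF) continue;
        const double tot = D[i][je] + (M - je) * skip_penalty;
        if (tot < best) { best = tot; bi = i; bj = je; }
      }
    if (bi < 0) continue;

    std::vector<int> mu, mv;
    int i = bi, j = bj;
    while (PU[i][j] >= 0) {
      mu.push_back(PU[i][j]);
      mv.push_back(PV[i][j]);
      i -= mu.back();
      j -= mv.back();
    }
    const int cs_used = j;
    if (bj - cs_used < min_matched) continue;
    std::reverse(mu.begin(), mu.end());
    std::reverse(mv.begin(), mv.end());
    const int nb = (int) mu.size();
    IntegerMatrix blocks(nb, 4);
    int mi = 0, cj = cs_used;
    for (int b = 0; b < nb; ++b) {
      blocks(b, 0) = a + mi;
      blocks(b, 1) = a + mi + mu[b];
      blocks(b, 2) = cj;
      blocks(b, 3) = cj + mv[b];
      mi += mu[b];
      cj += mv[b];
    }
    out.push_back(List::create(
      _["ms"] = a, _["me"] = a + bi, _["cs"] = cs_used, _["ce"] = bj,
      _["score"] = best, _["blocks"] = blocks));
  }
  return out;
}
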