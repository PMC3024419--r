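// Seed-and-extend alignment core: banded affine-gap extension with X-drop
// termination, run in both directions from an exact word seed.
//
// Scoring: match M (>0), mismatch mm (<0), gap of length g costs Q + g*R,
// i.e. the first gapped column costs go = Q + R and each further column
// ge = R. The band half-width is derived from the X-drop threshold: a path
// whose diagonal offset d has paid at least go + (d-1)*ge, so offsets beyond
// ~X/ge can never survive the X-drop.
//
// Sequences are passed as integer codes 0..4 (A,C,G,T,N); N never matches.

#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct Cell {
  int s, m, al;  // score, matches on path, aligned (match/mismatch) columns
};

struct ExtRes {
  int ai, bj, score, matches, aligned;  // consumed of a, of b; path stats
};

// Extension alignment of a[0..na-1] vs b[0..nb-1] (strided access so the
// caller can extend leftwards without copying). Alignment is anchored at
// (0, 0); returns the maximal-scoring endpoint under X-drop pruning.
ExtRes ext_dir(const int* a, int na, int astep, const int* b, int nb,
               int bstep, int M, int mm, int go, int ge, int X, int maxext) {
  ExtRes best = {0, 0, 0, 0, 0};
  if (na > maxext) na = maxext;
  if (nb > maxext) nb = maxext;
  if (na == 0 && nb == 0) return best;

  int bw = (ge > 0) ? (X / ge + 2) : 16;
  if (bw > 64) bw = 64;
  const int W = 2 * bw + 1;
  std::vector<Cell> H(W), E(W), F(W), pH(W), pF(W);
  const Cell none = {NEG, 0, 0};

  int bestScore = 0;
  // row 0: consume only b (gap)
  for (int d = 0; d < W; ++d) pH[d] = pF[d] = none;
  for (int d = bw; d < W; ++d) {
    int j = d - bw;
    if (j > nb) break;
    if (j == 0) {
      pH[d] = {0, 0, 0};
    } else {
      int sc = -(go + (j - 1) * ge);
      if (sc < bestScore - X) break;
      pH[d] = {sc, 0, 0};
    }
  }

  for (int i = 1; i <= na; ++i) {
    bool alive = false;
    const int ac = a[(i - 1) * astep];
    for (int d = 0; d < W; ++d) H[d] = E[d] = F[d] = none;
    int dlo = bw - i < 0 ? 0 : bw - i;
    int dhi = nb - i + bw;
    if (dhi > W - 1) dhi = W - 1;
    for (int d = dlo; d <= dhi; ++d) {
      const int j = i + d - bw;
      if (j < 0 || j > nb) continue;
      Cell h = none, e = none, f = none;
      if (j == 0) {
        int sc = -(go + (i - 1) * ge);
        h = {sc, 0, 0};
        f = h;
      } else {
        // gap consuming a: from row i-1, same j (offset d+1 in prev row)
        if (d + 1 < W) {
          if (pH[d + 1].s != NEG && pH[d + 1].s - go > f.s)
            f = {pH[d + 1].s - go, pH[d + 1].m, pH[d + 1].al};
          if (pF[d + 1].s != NEG && pF[d + 1].s - ge > f.s)
            f = {pF[d + 1].s - ge, pF[d + 1].m, pF[d + 1].al};
        }
        // gap consuming b: same row, j-1 (offset d-1, already computed)
        if (d - 1 >= 0) {
          if (H[d - 1].s != NEG && H[d - 1].s - go > e.s)
            e = {H[d - 1].s - go, H[d - 1].m, H[d - 1].al};
          if (E[d - 1].s != NEG && E[d - 1].s - ge > e.s)
            e = {E[d - 1].s - ge, E[d - 1].m, E[d - 1].al};
        }
        // diagonal
        if (pH[d].s != NEG) {
          const int bc = b[(j - 1) * bstep];
          const bool isM = (ac == bc && ac < 4);
          h = {pH[d].s + (isM ? M : mm), pH[d].m + (isM ? 1 : 0),
               pH[d].al + 1};
        }
        if (e.s > h.s) h = e;
        if (f.s > h.s) h = f;
      }
      if (h.s != NEG && h.s < bestScore - X) h = none;
      if (e.s != NEG && e.s < bestScore - X) e = none;
      if (f.s != NEG && f.s < bestScore - X) f = none;
      H[d] = h;
      E[d] = e;
      F[d] = f;
      if (h.s != NEG) {
        alive = true;
        if (h.s > bestScore) {
          bestScore = h.s;
          best = {i, j, h.s, h.m, h.al};
        }
      }
    }
    if (!alive) break;
    pH = H;
    pF = F;
  }
  return best;
}

}  // namespace

// Batch X-drop extension of word seeds. s1, s2: integer-coded sequences;
// i0, j0: 1-based seed start positions (seed = exact match of length w).
// Returns a matrix with columns start1, end1, start2, end2, score, matches,
// columns (alignment columns incl. gaps).
// [[Rcpp::export]]
IntegerMatrix xdrop_batch_cpp(IntegerVector s1, IntegerVector s2,
                              IntegerVector i0, IntegerVector j0, int w,
                              int M, int mm, int Q, int R, int X,
                              int maxext) {
  const int go = Q + R, ge = R;
  const int n1 = s1.size(), n2 = s2.size(), n = i0.size();
  const int* p1 = INTEGER(s1);
  const int* p2 = INTEGER(s2);
  IntegerMatrix out(n, 7);
  for (int k = 0; k < n; ++k) {
    const int a0 = i0[k], b0 = j0[k];
    if (a0 < 1 || b0 < 1 || a0 + w - 1 > n1 || b0 + w - 1 > n2)
      stop("seed outside sequence bounds");
    const int nra = n1 - (a0 + w - 1), nrb = n2 - (b0 + w - 1);
    ExtRes r = {0, 0, 0, 0, 0}, l = {0, 0, 0, 0, 0};
    if (nra > 0 || nrb > 0)
      r = ext_dir(p1 + (a0 + w - 1), nra, 1, p2 + (b0 + w - 1), nrb, 1, M,
                  mm, go, ge, X, maxext);
    const int nla = a0 - 1, nlb = b0 - 1;
    if (nla > 0 || nlb > 0)
      l = ext_dir(p1 + (nla > 0 ? a0 - 2 : 0), nla, -1,
                  p2 + (nlb > 0 ? b0 - 2 : 0), nlb, -1, M, mm, go, ge, X,
                  maxext);
    out(k, 0) = a0 - l.ai;
    out(k, 1) = a0 + w - 1 + r.ai;
    out(k, 2) = b0 - l.bj;
    out(k, 3) = b0 + w - 1 + r.bj;
    out(k, 4) = w * M + l.score + r.score;
    out(k, 5) = w + l.matches + r.matches;
    out(k, 6) = w + (l.ai + l.bj - l.aligned) + (r.ai + r.bj - r.aligned);
  }
  colnames(out) = CharacterVector::create("start1", "end1", "start2", "end2",
                                          "score", "matches", "columns");
  return out;
}
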