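#include "core.h"

namespace pyromap {

namespace {
constexpr int32_t INF = 1 << 28;
inline int idx(int i, int j, int lb) { return i * (lb + 1) + j; }
}  // namespace

// Three-state Gotoh with edit-like costs (match 0). States:
//   M: a[i-1] aligned to b[j-1]    ('=' / 'X')
//   X: a[i-1] consumed, gap in b   ('I', read insertion)
//   Y: b[j-1] consumed, gap in a   ('D', deletion from read)
// Deterministic tie-break: prefer M over X over Y everywhere.
Aln gotoh_align(const uint8_t* a, int la, const uint8_t* b, int lb,
                int mis, int go, int ge, int band, int mode) {
  Aln out;
  if (la == 0 && lb == 0) return out;
  if (la == 0) {
    if (mode == ALN_GLOBAL) { out.ops.assign(lb, 'D'); out.cost = go + lb * ge; }
    else if (mode == ALN_FREE_LEAD) { out.lead = lb; }  // all overhang, free
    // ALN_FREE_TRAIL / ALN_FREE_BOTH: stop immediately, overhang free
    return out;
  }
  const bool free_lead = (mode == ALN_FREE_LEAD || mode == ALN_FREE_BOTH);
  const bool free_trail = (mode == ALN_FREE_TRAIL || mode == ALN_FREE_BOTH);
  const size_t sz = (size_t)(la + 1) * (lb + 1);
  std::vector<int32_t> M(sz, INF), X(sz, INF), Y(sz, INF);
  M[idx(0, 0, lb)] = 0;
  for (int i = 1; i <= la; ++i) X[idx(i, 0, lb)] = go + i * ge;
  for (int j = 1; j <= lb; ++j) {
    if (free_lead) M[idx(0, j, lb)] = 0;  // alignment may start at (0,j)
    else Y[idx(0, j, lb)] = go + j * ge;
  }
  // diagonal corridor: j - i within [min(0, lb-la) - band, max(0, lb-la) + band];
  // it always contains both endpoints of the required path
  const bool banded = band >= 0;
  const int dlo = std::min(0, lb - la) - band, dhi = std::max(0, lb - la) + band;
  for (int i = 1; i <= la; ++i) {
    int jlo = 1, jhi = lb;
    if (banded) { jlo = std::max(1, i + dlo); jhi = std::min(lb, i + dhi); }
    for (int j = jlo; j <= jhi; ++j) {
      const int d = idx(i, j, lb), up = idx(i - 1, j, lb),
                lf = idx(i, j - 1, lb), dg = idx(i - 1, j - 1, lb);
      const int32_t sub = (a[i - 1] == b[j - 1]) ? 0 : mis;
      int32_t best = std::min(M[dg], std::min(X[dg], Y[dg]));
      if (best < INF) M[d] = best + sub;
      int32_t xo = std::min(M[up], Y[up]);
      X[d] = std::min(xo < INF ? xo + go + ge : INF,
                      X[up] < INF ? X[up] + ge : INF);
      int32_t yo = std::min(M[lf], X[lf]);
      Y[d] = std::min(yo < INF ? yo + go + ge : INF,
                      Y[lf] < INF ? Y[lf] + ge : INF);
    }
  }
  // terminal cell
  int ei = la, ej = lb;
  if (free_trail) {
    int32_t best = INF;
    for (int j = 0; j <= lb; ++j) {
      int32_t v = std::min(M[idx(la, j, lb)],
                           std::min(X[idx(la, j, lb)], Y[idx(la, j, lb)]));
      if (v < best) { best = v; ej = j; }  // ties: smallest j (least reference)
    }
  }
  const int e = idx(ei, ej, lb);
  int state;  // 0 M, 1 X, 2 Y
  if (M[e] <= X[e] && M[e] <= Y[e]) state = 0;
  else if (X[e] <= Y[e]) state = 1;
  else state = 2;
  out.cost = (state == 0 ? M[e] : state == 1 ? X[e] : Y[e]);
  if (out.cost >= INF) Rcpp::stop("alignment infeasible within band");

  std::string ops;
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0) break;  // free-lead start row
      const int32_t sub = (a[i - 1] == b[j - 1]) ? 0 : mis;
      ops.push_back(sub ? 'X' : '=');
      const int dg = idx(i - 1, j - 1, lb);
      const int32_t want = M[idx(i, j, lb)] - sub;
      --i; --j;
      if (M[dg] == want) state = 0;
      else if (X[dg] == want) state = 1;
      else state = 2;
      if (i == 0 && j > 0 && state == 0 && free_lead) break;
    } else if (state == 1) {
      ops.push_back('I');
      const int up = idx(i - 1, j, lb);
      const int32_t want = X[idx(i, j, lb)];
      --i;
      if (M[up] < INF && M[up] + go + ge == want) state = 0;
      else if (X[up] < INF && X[up] + ge == want) state = 1;
      else state = 2;
    } else {
      ops.push_back('D');
      const int lf = idx(i, j - 1, lb);
      const int32_t want = Y[idx(i, j, lb)];
      --j;
      if (M[lf] < INF && M[lf] + go + ge == want) state = 0;
      else if (X[lf] < INF && X[lf] + ge == want) state = 1;
      else state = 2;
    }
  }
  out.lead = j;  // >0 only with a free leading reference overhang
  std::reverse(ops.begin(), ops.end());
  out.ops = ops;
  return out;
}

std::string ops_to_cigar(const std::string& ops) {
  std::string cig;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    cig += std::to_string(j - i);
    cig.push_back(ops[i]);
    i = j;
  }
  return cig;
}

}  // namespace pyromap
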