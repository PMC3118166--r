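#include "core.h"

namespace pyromap {

std::vector<int32_t> build_suffix_array(const std::vector<uint8_t>& s) {
  const int32_t n = (int32_t)s.size();
  std::vector<int32_t> sa(n), rank(n), tmp(n);
  for (int32_t i = 0; i < n; ++i) { sa[i] = i; rank[i] = s[i]; }
  if (n <= 1) return sa;
  for (int32_t k = 1;; k <<= 1) {
    auto cmp = [&](int32_t a, int32_t b) {
      if (rank[a] != rank[b]) return rank[a] < rank[b];
      int32_t ra = (a + k < n) ? rank[a + k] : -1;
      int32_t rb = (b + k < n) ? rank[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int32_t i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank.swap(tmp);
    if (rank[sa[n - 1]] == n - 1) break;  // all ranks distinct
  }
  return sa;
}

void FM::build(const std::vector<uint8_t>& text, int rstride, int sstride) {
  n = (int32_t)text.size();
  rank_stride = rstride;
  sa_stride = sstride;
  std::vector<int32_t> sa = build_suffix_array(text);
  bwt.resize(n);
  sa_sample.assign(n, -1);
  for (int32_t i = 0; i < n; ++i) {
    int32_t p = sa[i];
    bwt[i] = text[p == 0 ? n - 1 : p - 1];
    if (p % sa_stride == 0) sa_sample[i] = p;  // text positions 0, s, 2s, ...
  }
  finish_from_bwt();
}

void FM::finish_from_bwt() {
  std::array<int64_t, NSYM> cnt{};
  const int32_t nblocks = n / rank_stride + 1;
  ckpt.assign((size_t)nblocks * NSYM, 0);
  for (int32_t i = 0; i < n; ++i) {
    if (i % rank_stride == 0) {
      int32_t b = i / rank_stride;
      for (int c = 0; c < NSYM; ++c) ckpt[(size_t)b * NSYM + c] = (int32_t)cnt[c];
    }
    cnt[bwt[i]]++;
  }
  if (n % rank_stride == 0 && n > 0) {
    int32_t b = n / rank_stride;
    for (int c = 0; c < NSYM; ++c) ckpt[(size_t)b * NSYM + c] = (int32_t)cnt[c];
  }
  C.fill(0);
  for (int c = 1; c <= NSYM; ++c) C[c] = C[c - 1] + cnt[c - 1];
}

int32_t FM::rank(uint8_t c, int32_t i) const {
  const int32_t b = i / rank_stride;
  int32_t r = ckpt[(size_t)b * NSYM + c];
  for (int32_t j = b * rank_stride; j < i; ++j) r += (bwt[j] == c);
  return r;
}

int32_t FM::sa_at(int32_t row) const {
  int32_t steps = 0;
  while (sa_sample[row] < 0) { row = lf(row); ++steps; }
  return sa_sample[row] + steps;
}

bool FM::extend_left(uint8_t c, int32_t& lo, int32_t& hi) const {
  lo = (int32_t)C[c] + rank(c, lo);
  hi = (int32_t)C[c] + rank(c, hi);
  return lo < hi;
}

int Bundle::seg_of(int64_t pos) const {
  if (seg_start.empty()) return -1;
  auto it = std::upper_bound(seg_start.begin(), seg_start.end(), pos);
  if (it == seg_start.begin()) return -1;
  int i = (int)(it - seg_start.begin()) - 1;
  return (pos < seg_end[i]) ? i : -1;
}

int longest_match(const Bundle& bd, const uint8_t* q, int m, int start,
                  int32_t& lo, int32_t& hi) {
  lo = 0;
  hi = bd.rev.n;
  int l = 0;
  while (start + l < m) {
    uint8_t c = q[start + l];
    if (c < 2) break;  // non-ACGT read symbol: cannot match
    int32_t lo2 = lo, hi2 = hi;
    if (!bd.rev.extend_left(c, lo2, hi2)) break;
    lo = lo2; hi = hi2; ++l;
  }
  return l;
}

}  // namespace pyromap
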