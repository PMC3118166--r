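#include "core.h"

namespace pyromap {

std::vector<Seed> extract_seeds(const Bundle& bd, const std::vector<uint8_t>& q,
                                int min_seed_len, int64_t max_occ,
                                int first_cursor) {
  std::vector<Seed> out;
  const int m = (int)q.size();
  int c = first_cursor;
  while (c < m) {
    int32_t lo, hi;
    int l = longest_match(bd, q.data(), m, c, lo, hi);
    if (l == 0) { ++c; continue; }  // first symbol absent: mismatch-skip case
    Seed s;
    s.start = c; s.len = l; s.lo = lo; s.hi = hi;
    s.occ = (int64_t)hi - lo;
    s.truncated = s.occ > max_occ;
    s.anchor = !s.truncated && l >= min_seed_len;
    const int nxt = c + l;
    if (nxt >= m) {
      s.skip = 2;
      out.push_back(s);
      break;
    }
    if (q[nxt] != q[nxt - 1]) {       // blocked by a differing symbol
      s.skip = 0;
      out.push_back(s);
      c = nxt + 1;                    // skip exactly one symbol
    } else {                          // blocked inside a homopolymer
      s.skip = 1;
      out.push_back(s);
      int j = nxt;
      while (j < m && q[j] == q[j - 1]) ++j;
      if (j >= m) break;              // homopolymer runs to the read end
      c = j;                          // start of the next homopolymer
    }
  }
  return out;
}

std::vector<Occ> collect_occurrences(const Bundle& bd, const std::vector<Seed>& seeds) {
  std::vector<Occ> v;
  for (int32_t i = 0; i < (int32_t)seeds.size(); ++i) {
    const Seed& s = seeds[i];
    if (!s.anchor) continue;
    for (int32_t row = s.lo; row < s.hi; ++row) {
      int64_t rev_pos = bd.rev.sa_at(row);
      v.push_back(Occ{i, rev_to_fwd(bd, rev_pos, s.len)});
    }
  }
  std::sort(v.begin(), v.end(), [](const Occ& a, const Occ& b) {
    if (a.pos != b.pos) return a.pos < b.pos;
    return a.seed < b.seed;
  });
  return v;
}

bool coherent_link(const Bundle& bd, const std::vector<Seed>& seeds,
                   const Occ& prev, const Occ& next, int eps_min, double rho) {
  if (next.seed <= prev.seed) return false;      // read order must be respected
  if (next.pos < prev.pos) return false;
  const int sp = bd.seg_of(prev.pos), sn = bd.seg_of(next.pos);
  if (sp < 0 || sp != sn) return false;          // never chain across segments
  const Seed& a = seeds[prev.seed];
  const Seed& b = seeds[next.seed];
  // read distance between the two seeds (concatenation of everything skipped)
  const int64_t agap = (int64_t)b.start - (a.start + a.len);
  const int64_t d = next.pos - (prev.pos + a.len);
  const int64_t eps = std::max<int64_t>(eps_min, (int64_t)std::ceil(rho * (double)agap));
  return d >= agap - eps && d <= agap + eps;
}

int chain_occurrences(const Bundle& bd, const std::vector<Seed>& seeds,
                      const std::vector<Occ>& occs, int eps_min, double rho,
                      std::vector<int32_t>& chain_id, int64_t* ntests) {
  chain_id.assign(occs.size(), 0);
  if (ntests) *ntests = 0;
  if (occs.empty()) return 0;
  int cur = 0;
  chain_id[0] = 0;
  // the tail of the current chain is always the previous occurrence, so the
  // scan performs exactly one coherence test per occurrence (linear overall)
  for (size_t k = 1; k < occs.size(); ++k) {
    if (ntests) ++(*ntests);
    if (coherent_link(bd, seeds, occs[k - 1], occs[k], eps_min, rho))
      chain_id[k] = cur;
    else
      chain_id[k] = ++cur;
  }
  return cur + 1;
}

MapRes extend_chain(const Bundle& bd, const std::vector<uint8_t>& q,
                    const std::vector<Seed>& seeds, const std::vector<Occ>& occs,
                    const std::vector<int32_t>& member_idx, const Scoring& sc) {
  MapRes res;
  if (member_idx.empty()) return res;
  const int m = (int)q.size();
  const Occ& first = occs[member_idx.front()];
  const Occ& last = occs[member_idx.back()];
  const int seg = bd.seg_of(first.pos);
  if (seg < 0) return res;
  const int64_t seg_lo = bd.seg_start[seg], seg_hi = bd.seg_end[seg];

  std::string ops;
  int32_t cost = 0;

  // left end: semi-global, leading reference overhang free
  const Seed& s1 = seeds[first.seed];
  int64_t gstart = first.pos;
  if (s1.start > 0) {
    const int la = s1.start;
    const int64_t wlo = std::max(seg_lo, first.pos - (int64_t)(la + sc.end_slack));
    const int lb = (int)(first.pos - wlo);
    Aln a = gotoh_align(q.data(), la, bd.text.data() + wlo, lb,
                        sc.mismatch, sc.gap_open, sc.gap_extend, sc.band_pad,
                        ALN_FREE_LEAD);
    gstart = wlo + a.lead;
    ops += a.ops;
    cost += a.cost;
  }
  ops.append(s1.len, '=');

  // inner blocks: banded global between consecutive anchors
  for (size_t t = 1; t < member_idx.size(); ++t) {
    const Occ& pv = occs[member_idx[t - 1]];
    const Occ& nx = occs[member_idx[t]];
    const Seed& sp = seeds[pv.seed];
    const Seed& sn = seeds[nx.seed];
    const int ra = sp.start + sp.len, rb = sn.start;   // read gap [ra, rb)
    const int64_t ga = pv.pos + sp.len, gb = nx.pos;   // reference gap [ga, gb)
    if (rb < ra || gb < ga) { res.ok = false; return res; }
    const int la = rb - ra, lb = (int)(gb - ga);
    Aln a = gotoh_align(q.data() + ra, la, bd.text.data() + ga, lb,
                        sc.mismatch, sc.gap_open, sc.gap_extend, sc.band_pad,
                        ALN_GLOBAL);
    ops += a.ops;
    cost += a.cost;
    ops.append(sn.len, '=');
  }

  // right end: semi-global, trailing reference overhang free
  const Seed& sq = seeds[last.seed];
  const int re = sq.start + sq.len;
  if (re < m) {
    const int la = m - re;
    const int64_t wst = last.pos + sq.len;
    const int64_t whi = std::min(seg_hi, wst + (int64_t)(la + sc.end_slack));
    const int lb = (int)(whi - wst);
    Aln a = gotoh_align(q.data() + re, la, bd.text.data() + wst, lb,
                        sc.mismatch, sc.gap_open, sc.gap_extend, sc.band_pad,
                        ALN_FREE_TRAIL);
    ops += a.ops;
    cost += a.cost;
  }

  int32_t ma = 0, mi = 0, in = 0, de = 0;
  for (char o : ops) {
    if (o == '=') ++ma; else if (o == 'X') ++mi;
    else if (o == 'I') ++in; else ++de;
  }
  res.ok = true;
  res.gstart = gstart;
  res.ops = ops;
  res.matches = ma; res.mism = mi; res.ins = in; res.del = de;
  res.cost = cost;
  res.identity = ops.empty() ? 0.0 : (double)ma / (double)ops.size();
  int64_t span = 0;
  for (int32_t k : member_idx) span += seeds[occs[k].seed].len;
  res.span = span;
  return res;
}

namespace {

std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& q) {
  std::vector<uint8_t> r(q.rbegin(), q.rend());
  for (auto& b : r) b = comp_base(b);
  return r;
}

bool accept_hit(const MapRes& r, const Params& P) {
  if (P.accept_mode == 0) return r.identity * 100.0 >= P.t;
  return (r.mism + r.ins + r.del) <= P.e;
}

// One greedy decomposition pass from a given cursor offset: seed, chain,
// extend the `top` largest candidates (span-ranked, leftmost first on ties).
// Candidates whose implied mapping diagonal was already extended by an
// earlier pass are skipped without consuming the pass's budget.
void map_one_pass(const Bundle& bd, const std::vector<uint8_t>& q, int strand,
                  int offset, const Params& P, std::vector<Hit>& hits,
                  std::vector<int64_t>& extended_diags) {
  if (offset >= (int)q.size()) return;
  std::vector<Seed> seeds = extract_seeds(bd, q, P.min_seed_len, P.max_occ, offset);
  if (seeds.empty()) return;
  std::vector<Occ> occs = collect_occurrences(bd, seeds);
  if (occs.empty()) return;
  std::vector<int32_t> chain_id;
  int nchains = chain_occurrences(bd, seeds, occs, P.eps_min, P.rho, chain_id, nullptr);
  std::vector<std::vector<int32_t>> chains(nchains);
  for (size_t k = 0; k < occs.size(); ++k) chains[chain_id[k]].push_back((int32_t)k);
  std::vector<int64_t> spans(nchains, 0);
  std::vector<int> order(nchains);
  for (int c = 0; c < nchains; ++c) {
    for (int32_t k : chains[c]) spans[c] += seeds[occs[k].seed].len;
    order[c] = c;
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return spans[a] > spans[b]; });
  int taken = 0;
  for (int t = 0; t < nchains && taken < P.top; ++t) {
    const std::vector<int32_t>& ch = chains[order[t]];
    const Occ& f = occs[ch.front()];
    const int64_t diag = f.pos - seeds[f.seed].start;  // implied mapping start
    bool seen = false;
    for (int64_t d : extended_diags)
      if (std::llabs(d - diag) <= 2) { seen = true; break; }
    if (seen) continue;
    extended_diags.push_back(diag);
    ++taken;
    MapRes r = extend_chain(bd, q, seeds, occs, ch, P.sc);
    if (!r.ok || !accept_hit(r, P)) continue;
    Hit h;
    h.gstart = r.gstart; h.strand = strand; h.ops = r.ops;
    h.matches = r.matches; h.mism = r.mism; h.ins = r.ins; h.del = r.del;
    h.identity = r.identity;
    h.errors = r.mism + r.ins + r.del;
    hits.push_back(h);
  }
}

// High error rates fragment the exact-match structure, and a single greedy
// decomposition probes only one set of cursor positions: a maximal match
// can be "hijacked" by a chance locus that extends further than the true
// one, dropping the true occurrence from the seed's interval. Restarting
// the same procedure a few symbols deeper yields a decorrelated
// decomposition and recovers anchors the first pass lost; the fewest-errors
// rule then arbitrates between candidates from all passes.
void map_one_strand(const Bundle& bd, const std::vector<uint8_t>& q, int strand,
                    const Params& P, std::vector<Hit>& hits) {
  std::vector<int64_t> extended_diags;
  for (int off : P.restart_offsets)
    map_one_pass(bd, q, strand, off, P, hits, extended_diags);
}

// Dense fixed-length k-mer anchoring, used as a fallback when greedy
// maximal-match seeding leaves a read without a convincing candidate:
// every erroneous homopolymer can truncate a maximal match, and a read with
// only short clean stretches may retain no true-locus anchor at all. Exact
// k-mer probes at a small stride recover short clean stretches; their hits
// are clustered by alignment diagonal and each cluster's non-overlapping
// coherent subset is extended with the ordinary machinery.
void rescue_strand(const Bundle& bd, const std::vector<uint8_t>& q, int strand,
                   const Params& P, std::vector<Hit>& hits) {
  const int m = (int)q.size();
  const int k = P.rescue_k, stride = P.rescue_stride;
  if (m < k) return;
  std::vector<Seed> seeds;
  std::vector<Occ> occs;
  for (int i = 0; i + k <= m; i += stride) {
    int32_t lo = 0, hi = bd.rev.n;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      uint8_t c = q[i + j];
      if (c < 2 || !bd.rev.extend_left(c, lo, hi)) { ok = false; break; }
    }
    if (!ok || (int64_t)(hi - lo) > P.rescue_max_occ) continue;
    Seed s;
    s.start = i; s.len = k; s.lo = lo; s.hi = hi; s.occ = hi - lo;
    s.anchor = true;
    const int32_t sidx = (int32_t)seeds.size();
    seeds.push_back(s);
    for (int32_t row = lo; row < hi; ++row)
      occs.push_back(Occ{sidx, rev_to_fwd(bd, bd.rev.sa_at(row), k)});
  }
  if (occs.empty()) return;
  // cluster hits on nearby alignment diagonals (single-linkage along the
  // sorted diagonal values, so gradual indel drift stays in one cluster)
  std::vector<std::pair<int64_t, int32_t>> byd(occs.size());
  for (size_t i = 0; i < occs.size(); ++i)
    byd[i] = {occs[i].pos - seeds[occs[i].seed].start, (int32_t)i};
  std::sort(byd.begin(), byd.end());
  const int64_t link_gap = std::max<int64_t>(16, 2 * P.eps_min);
  // per cluster, keep the non-overlapping coherent subset as a chain; rank
  // candidate clusters by chain span (distinct read bases anchored), so a
  // pair of short true-locus stretches outranks the overlapping probes of a
  // single chance stretch
  std::vector<std::vector<int32_t>> cand;
  std::vector<int64_t> cand_span;
  size_t a = 0;
  for (size_t b = 1; b <= byd.size(); ++b) {
    if (b < byd.size() && byd[b].first - byd[b - 1].first <= link_gap) continue;
    std::vector<int32_t> mem;
    for (size_t t = a; t < b; ++t) mem.push_back(byd[t].second);
    a = b;
    std::sort(mem.begin(), mem.end(), [&](int32_t x, int32_t y) {
      if (seeds[occs[x].seed].start != seeds[occs[y].seed].start)
        return seeds[occs[x].seed].start < seeds[occs[y].seed].start;
      return occs[x].pos < occs[y].pos;
    });
    std::vector<int32_t> chain;
    for (int32_t idx : mem) {
      if (chain.empty()) { chain.push_back(idx); continue; }
      const Occ& pv = occs[chain.back()];
      const Occ& nx = occs[idx];
      const Seed& sp = seeds[pv.seed];
      if (seeds[nx.seed].start < sp.start + sp.len) continue;   // overlap
      if (nx.pos < pv.pos + sp.len) continue;
      if (!coherent_link(bd, seeds, pv, nx, std::max(P.eps_min, (int)link_gap),
                         P.rho)) continue;
      chain.push_back(idx);
    }
    if (chain.empty()) continue;
    cand.push_back(chain);
    cand_span.push_back((int64_t)chain.size() * k);
  }
  std::vector<int> order(cand.size());
  for (size_t i = 0; i < cand.size(); ++i) order[i] = (int)i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int x, int y) { return cand_span[x] > cand_span[y]; });
  for (size_t ci = 0; ci < order.size() && ci < (size_t)P.top; ++ci) {
    MapRes r = extend_chain(bd, q, seeds, occs, cand[order[ci]], P.sc);
    if (!r.ok || !accept_hit(r, P)) continue;
    Hit h;
    h.gstart = r.gstart; h.strand = strand; h.ops = r.ops;
    h.matches = r.matches; h.mism = r.mism; h.ins = r.ins; h.del = r.del;
    h.identity = r.identity;
    h.errors = r.mism + r.ins + r.del;
    hits.push_back(h);
  }
}

// Final polish: one unconstrained semi-global alignment of the whole read
// over the candidate's reference window. The stitched alignment is
// conditioned on the anchor placement; when the read ends are noisy that
// can misplace the mapping start by more than the net indel drift. The hit
// is replaced only when the free alignment is strictly cheaper, so exact
// stitched paths (and their deterministic CIGARs) are preserved.
void polish_hit(const Bundle& bd, const std::vector<uint8_t>& q, Hit& h,
                const Scoring& sc) {
  const int seg = bd.seg_of(h.gstart);
  if (seg < 0) return;
  const int64_t ref_span = h.matches + h.mism + h.del;
  const int64_t wlo = std::max(bd.seg_start[seg], h.gstart - 32);
  const int64_t whi = std::min(bd.seg_end[seg], h.gstart + ref_span + 32);
  const int la = (int)q.size(), lb = (int)(whi - wlo);
  if (lb <= 0) return;
  Aln a = gotoh_align(q.data(), la, bd.text.data() + wlo, lb,
                      sc.mismatch, sc.gap_open, sc.gap_extend,
                      32 + sc.band_pad, ALN_FREE_BOTH);
  int32_t old_cost = h.mism * sc.mismatch;
  // recover the stitched cost from the op string (gap events + bases)
  for (size_t i = 0; i < h.ops.size(); ++i) {
    if (h.ops[i] == 'I' || h.ops[i] == 'D') {
      if (i == 0 || h.ops[i] != h.ops[i - 1]) old_cost += sc.gap_open;
      old_cost += sc.gap_extend;
    }
  }
  if (a.cost >= old_cost) return;
  int32_t ma = 0, mi = 0, in = 0, de = 0;
  for (char o : a.ops) {
    if (o == '=') ++ma; else if (o == 'X') ++mi;
    else if (o == 'I') ++in; else ++de;
  }
  h.gstart = wlo + a.lead;
  h.ops = a.ops;
  h.matches = ma; h.mism = mi; h.ins = in; h.del = de;
  h.errors = mi + in + de;
  h.identity = a.ops.empty() ? 0.0 : (double)ma / (double)a.ops.size();
}

}  // namespace

std::vector<Hit> map_read_codes(const Bundle& bd, const std::vector<uint8_t>& q,
                                const Params& P) {
  std::vector<Hit> hits;
  std::vector<uint8_t> rc;
  map_one_strand(bd, q, 0, P, hits);
  if (P.both_strands) {
    rc = revcomp_codes(q);
    map_one_strand(bd, rc, 1, P, hits);
  }
  if (P.rescue) {
    double best_id = 0.0;
    for (const Hit& h : hits) best_id = std::max(best_id, h.identity);
    if (hits.empty() || best_id * 100.0 < P.rescue_identity) {
      rescue_strand(bd, q, 0, P, hits);
      if (P.both_strands) rescue_strand(bd, rc, 1, P, hits);
    }
  }
  if (hits.empty()) return hits;
  if (P.polish)
    for (Hit& h : hits)
      polish_hit(bd, h.strand == 0 ? q : rc, h, P.sc);
  // deterministic order: fewest errors, then leftmost, then forward strand
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.errors != b.errors) return a.errors < b.errors;
    if (a.gstart != b.gstart) return a.gstart < b.gstart;
    return a.strand < b.strand;
  });
  // drop exact duplicates (tied chains can extend to the same alignment)
  std::vector<Hit> uniq;
  for (auto& h : hits) {
    bool dup = false;
    for (auto& u : uniq)
      if (u.gstart == h.gstart && u.strand == h.strand && u.ops == h.ops) { dup = true; break; }
    if (!dup) uniq.push_back(h);
  }
  if (!P.report_all) {
    std::vector<Hit> best;
    for (auto& h : uniq) if (h.errors == uniq.front().errors) best.push_back(h);
    return best;
  }
  return uniq;
}

}  // namespace pyromap
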