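#include "core.h"

using namespace Rcpp;
using namespace pyromap;

namespace {

Bundle* get_bundle(SEXP ptr) {
  XPtr<Bundle> xp(ptr);
  if (!xp) stop("invalid index pointer (rebuild or reload the index)");
  return xp.get();
}

Params params_from_list(const List& P) {
  Params p;
  p.min_seed_len = as<int>(P["min_seed_len"]);
  p.max_occ = (int64_t)as<double>(P["max_occ"]);
  p.eps_min = as<int>(P["eps_min"]);
  p.rho = as<double>(P["rho"]);
  p.top = as<int>(P["top"]);
  p.restart_offsets.clear();
  IntegerVector ro = P["restart_offsets"];
  for (int i = 0; i < ro.size(); ++i) p.restart_offsets.push_back(ro[i]);
  p.rescue = as<bool>(P["rescue"]) ? 1 : 0;
  p.rescue_k = as<int>(P["rescue_k"]);
  p.rescue_stride = as<int>(P["rescue_stride"]);
  p.rescue_max_occ = (int64_t)as<double>(P["rescue_max_occ"]);
  p.rescue_identity = as<double>(P["rescue_identity"]);
  p.polish = as<bool>(P["polish"]) ? 1 : 0;
  p.sc.mismatch = as<int>(P["mismatch"]);
  p.sc.gap_open = as<int>(P["gap_open"]);
  p.sc.gap_extend = as<int>(P["gap_extend"]);
  p.sc.band_pad = as<int>(P["band_pad"]);
  p.sc.end_slack = as<int>(P["end_slack"]);
  p.accept_mode = as<std::string>(P["mode"]) == "errors" ? 1 : 0;
  p.t = as<double>(P["t"]);
  p.e = as<int>(P["e"]);
  p.report_all = as<std::string>(P["report"]) == "all" ? 1 : 0;
  p.both_strands = as<bool>(P["both_strands"]) ? 1 : 0;
  return p;
}

std::vector<Seed> seeds_from_df(const IntegerVector& start0, const IntegerVector& len,
                                const IntegerVector& lo0, const IntegerVector& hi0,
                                const LogicalVector& anchor) {
  std::vector<Seed> seeds(start0.size());
  for (int i = 0; i < start0.size(); ++i) {
    seeds[i].start = start0[i];
    seeds[i].len = len[i];
    seeds[i].lo = lo0[i];
    seeds[i].hi = hi0[i];
    seeds[i].occ = hi0[i] - lo0[i];
    seeds[i].anchor = anchor[i];
  }
  return seeds;
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_build_bundle(std::string text, NumericVector seg_start, NumericVector seg_end,
                      IntegerVector seg_rec, NumericVector seg_local,
                      CharacterVector rec_names, NumericVector rec_len,
                      int rank_stride, int sa_stride) {
  if (text.empty() || text.back() != '$') stop("encoded text must end with the sentinel '$'");
  XPtr<Bundle> xp(new Bundle(), true);
  Bundle& bd = *xp;
  bd.text = encode_string(text);
  for (size_t i = 0; i + 1 < bd.text.size(); ++i)
    if (bd.text[i] == 0) stop("sentinel '$' may only appear at the end of the text");
  const int64_t n = bd.n();
  bd.fwd.build(bd.text, rank_stride, sa_stride);
  std::vector<uint8_t> rev(bd.text.rbegin() + 1, bd.text.rend());
  rev.push_back(0);
  bd.rev.build(rev, rank_stride, sa_stride);
  for (int i = 0; i < seg_start.size(); ++i) {
    bd.seg_start.push_back((int64_t)seg_start[i]);
    bd.seg_end.push_back((int64_t)seg_end[i]);
    bd.seg_local.push_back((int64_t)seg_local[i]);
    bd.seg_rec.push_back(seg_rec[i]);
    if (bd.seg_end.back() > n - 1) stop("segment exceeds text length");
  }
  for (int r = 0; r < rec_names.size(); ++r) {
    bd.rec_names.push_back(as<std::string>(rec_names[r]));
    bd.rec_len.push_back((int64_t)rec_len[r]);
  }
  return xp;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP ptr) {
  Bundle* bd = get_bundle(ptr);
  NumericVector C(NSYM);
  CharacterVector nm(NSYM);
  for (int c = 0; c < NSYM; ++c) {
    C[c] = (double)bd->fwd.C[c];
    nm[c] = std::string(1, decode_base((uint8_t)c));
  }
  C.attr("names") = nm;
  std::string bwt(bd->fwd.n, ' ');
  for (int32_t i = 0; i < bd->fwd.n; ++i) bwt[i] = decode_base(bd->fwd.bwt[i]);
  return List::create(_["n"] = (double)bd->n(), _["counts"] = C, _["bwt"] = bwt,
                      _["rank_stride"] = bd->fwd.rank_stride,
                      _["sa_stride"] = bd->fwd.sa_stride);
}

// [[Rcpp::export]]
NumericVector cpp_backward_search(SEXP ptr, std::string pattern) {
  Bundle* bd = get_bundle(ptr);
  int32_t lo = 0, hi = bd->fwd.n;
  for (auto it = pattern.rbegin(); it != pattern.rend(); ++it) {
    uint8_t c = encode_base(*it);
    if (c < 2) { lo = hi = 0; break; }  // outside {A,C,G,T}: empty interval
    if (!bd->fwd.extend_left(c, lo, hi)) { lo = hi = 0; break; }
  }
  return NumericVector::create((double)lo, (double)hi);
}

// [[Rcpp::export]]
List cpp_locate(SEXP ptr, double lo, double hi, double max_occ) {
  Bundle* bd = get_bundle(ptr);
  const int32_t l = (int32_t)lo, h = (int32_t)hi;
  if (l < 0 || h > bd->fwd.n || l > h) stop("invalid suffix-array interval");
  if ((double)(h - l) > max_occ)
    return List::create(_["pos"] = NumericVector(0), _["truncated"] = true);
  std::vector<double> pos;
  for (int32_t row = l; row < h; ++row) pos.push_back((double)bd->fwd.sa_at(row));
  std::sort(pos.begin(), pos.end());
  return List::create(_["pos"] = wrap(pos), _["truncated"] = false);
}

// [[Rcpp::export]]
List cpp_longest_match(SEXP ptr, std::string query, int start0, double max_occ) {
  Bundle* bd = get_bundle(ptr);
  std::vector<uint8_t> q = encode_string(query);
  if (start0 < 0 || start0 > (int)q.size()) stop("start out of range");
  int32_t lo, hi;
  int l = longest_match(*bd, q.data(), (int)q.size(), start0, lo, hi);
  std::vector<double> pos;
  bool trunc = false;
  if (l > 0) {
    if ((double)(hi - lo) > max_occ) {
      trunc = true;
    } else {
      for (int32_t row = lo; row < hi; ++row)
        pos.push_back((double)rev_to_fwd(*bd, bd->rev.sa_at(row), l));
      std::sort(pos.begin(), pos.end());
    }
  }
  return List::create(_["length"] = l, _["pos"] = wrap(pos), _["truncated"] = trunc);
}

// [[Rcpp::export]]
DataFrame cpp_extract_seeds(SEXP ptr, std::string read, int min_seed_len, double max_occ,
                            int first_cursor0) {
  Bundle* bd = get_bundle(ptr);
  std::vector<uint8_t> q = encode_string(read);
  std::vector<Seed> seeds = extract_seeds(*bd, q, min_seed_len, (int64_t)max_occ,
                                          first_cursor0);
  const int k = (int)seeds.size();
  IntegerVector start0(k), len(k), lo0(k), hi0(k);
  NumericVector occ(k);
  LogicalVector trunc(k), anchor(k);
  CharacterVector skip(k);
  for (int i = 0; i < k; ++i) {
    start0[i] = seeds[i].start; len[i] = seeds[i].len;
    lo0[i] = seeds[i].lo; hi0[i] = seeds[i].hi;
    occ[i] = (double)seeds[i].occ;
    trunc[i] = seeds[i].truncated; anchor[i] = seeds[i].anchor;
    skip[i] = seeds[i].skip == 0 ? "mismatch" : seeds[i].skip == 1 ? "homopolymer" : "read_end";
  }
  return DataFrame::create(_["start0"] = start0, _["length"] = len, _["occ"] = occ,
                           _["truncated"] = trunc, _["anchor"] = anchor,
                           _["skip"] = skip, _["lo0"] = lo0, _["hi0"] = hi0,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_collect_occurrences(SEXP ptr, IntegerVector start0, IntegerVector len,
                                  IntegerVector lo0, IntegerVector hi0,
                                  LogicalVector anchor) {
  Bundle* bd = get_bundle(ptr);
  std::vector<Seed> seeds = seeds_from_df(start0, len, lo0, hi0, anchor);
  std::vector<Occ> occs = collect_occurrences(*bd, seeds);
  const int k = (int)occs.size();
  IntegerVector seed(k);
  NumericVector pos0(k);
  for (int i = 0; i < k; ++i) { seed[i] = occs[i].seed; pos0[i] = (double)occs[i].pos; }
  return DataFrame::create(_["seed0"] = seed, _["pos0"] = pos0);
}

// [[Rcpp::export]]
List cpp_chain(SEXP ptr, IntegerVector occ_seed0, NumericVector occ_pos0,
               IntegerVector start0, IntegerVector len,
               int eps_min, double rho) {
  Bundle* bd = get_bundle(ptr);
  std::vector<Seed> seeds(start0.size());
  for (int i = 0; i < start0.size(); ++i) { seeds[i].start = start0[i]; seeds[i].len = len[i]; }
  std::vector<Occ> occs(occ_seed0.size());
  for (int i = 0; i < occ_seed0.size(); ++i)
    occs[i] = Occ{occ_seed0[i], (int64_t)occ_pos0[i]};
  std::vector<int32_t> chain_id;
  int64_t ntests = 0;
  chain_occurrences(*bd, seeds, occs, eps_min, rho, chain_id, &ntests);
  return List::create(_["chain0"] = wrap(chain_id), _["n_tests"] = (double)ntests);
}

// [[Rcpp::export]]
bool cpp_coherent(SEXP ptr, int prev_seed0, double prev_pos0, int next_seed0,
                  double next_pos0, IntegerVector start0, IntegerVector len,
                  int eps_min, double rho) {
  Bundle* bd = get_bundle(ptr);
  std::vector<Seed> seeds(start0.size());
  for (int i = 0; i < start0.size(); ++i) { seeds[i].start = start0[i]; seeds[i].len = len[i]; }
  return coherent_link(*bd, seeds, Occ{prev_seed0, (int64_t)prev_pos0},
                       Occ{next_seed0, (int64_t)next_pos0}, eps_min, rho);
}

// [[Rcpp::export]]
List cpp_gotoh(std::string a, std::string b, int mismatch, int gap_open,
               int gap_extend, int band, int mode) {
  std::vector<uint8_t> ca(a.size()), cb(b.size());
  for (size_t i = 0; i < a.size(); ++i) ca[i] = (uint8_t)a[i];  // literal bytes:
  for (size_t i = 0; i < b.size(); ++i) cb[i] = (uint8_t)b[i];  // works on any alphabet
  Aln r = gotoh_align(ca.data(), (int)ca.size(), cb.data(), (int)cb.size(),
                      mismatch, gap_open, gap_extend, band, mode);
  return List::create(_["ops"] = r.ops, _["cost"] = r.cost, _["lead"] = r.lead,
                      _["cigar"] = ops_to_cigar(r.ops));
}

// [[Rcpp::export]]
List cpp_extend_chain(SEXP ptr, std::string read,
                      IntegerVector ch_start0, IntegerVector ch_len, NumericVector ch_pos0,
                      int mismatch, int gap_open, int gap_extend,
                      int band_pad, int end_slack) {
  Bundle* bd = get_bundle(ptr);
  std::vector<uint8_t> q = encode_string(read);
  const int k = ch_start0.size();
  std::vector<Seed> seeds(k);
  std::vector<Occ> occs(k);
  std::vector<int32_t> member(k);
  for (int i = 0; i < k; ++i) {
    seeds[i].start = ch_start0[i];
    seeds[i].len = ch_len[i];
    occs[i] = Occ{i, (int64_t)ch_pos0[i]};
    member[i] = i;
  }
  Scoring sc;
  sc.mismatch = mismatch; sc.gap_open = gap_open; sc.gap_extend = gap_extend;
  sc.band_pad = band_pad; sc.end_slack = end_slack;
  MapRes r = extend_chain(*bd, q, seeds, occs, member, sc);
  return List::create(_["ok"] = r.ok, _["gstart0"] = (double)r.gstart,
                      _["ops"] = r.ops, _["cigar"] = ops_to_cigar(r.ops),
                      _["matches"] = r.matches, _["mismatches"] = r.mism,
                      _["insertions"] = r.ins, _["deletions"] = r.del,
                      _["cost"] = r.cost, _["identity"] = r.identity,
                      _["span"] = (double)r.span);
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP ptr, CharacterVector seqs, List P) {
  Bundle* bd = get_bundle(ptr);
  Params prm = params_from_list(P);
  std::vector<int> o_read;
  std::vector<double> o_pos0;
  std::vector<int> o_strand, o_ma, o_mi, o_in, o_de;
  std::vector<double> o_id;
  std::vector<std::string> o_cigar;
  std::vector<int> o_mapped;
  for (int i = 0; i < seqs.size(); ++i) {
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
    std::vector<uint8_t> q = encode_string(as<std::string>(seqs[i]));
    std::vector<Hit> hits = map_read_codes(*bd, q, prm);
    if (hits.empty()) {
      o_read.push_back(i + 1); o_mapped.push_back(0);
      o_pos0.push_back(NA_REAL); o_strand.push_back(NA_INTEGER);
      o_cigar.push_back("");
      o_ma.push_back(NA_INTEGER); o_mi.push_back(NA_INTEGER);
      o_in.push_back(NA_INTEGER); o_de.push_back(NA_INTEGER);
      o_id.push_back(NA_REAL);
    } else {
      for (auto& h : hits) {
        o_read.push_back(i + 1); o_mapped.push_back(1);
        o_pos0.push_back((double)h.gstart); o_strand.push_back(h.strand);
        o_cigar.push_back(ops_to_cigar(h.ops));
        o_ma.push_back(h.matches); o_mi.push_back(h.mism);
        o_in.push_back(h.ins); o_de.push_back(h.del);
        o_id.push_back(h.identity);
      }
    }
  }
  return DataFrame::create(
      _["read"] = wrap(o_read), _["mapped"] = wrap(o_mapped),
      _["pos0"] = wrap(o_pos0), _["strand0"] = wrap(o_strand),
      _["cigar"] = wrap(o_cigar), _["matches"] = wrap(o_ma),
      _["mismatches"] = wrap(o_mi), _["insertions"] = wrap(o_in),
      _["deletions"] = wrap(o_de), _["identity"] = wrap(o_id),
      _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
IntegerVector cpp_suffix_array(RawVector bytes) {
  std::vector<uint8_t> s(bytes.begin(), bytes.end());
  std::vector<int32_t> sa = build_suffix_array(s);
  return IntegerVector(sa.begin(), sa.end());  // 0-based
}

// [[Rcpp::export]]
void cpp_save_index(SEXP ptr, std::string path) {
  save_bundle(*get_bundle(ptr), path);
}

// [[Rcpp::export]]
List cpp_load_index(std::string path) {
  Bundle* raw = load_bundle(path);
  XPtr<Bundle> xp(raw, true);
  Bundle& bd = *xp;
  const int ns = (int)bd.seg_start.size();
  NumericVector ss(ns), se(ns), sl(ns);
  IntegerVector sr(ns);
  for (int i = 0; i < ns; ++i) {
    ss[i] = (double)bd.seg_start[i]; se[i] = (double)bd.seg_end[i];
    sl[i] = (double)bd.seg_local[i]; sr[i] = bd.seg_rec[i];
  }
  NumericVector rl(bd.rec_len.size());
  CharacterVector rn(bd.rec_names.size());
  for (size_t i = 0; i < bd.rec_names.size(); ++i) {
    rn[i] = bd.rec_names[i]; rl[i] = (double)bd.rec_len[i];
  }
  std::string text(bd.text.size(), ' ');
  for (size_t i = 0; i < bd.text.size(); ++i) text[i] = decode_base(bd.text[i]);
  return List::create(_["ptr"] = xp, _["text"] = text,
                      _["seg_start"] = ss, _["seg_end"] = se, _["seg_local"] = sl,
                      _["seg_rec"] = sr, _["rec_names"] = rn, _["rec_len"] = rl,
                      _["rank_stride"] = bd.fwd.rank_stride,
                      _["sa_stride"] = bd.fwd.sa_stride,
                      _["n"] = (double)bd.n());
}
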