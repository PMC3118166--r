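#pragma once

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <string>
#include <vector>

namespace pyromap {

// Symbol codes. The sentinel must sort below everything, the inter-segment
// separator below the DNA alphabet, so no pattern over {A,C,G,T} can ever
// match across a segment boundary.
constexpr int NSYM = 6;  // 0 = '$' sentinel, 1 = '#' separator, 2..5 = A,C,G,T

inline uint8_t encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 2;
    case 'C': case 'c': return 3;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 5;
    case '$': return 0;
    default:  return 1;  // '#' and any non-ACGT symbol
  }
}

inline char decode_base(uint8_t b) { return "$#ACGT"[b]; }

// A(2)<->T(5), C(3)<->G(4); separators map to themselves.
inline uint8_t comp_base(uint8_t b) { return (b >= 2 && b <= 5) ? (uint8_t)(7 - b) : b; }

// Prefix-doubling suffix array over arbitrary byte symbols (caller supplies
// the terminated text). O(n log^2 n) worst case; ranks become distinct after
// a few rounds on genomic texts.
std::vector<int32_t> build_suffix_array(const std::vector<uint8_t>& s);

struct FM {
  int32_t n = 0;
  int32_t rank_stride = 128;
  int32_t sa_stride = 32;
  std::vector<uint8_t> bwt;
  std::array<int64_t, NSYM + 1> C{};   // C[c] = #symbols lexicographically < c
  std::vector<int32_t> ckpt;           // rank checkpoints, NSYM per block
  std::vector<int32_t> sa_sample;      // per BWT row: SA value, or -1 if unsampled

  void build(const std::vector<uint8_t>& text, int rstride, int sstride);
  void finish_from_bwt();              // recompute C and ckpt from bwt
  int32_t rank(uint8_t c, int32_t i) const;  // #occurrences of c in bwt[0,i)
  int32_t lf(int32_t row) const { uint8_t c = bwt[row]; return (int32_t)C[c] + rank(c, row); }
  int32_t sa_at(int32_t row) const;
  // Narrow [lo,hi) by prepending symbol c; returns false if empty.
  bool extend_left(uint8_t c, int32_t& lo, int32_t& hi) const;
};

struct Bundle {
  std::vector<uint8_t> text;  // encoded reference, ends with the sentinel
  FM fwd;                     // index of text: backward search
  FM rev;                     // index of reversed payload: forward longest-match
  std::vector<int64_t> seg_start, seg_end;  // global half-open, sorted
  std::vector<int64_t> seg_local;           // record-local 0-based offset of segment start
  std::vector<int32_t> seg_rec;             // record id per segment
  std::vector<std::string> rec_names;
  std::vector<int64_t> rec_len;

  int64_t n() const { return (int64_t)text.size(); }
  int seg_of(int64_t pos) const;  // segment index or -1 (separator/sentinel)
};

// ---- seeding -------------------------------------------------------------

struct Seed {
  int32_t start = 0, len = 0;       // read coordinates, 0-based
  int32_t lo = 0, hi = 0;           // SA interval in the REVERSED-text index
  int64_t occ = 0;
  bool truncated = false;           // occ > max_occ
  bool anchor = false;              // usable for chaining
  int skip = 0;                     // 0 mismatch-skip, 1 homopolymer-skip, 2 read-end
};

// Forward maximal match of q[start..) using the reversed-text index.
int longest_match(const Bundle& bd, const uint8_t* q, int m, int start,
                  int32_t& lo, int32_t& hi);
// Translate a reversed-text occurrence start into a forward-strand start.
inline int64_t rev_to_fwd(const Bundle& bd, int64_t rev_pos, int match_len) {
  return (bd.n() - 1) - match_len - rev_pos;
}

std::vector<Seed> extract_seeds(const Bundle& bd, const std::vector<uint8_t>& q,
                                int min_seed_len, int64_t max_occ,
                                int first_cursor = 0);

// ---- chaining ------------------------------------------------------------

struct Occ {
  int32_t seed;   // index into the seed vector
  int64_t pos;    // forward-strand global 0-based start
};

std::vector<Occ> collect_occurrences(const Bundle& bd, const std::vector<Seed>& seeds);

bool coherent_link(const Bundle& bd, const std::vector<Seed>& seeds,
                   const Occ& prev, const Occ& next, int eps_min, double rho);

// Greedy single left-to-right scan; every occurrence lands in exactly one
// chain. chain_id is filled per occurrence; returns number of chains and
// counts coherence tests in *ntests.
int chain_occurrences(const Bundle& bd, const std::vector<Seed>& seeds,
                      const std::vector<Occ>& occs, int eps_min, double rho,
                      std::vector<int32_t>& chain_id, int64_t* ntests);

// ---- alignment -----------------------------------------------------------

constexpr int ALN_GLOBAL = 0;      // banded global (between anchors)
constexpr int ALN_FREE_LEAD = 1;   // left read end: leading reference overhang free
constexpr int ALN_FREE_TRAIL = 2;  // right read end: trailing reference overhang free
constexpr int ALN_FREE_BOTH = 3;   // whole-read semi-global (candidate polish)

struct Aln {
  std::string ops;   // '=', 'X', 'I' (read base, no ref), 'D' (ref base, no read)
  int32_t cost = 0;
  int32_t lead = 0;  // ALN_FREE_LEAD: reference bases skipped for free at the start
};

// Minimising affine-cost alignment: match 0, mismatch `mis`, gap of length k
// costs go + k*ge. band < 0 disables banding.
Aln gotoh_align(const uint8_t* a, int la, const uint8_t* b, int lb,
                int mis, int go, int ge, int band, int mode);

struct MapRes {
  bool ok = false;
  int64_t gstart = -1;       // global 0-based leftmost reference column consumed
  std::string ops;
  int32_t matches = 0, mism = 0, ins = 0, del = 0, cost = 0;
  double identity = 0.0;
  int64_t span = 0;          // seed bases of the source chain
};

struct Scoring {
  int mismatch = 1, gap_open = 1, gap_extend = 1;
  int band_pad = 8, end_slack = 16;
};

MapRes extend_chain(const Bundle& bd, const std::vector<uint8_t>& q,
                    const std::vector<Seed>& seeds, const std::vector<Occ>& occs,
                    const std::vector<int32_t>& member_idx, const Scoring& sc);

// ---- whole-read mapping --------------------------------------------------

struct Params {
  int min_seed_len = 10;
  int64_t max_occ = 500;
  int eps_min = 5;
  double rho = 0.1;
  int top = 8;
  std::vector<int> restart_offsets{0, 3, 7, 11, 15, 19};
  int rescue = 1;                // dense k-mer fallback anchoring
  int rescue_k = 9;
  int rescue_stride = 1;
  int64_t rescue_max_occ = 64;
  double rescue_identity = 68.0; // trigger when the best hit is weaker
  int polish = 1;                // final whole-read semi-global refinement
  Scoring sc;
  int accept_mode = 0;       // 0 identity, 1 errors
  double t = 50.0;           // identity threshold (percent)
  int e = 0;                 // max errors
  int report_all = 0;        // 0 best, 1 all
  int both_strands = 1;
};

struct Hit {
  int64_t gstart = -1;
  int strand = 0;            // 0 forward, 1 reverse
  std::string ops;
  int32_t matches = 0, mism = 0, ins = 0, del = 0;
  double identity = 0.0;
  int32_t errors = 0;
};

std::vector<Hit> map_read_codes(const Bundle& bd, const std::vector<uint8_t>& q,
                                const Params& P);

std::string ops_to_cigar(const std::string& ops);

void save_bundle(const Bundle& bd, const std::string& path);
Bundle* load_bundle(const std::string& path);

inline std::vector<uint8_t> encode_string(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = encode_base(s[i]);
  return v;
}

}  // namespace pyromap
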