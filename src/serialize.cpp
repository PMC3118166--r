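#include "core.h"
#include <cstdio>
#include <fstream>
#include <memory>

// Binary index file layout (little-endian, all integers fixed width):
//   char[8]  magic  "PYMIDX01"
//   i32      format version (1)
//   i32      rank_stride, i32 sa_stride
//   i64      n (text length incl. sentinel)
//   i32      n_records; per record: i32 name length, bytes, i64 record length
//   i32      n_segments; then i64 seg_start[], i64 seg_end[], i64 seg_local[],
//            i32 seg_rec[]
//   u8[n]    encoded text
//   per index (forward then reversed): u8 bwt[n]; i64 n_samples;
//            (i32 row, i32 value) pairs
// Rank checkpoints and the C table are recomputed on load (linear scan).

namespace pyromap {
namespace {

template <typename T> void wr(std::ofstream& f, const T& x) {
  f.write(reinterpret_cast<const char*>(&x), sizeof(T));
}
template <typename T> void rd(std::ifstream& f, T& x) {
  f.read(reinterpret_cast<char*>(&x), sizeof(T));
  if (!f) Rcpp::stop("index file truncated or corrupt");
}

void write_fm(std::ofstream& f, const FM& fm) {
  f.write(reinterpret_cast<const char*>(fm.bwt.data()), fm.n);
  int64_t ns = 0;
  for (int32_t i = 0; i < fm.n; ++i) ns += (fm.sa_sample[i] >= 0);
  wr(f, ns);
  for (int32_t i = 0; i < fm.n; ++i)
    if (fm.sa_sample[i] >= 0) { wr(f, i); wr(f, fm.sa_sample[i]); }
}

void read_fm(std::ifstream& f, FM& fm, int64_t n, int rstride, int sstride) {
  fm.n = (int32_t)n;
  fm.rank_stride = rstride;
  fm.sa_stride = sstride;
  fm.bwt.resize(n);
  f.read(reinterpret_cast<char*>(fm.bwt.data()), n);
  if (!f) Rcpp::stop("index file truncated or corrupt");
  int64_t ns;
  rd(f, ns);
  fm.sa_sample.assign(n, -1);
  for (int64_t k = 0; k < ns; ++k) {
    int32_t row, val;
    rd(f, row); rd(f, val);
    if (row < 0 || row >= n) Rcpp::stop("index file truncated or corrupt");
    fm.sa_sample[row] = val;
  }
  fm.finish_from_bwt();
}

}  // namespace

void save_bundle(const Bundle& bd, const std::string& path) {
  std::ofstream f(path.c_str(), std::ios::binary);
  if (!f) Rcpp::stop("cannot open '%s' for writing", path);
  f.write("PYMIDX01", 8);
  wr(f, (int32_t)1);
  wr(f, bd.fwd.rank_stride);
  wr(f, bd.fwd.sa_stride);
  wr(f, (int64_t)bd.text.size());
  wr(f, (int32_t)bd.rec_names.size());
  for (size_t r = 0; r < bd.rec_names.size(); ++r) {
    wr(f, (int32_t)bd.rec_names[r].size());
    f.write(bd.rec_names[r].data(), bd.rec_names[r].size());
    wr(f, bd.rec_len[r]);
  }
  wr(f, (int32_t)bd.seg_start.size());
  for (auto v : bd.seg_start) wr(f, v);
  for (auto v : bd.seg_end) wr(f, v);
  for (auto v : bd.seg_local) wr(f, v);
  for (auto v : bd.seg_rec) wr(f, v);
  f.write(reinterpret_cast<const char*>(bd.text.data()), bd.text.size());
  write_fm(f, bd.fwd);
  write_fm(f, bd.rev);
  if (!f) Rcpp::stop("write to '%s' failed", path);
}

Bundle* load_bundle(const std::string& path) {
  std::ifstream f(path.c_str(), std::ios::binary);
  if (!f) Rcpp::stop("cannot open '%s'", path);
  char magic[8];
  f.read(magic, 8);
  if (!f || std::string(magic, 8) != "PYMIDX01")
    Rcpp::stop("'%s' is not a pyromap index file", path);
  int32_t version;
  rd(f, version);
  if (version != 1)
    Rcpp::stop("index format version %d not supported (expected 1)", version);
  int32_t rstride, sstride;
  rd(f, rstride); rd(f, sstride);
  int64_t n;
  rd(f, n);
  if (n <= 0) Rcpp::stop("index file truncated or corrupt");
  std::unique_ptr<Bundle> bd(new Bundle());
  int32_t nrec;
  rd(f, nrec);
  for (int32_t r = 0; r < nrec; ++r) {
    int32_t nl;
    rd(f, nl);
    if (nl < 0 || nl > 1 << 20) Rcpp::stop("index file truncated or corrupt");
    std::string nm(nl, '\0');
    f.read(&nm[0], nl);
    if (!f) Rcpp::stop("index file truncated or corrupt");
    int64_t rl;
    rd(f, rl);
    bd->rec_names.push_back(nm);
    bd->rec_len.push_back(rl);
  }
  int32_t nseg;
  rd(f, nseg);
  bd->seg_start.resize(nseg); bd->seg_end.resize(nseg);
  bd->seg_local.resize(nseg); bd->seg_rec.resize(nseg);
  for (auto& v : bd->seg_start) rd(f, v);
  for (auto& v : bd->seg_end) rd(f, v);
  for (auto& v : bd->seg_local) rd(f, v);
  for (auto& v : bd->seg_rec) rd(f, v);
  bd->text.resize(n);
  f.read(reinterpret_cast<char*>(bd->text.data()), n);
  if (!f) Rcpp::stop("index file truncated or corrupt");
  read_fm(f, bd->fwd, n, rstride, sstride);
  read_fm(f, bd->rev, n, rstride, sstride);
  return bd.release();
}

}  // namespace pyromap
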