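#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// 2-bit k-mer machinery shared by the vector-read scanner and the
// unique-k-mer flank anchor mapper. k is capped at 31 so a k-mer fits in
// one 64-bit word; k-mers containing non-ACGT characters are skipped.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// enumerate valid k-mers of s; calls f(code, offset)
template <typename F>
static void scan_kmers(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(code, (int64_t)(i + 1 - k));
  }
}

static uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

struct KmerIndex {
  int k;
  std::vector<std::string> chroms;
  // value: (chrom_idx << 40) | pos for unique k-mers; UINT64_MAX marks a
  // k-mer seen more than once (repeats never vote)
  std::unordered_map<uint64_t, uint64_t> pos;
};
static const uint64_t REPEAT = ~0ULL;

// [[Rcpp::export]]
SEXP cpp_build_kmer_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  for (int ci = 0; ci < seqs.size(); ++ci) {
    idx->chroms.push_back(as<std::string>(nm[ci]));
    std::string s = as<std::string>(seqs[ci]);
    scan_kmers(s, k, [&](uint64_t code, int64_t off) {
      auto it = idx->pos.find(code);
      uint64_t val = ((uint64_t)ci << 40) | (uint64_t)off;
      if (it == idx->pos.end()) idx->pos[code] = val;
      else it->second = REPEAT;
    });
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// Map one flank by unique-k-mer junction voting. side: 0 = left flank
// (sequence 5' of the vector in the read), 1 = right flank. Each k-mer of
// the flank that occurs uniquely in the reference implies a junction
// coordinate; the modal implied coordinate wins if it has >= min_votes
// and >= 2x the runner-up's votes. Both reference strands are considered.
// [[Rcpp::export]]
List cpp_map_flank(std::string flank, SEXP index_ptr, int side,
                   int min_votes) {
  XPtr<KmerIndex> idx(index_ptr);
  const int k = idx->k;
  const int64_t Lf = flank.size();
  std::unordered_map<uint64_t, int> votes;  // key: (chrom<<41)|(strand<<40)|junction
  if (Lf >= k) {
    scan_kmers(flank, k, [&](uint64_t code, int64_t i) {
      // forward-strand match
      auto it = idx->pos.find(code);
      if (it != idx->pos.end() && it->second != REPEAT) {
        uint64_t ci = it->second >> 40;
        int64_t p = (int64_t)(it->second & ((1ULL << 40) - 1));
        int64_t junction = (side == 0) ? p - i + Lf : p - i;
        if (junction >= 0)
          votes[(ci << 41) | (uint64_t)junction]++;
      }
      // reverse-strand match: revcomp(kmer) occurs in the reference
      uint64_t rc = revcomp_code(code, k);
      auto it2 = idx->pos.find(rc);
      if (it2 != idx->pos.end() && it2->second != REPEAT) {
        uint64_t ci = it2->second >> 40;
        int64_t p = (int64_t)(it2->second & ((1ULL << 40) - 1));
        // on the minus strand the revcomp of a left flank occupies
        // [junction, junction+Lf) in ref-forward coordinates and the
        // revcomp of a right flank occupies [junction-Lf, junction)
        int64_t junction = (side == 0) ? p - (Lf - k - i) : p + k + i;
        if (junction >= 0)
          votes[(ci << 41) | (1ULL << 40) | (uint64_t)junction]++;
      }
    });
  }
  // modal coordinate vs runner-up
  uint64_t best_key = 0; int best = 0, second = 0;
  for (auto& kv : votes) {
    if (kv.second > best) { second = best; best = kv.second; best_key = kv.first; }
    else if (kv.second > second) second = kv.second;
  }
  bool placed = best >= min_votes && best >= 2 * second;
  if (!placed) {
    return List::create(_["placed"] = false, _["chrom"] = NA_STRING,
                        _["junction"] = NA_REAL, _["strand"] = NA_STRING,
                        _["votes"] = best);
  }
  uint64_t ci = best_key >> 41;
  int strand_bit = (best_key >> 40) & 1ULL;
  double junction = (double)(best_key & ((1ULL << 40) - 1));
  return List::create(_["placed"] = true,
                      _["chrom"] = idx->chroms[ci],
                      _["junction"] = junction,
                      _["strand"] = strand_bit ? "-" : "+",
                      _["votes"] = best);
}

// Scan reads for vector content by distinct shared k-mers on either
// strand. Returns one row per hit: read index (1-based), match span in
// the read (0-based half-open, minimal seed cover plus ungapped
// extension), orientation (+/-), and the distinct-k-mer count.
// [[Rcpp::export]]
DataFrame cpp_find_vector_hits(CharacterVector reads, std::string vec,
                               int k, int min_kmers) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, int64_t> fwd, rev;  // kmer -> first offset
  scan_kmers(vec, k, [&](uint64_t code, int64_t off) {
    if (!fwd.count(code)) fwd[code] = off;
  });
  std::string rcv(vec.rbegin(), vec.rend());
  for (auto& c : rcv) {
    int b = base2bits(c);
    c = (b < 0) ? 'N' : "TGCA"[b];
  }
  scan_kmers(rcv, k, [&](uint64_t code, int64_t off) {
    if (!rev.count(code)) rev[code] = off;
  });

  std::vector<int> out_read;
  std::vector<double> out_start, out_end;
  std::vector<std::string> out_orient;
  std::vector<int> out_nkmer;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    std::unordered_set<uint64_t> seen;
    int nf = 0, nr = 0;
    int64_t f_lo = -1, f_hi = -1, f_vlo = 0, f_vhi = 0;
    int64_t r_lo = -1, r_hi = -1, r_vlo = 0, r_vhi = 0;
    scan_kmers(rd, k, [&](uint64_t code, int64_t i) {
      auto itf = fwd.find(code);
      bool newk = false;
      if (itf != fwd.end()) {
        if (seen.insert(code).second) newk = true;
        if (newk) ++nf;
        if (f_lo < 0 || i < f_lo) { f_lo = i; f_vlo = itf->second; }
        if (i + k > f_hi) { f_hi = i + k; f_vhi = itf->second + k; }
      }
      auto itr = rev.find(code);
      if (itr != rev.end()) {
        if (seen.insert(code).second && itf == fwd.end()) ++nr;
        if (r_lo < 0 || i < r_lo) { r_lo = i; r_vlo = itr->second; }
        if (i + k > r_hi) { r_hi = i + k; r_vhi = itr->second + k; }
      }
    });
    if (nf + nr < min_kmers) continue;
    bool forward = nf >= nr;
    const std::string& tpl = forward ? vec : rcv;
    int64_t lo = forward ? f_lo : r_lo, hi = forward ? f_hi : r_hi;
    int64_t vlo = forward ? f_vlo : r_vlo, vhi = forward ? f_vhi : r_vhi;
    // ungapped extension against the matching template strand
    while (lo > 0 && vlo > 0 && rd[lo - 1] == tpl[vlo - 1]) { --lo; --vlo; }
    while (hi < (int64_t)rd.size() && vhi < (int64_t)tpl.size() &&
           rd[hi] == tpl[vhi]) { ++hi; ++vhi; }
    out_read.push_back(ri + 1);
    out_start.push_back((double)lo);
    out_end.push_back((double)hi);
    out_orient.push_back(forward ? "+" : "-");
    out_nkmer.push_back(nf + nr);
  }
  return DataFrame::create(_["read_idx"] = out_read,
                           _["start"] = out_start, _["end"] = out_end,
                           _["orientation"] = out_orient,
                           _["n_kmers"] = out_nkmer,
                           _["stringsAsFactors"] = false);
}
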