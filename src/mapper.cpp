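// Deterministic best-hit read mapper: exact k-mer seeding on both
// strands, full-read Hamming extension, single best alignment per read.
// Tie-break order: fewest mismatches, lowest contig index, leftmost
// position, forward strand.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

struct KmerIndex {
  int k;
  uint64_t mask;
  std::vector<std::string> ref;
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;
};

static void build_index(KmerIndex& idx, const CharacterVector& contigs,
                        int k) {
  idx.k = k;
  idx.mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int nc = contigs.size();
  idx.ref.resize(nc);
  for (int i = 0; i < nc; ++i) idx.ref[i] = as<std::string>(contigs[i]);
  size_t total = 0;
  for (int i = 0; i < nc; ++i) total += idx.ref[i].size();
  idx.table.reserve(total);
  for (int ci = 0; ci < nc; ++ci) {
    const std::string& s = idx.ref[ci];
    const int L = (int)s.size();
    uint64_t kmer = 0;
    int valid = 0;
    for (int j = 0; j < L; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & idx.mask;
      if (++valid >= k)
        idx.table[kmer].push_back(((uint64_t)ci << 32) |
                                  (uint64_t)(j - k + 1));
    }
  }
}

// [[Rcpp::export]]
SEXP build_index_cpp(CharacterVector contigs, int k) {
  if (k < 1 || k > 32) stop("seed length k must be in [1, 32]");
  XPtr<KmerIndex> p(new KmerIndex(), true);
  build_index(*p, contigs, k);
  return p;
}

static List map_with(const KmerIndex& idx, const CharacterVector& reads) {
  const int k = idx.k;
  const int nr = reads.size();
  IntegerVector out_ref(nr), out_pos(nr), out_mm(nr);
  LogicalVector out_rev(nr), out_mapped(nr);

  std::vector<int> seed_offsets;
  std::vector<uint64_t> seen;
  std::string rev;
  for (int ri = 0; ri < nr; ++ri) {
    SEXP rs = STRING_ELT(reads, ri);
    const char* fwd = CHAR(rs);
    const int L = (int)LENGTH(rs);
    if (L < k) { out_mapped[ri] = false; continue; }
    rev.assign(L, 'N');
    for (int j = 0; j < L; ++j) rev[j] = comp(fwd[L - 1 - j]);

    // non-overlapping seeds plus the final window
    seed_offsets.clear();
    for (int o = 0; o + k <= L; o += k) seed_offsets.push_back(o);
    if (seed_offsets.empty() || seed_offsets.back() != L - k)
      seed_offsets.push_back(L - k);

    int best_mm = -1, best_ci = -1, best_pos = -1, best_rev = 0;
    seen.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const char* q = strand == 0 ? fwd : rev.data();
      for (size_t si = 0; si < seed_offsets.size(); ++si) {
        const int o = seed_offsets[si];
        uint64_t kmer = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = base2bits(q[o + j]);
          if (b < 0) { ok = false; break; }
          kmer = (kmer << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
          it = idx.table.find(kmer & idx.mask);
        if (it == idx.table.end()) continue;
        const std::vector<uint64_t>& hits = it->second;
        for (size_t hi = 0; hi < hits.size(); ++hi) {
          const int ci = (int)(hits[hi] >> 32);
          const long start = (long)(uint32_t)hits[hi] - o;
          if (start < 0 || start + L > (long)idx.ref[ci].size()) continue;
          uint64_t key = ((uint64_t)strand << 63) |
            ((uint64_t)ci << 32) | (uint64_t)start;
          bool dup = false;
          for (size_t sj = 0; sj < seen.size(); ++sj)
            if (seen[sj] == key) { dup = true; break; }
          if (dup) continue;
          seen.push_back(key);
          const char* r = idx.ref[ci].data() + start;
          int mm = 0;
          for (int j = 0; j < L; ++j) if (r[j] != q[j]) ++mm;
          bool better;
          if (best_mm < 0) better = true;
          else if (mm != best_mm) better = mm < best_mm;
          else if (ci != best_ci) better = ci < best_ci;
          else if ((int)start != best_pos) better = (int)start < best_pos;
          else better = strand < best_rev;
          if (better) {
            best_mm = mm; best_ci = ci; best_pos = (int)start;
            best_rev = strand;
          }
        }
      }
    }
    if (best_mm < 0) {
      out_mapped[ri] = false;
    } else {
      out_mapped[ri] = true;
      out_ref[ri] = best_ci + 1;     // 1-based contig index
      out_pos[ri] = best_pos + 1;    // 1-based leftmost position
      out_rev[ri] = best_rev == 1;
      out_mm[ri] = best_mm;
    }
  }
  return List::create(_["mapped"] = out_mapped, _["ref"] = out_ref,
                      _["pos"] = out_pos, _["rev"] = out_rev,
                      _["mismatches"] = out_mm);
}

// [[Rcpp::export]]
List map_with_index_cpp(SEXP index, CharacterVector reads) {
  XPtr<KmerIndex> p(index);
  return map_with(*p, reads);
}

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector contigs, CharacterVector reads, int k) {
  if (k < 1 || k > 32) stop("seed length k must be in [1, 32]");
  KmerIndex idx;
  build_index(idx, contigs, k);
  return map_with(idx, reads);
}

// Substitution-only sequencing errors at a fixed per-base rate, each
// errored base replaced by a uniformly chosen different base. Uses R's
// RNG stream so results are reproducible from set.seed().
// [[Rcpp::export]]
CharacterVector inject_errors_cpp(CharacterVector reads, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = reads.size();
  CharacterVector out(n);
  GetRNGstate();
  std::string buf;
  for (int i = 0; i < n; ++i) {
    SEXP rs = STRING_ELT(reads, i);
    const char* s = CHAR(rs);
    const int L = (int)LENGTH(rs);
    buf.assign(s, L);
    for (int j = 0; j < L; ++j) {
      if (unif_rand() < rate) {
        int b = base2bits(buf[j]);
        if (b < 0) continue;
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        buf[j] = bases[(b + shift) % 4];
      }
    }
    out[i] = buf;
  }
  PutRNGstate();
  return out;
}

// Reverse complement, vectorised (used when writing SAM records).
// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    const int L = (int)s.size();
    std::string r(L, 'N');
    for (int j = 0; j < L; ++j) r[j] = comp(s[L - 1 - j]);
    out[i] = r;
  }
  return out;
}
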