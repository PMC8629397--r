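#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoded exact k-mer counting, k <= 32. Windows containing any
// character outside {A,C,G,T} (case-insensitive) are skipped entirely.
// Canonical mode keys each k-mer by min(kmer, revcomp(kmer)) on the
// 2-bit encoding, which coincides with lexicographic order on ACGT.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, uint32_t> kmer_map;

static void count_into(const std::string& seq, int k, bool canonical,
                       kmer_map& counts) {
  const size_t n = seq.size();
  if ((int)n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rc_shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;  // length of current run of valid bases
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << rc_shift);
    if (++valid >= k) {
      uint64_t key = canonical ? std::min(fwd, rev) : fwd;
      ++counts[key];
    }
  }
}

static std::string decode_kmer(uint64_t key, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[key & 3ULL];
    key >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
List cpp_kmer_table(CharacterVector seqs, int k, bool canonical) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  kmer_map counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    count_into(std::string(seqs[i]), k, canonical, counts);
  }
  const size_t sz = counts.size();
  CharacterVector kmers(sz);
  IntegerVector cnt(sz);
  size_t idx = 0;
  for (kmer_map::const_iterator it = counts.begin(); it != counts.end(); ++it) {
    kmers[idx] = decode_kmer(it->first, k);
    cnt[idx] = (int)it->second;
    ++idx;
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// Histogram o_h = number of distinct k-mers with multiplicity h,
// h = 1..max multiplicity; avoids materialising k-mer strings.
// [[Rcpp::export]]
NumericVector cpp_kmer_histogram(CharacterVector seqs, int k, bool canonical) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  kmer_map counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    count_into(std::string(seqs[i]), k, canonical, counts);
  }
  uint32_t hmax = 0;
  for (kmer_map::const_iterator it = counts.begin(); it != counts.end(); ++it)
    hmax = std::max(hmax, it->second);
  NumericVector o(hmax);
  for (kmer_map::const_iterator it = counts.begin(); it != counts.end(); ++it)
    o[it->second - 1] += 1.0;
  return o;
}

// Multiplicities of the `top` most abundant k-mers, descending.
// [[Rcpp::export]]
NumericVector cpp_kmer_top_counts(CharacterVector seqs, int k, bool canonical,
                                  int top) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  kmer_map counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    count_into(std::string(seqs[i]), k, canonical, counts);
  }
  std::vector<uint32_t> v;
  v.reserve(counts.size());
  for (kmer_map::const_iterator it = counts.begin(); it != counts.end(); ++it)
    v.push_back(it->second);
  std::sort(v.begin(), v.end(), std::greater<uint32_t>());
  const int nout = std::min<int>(top, (int)v.size());
  NumericVector out(nout);
  for (int i = 0; i < nout; ++i) out[i] = (double)v[i];
  return out;
}
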