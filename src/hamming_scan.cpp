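#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Seed-and-extend Hamming-bounded scan of query k-mers against transcripts.
//
// Pigeonhole: a match with at most max_mm substitutions of a k-mer must
// contain an exact seed of length floor(k_min / (max_mm + 1)) at one of
// max_mm + 1 fixed, non-overlapping offsets. We index all seed-length words
// of every transcript (2-bit packed), look up each query chunk, and verify
// the full k-mer by direct Hamming count at each candidate offset.
//
// Transcript positions containing non-ACGT characters contribute no seeds
// and can never verify, matching the brute-force definition over the DNA
// alphabet.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// [[Rcpp::export(name = ".hamming_scan_cpp")]]
DataFrame hamming_scan_cpp(CharacterVector kmers, CharacterVector transcripts,
                           CharacterVector transcript_ids, int max_mm) {
  const int n_tx = transcripts.size();
  const int n_q = kmers.size();

  int k_min = 0;
  for (int i = 0; i < n_q; ++i) {
    int k = LENGTH(STRING_ELT(kmers, i));
    if (k_min == 0 || k < k_min) k_min = k;
  }
  if (n_q == 0 || n_tx == 0) {
    return DataFrame::create(_["kmer_index"] = IntegerVector(0),
                             _["transcript_index"] = IntegerVector(0),
                             _["start"] = IntegerVector(0),
                             _["mismatches"] = IntegerVector(0));
  }
  int seed_len = k_min / (max_mm + 1);
  if (seed_len < 1) seed_len = 1;
  if (seed_len > 31) seed_len = 31;  // 2-bit packing bound

  // index: packed seed -> (transcript, position) occurrences
  std::vector<std::string> tx(n_tx);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  const uint64_t mask =
      (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1ULL);
  for (int t = 0; t < n_tx; ++t) {
    tx[t] = as<std::string>(transcripts[t]);
    const std::string& s = tx[t];
    if ((int)s.size() < seed_len) continue;
    uint64_t h = 0;
    int valid = 0;  // run length of valid bases ending here
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_len) {
        index[h].push_back(std::make_pair(t, i - seed_len + 1));
      }
    }
  }

  std::vector<int> out_q, out_t, out_pos, out_mm;
  std::vector<std::pair<int, int> > seen;  // candidates verified for this query

  for (int q = 0; q < n_q; ++q) {
    const std::string km = as<std::string>(kmers[q]);
    const int k = (int)km.size();
    seen.clear();
    const int n_chunks = max_mm + 1;
    for (int c = 0; c < n_chunks; ++c) {
      const int off = c * seed_len;
      if (off + seed_len > k) break;
      uint64_t h = 0;
      bool ok = true;
      for (int i = 0; i < seed_len; ++i) {
        int b = base2bits(km[off + i]);
        if (b < 0) { ok = false; break; }
        h = (h << 2) | (uint64_t)b;
      }
      if (!ok) continue;
      std::unordered_map<uint64_t,
          std::vector<std::pair<int, int> > >::const_iterator it =
          index.find(h & mask);
      if (it == index.end()) continue;
      for (size_t j = 0; j < it->second.size(); ++j) {
        const int t = it->second[j].first;
        const int start = it->second[j].second - off;
        if (start < 0 || start + k > (int)tx[t].size()) continue;
        bool dup = false;  // candidate already verified via an earlier chunk
        for (size_t s2 = 0; s2 < seen.size(); ++s2) {
          if (seen[s2].first == t && seen[s2].second == start) { dup = true; break; }
        }
        if (dup) continue;
        seen.push_back(std::make_pair(t, start));
        int mm = 0;
        const std::string& s = tx[t];
        for (int i = 0; i < k && mm <= max_mm; ++i) {
          char ch = s[start + i];
          if (base2bits(ch) < 0) { mm = max_mm + 1; break; }
          if (ch != km[i]) ++mm;
        }
        if (mm <= max_mm) {
          out_q.push_back(q + 1);
          out_t.push_back(t + 1);
          out_pos.push_back(start);
          out_mm.push_back(mm);
        }
      }
    }
  }

  return DataFrame::create(_["kmer_index"] = wrap(out_q),
                           _["transcript_index"] = wrap(out_t),
                           _["start"] = wrap(out_pos),
                           _["mismatches"] = wrap(out_mm));
}
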