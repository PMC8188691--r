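// Exact canonical k-mer index and classifier.
//
// Genomes are decomposed into canonical k-mers (lexicographic min of the
// k-mer and its reverse complement under the 2-bit encoding A=0 C=1 G=2 T=3)
// stored in an open-addressing hash table k-mer -> species taxid(s). Most
// k-mers belong to a single species, so the table stores one int32 per slot:
// positive values are taxids, negative values index a side table of
// multi-species posting lists. Classification walks each read's k-mers,
// votes per species, and reports the top-voted species (all of them when
// tied) plus the number of matching k-mers. k is capped at 31 so a k-mer
// packs into 62 bits and the all-ones word can serve as the empty-slot
// sentinel. Bases outside ACGT break the rolling window (no k-mer spans N).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const uint64_t SLOT_EMPTY = ~0ULL;

// splitmix64 finalizer: spreads consecutive k-mer codes across buckets
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct KmerIndexCpp {
  int k;
  std::vector<uint64_t> keys;
  std::vector<int32_t> vals;              // >0: taxid; <0: -(multi index + 1)
  std::vector<std::vector<int32_t>> multi; // sorted multi-species postings
  uint64_t mask = 0;
  size_t n_keys = 0;

  void init(size_t hint) {
    size_t slots = 1024;
    while (slots < 2 * hint && slots < (1ULL << 26)) slots <<= 1;
    keys.assign(slots, SLOT_EMPTY);
    vals.assign(slots, 0);
    mask = slots - 1;
  }

  void grow() {
    std::vector<uint64_t> old_keys;
    std::vector<int32_t> old_vals;
    old_keys.swap(keys);
    old_vals.swap(vals);
    size_t slots = (old_keys.size()) << 1;
    keys.assign(slots, SLOT_EMPTY);
    vals.assign(slots, 0);
    mask = slots - 1;
    for (size_t i = 0; i < old_keys.size(); ++i) {
      if (old_keys[i] == SLOT_EMPTY) continue;
      uint64_t s = mix64(old_keys[i]) & mask;
      while (keys[s] != SLOT_EMPTY) s = (s + 1) & mask;
      keys[s] = old_keys[i];
      vals[s] = old_vals[i];
    }
  }

  void insert(uint64_t km, int32_t tax) {
    if (2 * (n_keys + 1) > keys.size()) grow();
    uint64_t s = mix64(km) & mask;
    while (true) {
      if (keys[s] == SLOT_EMPTY) {
        keys[s] = km;
        vals[s] = tax;
        ++n_keys;
        return;
      }
      if (keys[s] == km) {
        int32_t v = vals[s];
        if (v > 0) {
          if (v != tax) {
            multi.push_back({std::min(v, tax), std::max(v, tax)});
            vals[s] = -(int32_t)multi.size();
          }
        } else {
          std::vector<int32_t>& m = multi[-v - 1];
          if (!std::binary_search(m.begin(), m.end(), tax)) {
            m.insert(std::lower_bound(m.begin(), m.end(), tax), tax);
          }
        }
        return;
      }
      s = (s + 1) & mask;
    }
  }

  // returns 0 when absent, a taxid, or a negative multi reference
  inline int32_t find(uint64_t km) const {
    uint64_t s = mix64(km) & mask;
    while (true) {
      if (keys[s] == km) return vals[s];
      if (keys[s] == SLOT_EMPTY) return 0;
      s = (s + 1) & mask;
    }
  }
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// Calls fn(canonical) for every ACGT-only k-mer of seq.
template <typename F>
static void for_each_canonical(const char* seq, int len, int k, F fn) {
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int rc_shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (int i = 0; i < len; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << rc_shift);
    if (++run >= k) fn(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector seqs, IntegerVector taxids, int k) {
  if (seqs.size() != taxids.size()) stop("seqs and taxids must have equal length");
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  for (R_xlen_t s = 0; s < taxids.size(); ++s) {
    if (taxids[s] <= 0) stop("taxids must be positive");
  }
  KmerIndexCpp* idx = new KmerIndexCpp();
  idx->k = k;
  size_t hint = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    int len = LENGTH(STRING_ELT(seqs, s));
    if (len >= k) hint += (size_t)(len - k + 1);
  }
  idx->init(hint);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    int len = LENGTH(STRING_ELT(seqs, s));
    int32_t tax = taxids[s];
    for_each_canonical(str, len, k, [&](uint64_t km) { idx->insert(km, tax); });
  }
  XPtr<KmerIndexCpp> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".kmer_index_size")]]
double kmer_index_size(SEXP xp) {
  XPtr<KmerIndexCpp> idx(xp);
  return (double)idx->n_keys;
}

// [[Rcpp::export(name = ".kmer_index_lookup")]]
List kmer_index_lookup(SEXP xp, CharacterVector kmers) {
  XPtr<KmerIndexCpp> idx(xp);
  int k = idx->k;
  List out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* str = CHAR(STRING_ELT(kmers, i));
    int len = LENGTH(STRING_ELT(kmers, i));
    if (len != k) stop("query k-mer length does not match index k");
    std::vector<int32_t> hit;
    for_each_canonical(str, len, k, [&](uint64_t km) {
      int32_t v = idx->find(km);
      if (v > 0) hit.assign(1, v);
      else if (v < 0) hit = idx->multi[-v - 1];
    });
    out[i] = IntegerVector(hit.begin(), hit.end());
  }
  return out;
}

// [[Rcpp::export(name = ".kmer_classify")]]
List kmer_classify(SEXP xp, CharacterVector reads, int min_hits) {
  XPtr<KmerIndexCpp> idx(xp);
  int k = idx->k;
  R_xlen_t n = reads.size();
  IntegerVector n_hits(n);
  List top(n);

  std::vector<std::pair<int32_t, int>> votes; // (taxid, count); few entries
  auto vote = [&](int32_t tax) {
    for (auto& v : votes) {
      if (v.first == tax) { ++v.second; return; }
    }
    votes.push_back({tax, 1});
  };

  for (R_xlen_t i = 0; i < n; ++i) {
    const char* str = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    votes.clear();
    int hits = 0;
    for_each_canonical(str, len, k, [&](uint64_t km) {
      int32_t v = idx->find(km);
      if (v == 0) return;
      ++hits;
      if (v > 0) {
        vote(v);
      } else {
        for (int32_t tax : idx->multi[-v - 1]) vote(tax);
      }
    });
    n_hits[i] = hits;
    if (hits < min_hits || votes.empty()) {
      top[i] = IntegerVector(0);
      continue;
    }
    int best = 0;
    for (auto& v : votes) if (v.second > best) best = v.second;
    std::vector<int32_t> tied;
    for (auto& v : votes) if (v.second == best) tied.push_back(v.first);
    std::sort(tied.begin(), tied.end());
    top[i] = IntegerVector(tied.begin(), tied.end());
  }
  return List::create(_["n_hits"] = n_hits, _["top"] = top);
}
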