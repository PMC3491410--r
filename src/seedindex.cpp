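#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit code shared by the base alphabet (A,C,G,T) and the color digits
// (0,1,2,3); -1 marks a symbol that can never match a sanitized reference.
static inline int code4(char c) {
  switch (c) {
  case 'A': case '0': return 0;
  case 'C': case '1': return 1;
  case 'G': case '2': return 2;
  case 'T': case '3': return 3;
  default: return -1;
  }
}

// Hash-table index of all seed_len-mers of a set of chromosome texts,
// concatenated with per-chromosome offsets so hits never span chromosomes.
struct SeedIndex {
  std::string text;
  std::vector<size_t> offsets;   // size n_chrom + 1
  int seed_len;
  std::unordered_map<uint64_t, std::vector<int32_t> > table;
};

// [[Rcpp::export]]
SEXP si_build(CharacterVector seqs, int seed_len) {
  if (seed_len < 1 || seed_len > 31) stop("seed_len must be in 1..31");
  SeedIndex* idx = new SeedIndex();
  idx->seed_len = seed_len;
  size_t total = 0;
  for (int i = 0; i < seqs.size(); ++i) total += LENGTH(STRING_ELT(seqs, i));
  idx->text.reserve(total);
  idx->offsets.push_back(0);
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    idx->text.append(s);
    idx->offsets.push_back(idx->text.size());
  }
  const uint64_t mask = (seed_len == 31) ? ((1ULL << 62) - 1)
                                         : ((1ULL << (2 * seed_len)) - 1);
  for (size_t c = 0; c + 1 < idx->offsets.size(); ++c) {
    size_t beg = idx->offsets[c], end = idx->offsets[c + 1];
    if (end - beg < (size_t)seed_len) continue;
    uint64_t key = 0;
    int valid = 0;  // length of current valid run feeding the rolling hash
    for (size_t p = beg; p < end; ++p) {
      int b = code4(idx->text[p]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_len)
        idx->table[key].push_back((int32_t)(p - seed_len + 1));
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

static void hamming_verify(const std::string& text, size_t beg, size_t end,
                           const char* q, int qlen, int k,
                           size_t start, std::vector<int>& out_pos,
                           std::vector<int>& out_mm) {
  if (start < beg || start + qlen > end) return;
  int mm = 0;
  for (int j = 0; j < qlen; ++j) {
    if (text[start + j] != q[j] && ++mm > k) return;
  }
  out_pos.push_back((int)(start - beg));
  out_mm.push_back(mm);
}

// Enumerate all occurrences of `query` with Hamming distance <= k using
// k+1 disjoint pigeonhole seeds. Caller guarantees (k+1)*seed_len <= |query|.
// [[Rcpp::export]]
List si_find(SEXP sip, std::string query, int k) {
  XPtr<SeedIndex> idx(sip);
  const int qlen = (int)query.size();
  const int s = idx->seed_len;
  if ((k + 1) * s > qlen) stop("query too short for this seed index");
  std::vector<int64_t> cand;  // global candidate starts
  const uint64_t mask = (s == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * s)) - 1);
  for (int i = 0; i <= k; ++i) {
    int off = i * s;
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < s; ++j) {
      int b = code4(query[off + j]);
      if (b < 0) { ok = false; break; }
      key = ((key << 2) | (uint64_t)b) & mask;
    }
    if (!ok) continue;
    std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it =
        idx->table.find(key);
    if (it == idx->table.end()) continue;
    for (size_t j = 0; j < it->second.size(); ++j) {
      int64_t st = (int64_t)it->second[j] - off;
      if (st >= 0) cand.push_back(st);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  std::vector<int> pos, mm, chrom;
  std::vector<int> tmp_pos, tmp_mm;
  for (size_t i = 0; i < cand.size(); ++i) {
    size_t st = (size_t)cand[i];
    // locate chromosome containing st
    size_t lo = std::upper_bound(idx->offsets.begin(), idx->offsets.end(),
                                 st) - idx->offsets.begin();
    if (lo == 0 || lo >= idx->offsets.size()) continue;
    size_t c = lo - 1;
    tmp_pos.clear(); tmp_mm.clear();
    hamming_verify(idx->text, idx->offsets[c], idx->offsets[c + 1],
                   query.c_str(), qlen, k, st, tmp_pos, tmp_mm);
    for (size_t j = 0; j < tmp_pos.size(); ++j) {
      chrom.push_back((int)c + 1);
      pos.push_back(tmp_pos[j]);
      mm.push_back(tmp_mm[j]);
    }
  }
  return List::create(_["chrom"] = chrom, _["pos"] = pos, _["mm"] = mm);
}

// Definition-level fallback used for queries too short to seed.
// [[Rcpp::export]]
List cpp_naive_find(CharacterVector seqs, std::string query, int k) {
  const int qlen = (int)query.size();
  std::vector<int> chrom, pos, mm;
  for (int c = 0; c < seqs.size(); ++c) {
    const char* t = CHAR(STRING_ELT(seqs, c));
    int n = LENGTH(STRING_ELT(seqs, c));
    for (int p = 0; p + qlen <= n; ++p) {
      int d = 0;
      bool keep = true;
      for (int j = 0; j < qlen; ++j) {
        if (t[p + j] != query[j] && ++d > k) { keep = false; break; }
      }
      if (keep) { chrom.push_back(c + 1); pos.push_back(p); mm.push_back(d); }
    }
  }
  return List::create(_["chrom"] = chrom, _["pos"] = pos, _["mm"] = mm);
}
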