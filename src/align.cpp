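#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Complete <=M-mismatch search of color-space patterns against a set of
// reference color strings, by pigeonhole seeding: the pattern is partitioned
// into M+1 contiguous blocks; if the full alignment has at most M mismatches
// at some window, at least one block matches the window exactly, so looking
// up the first 8 colors of every block in a k-mer index of the reference
// finds every such window. Candidates are then verified by a full mismatch
// count. Falls back to a full scan when blocks are shorter than the k-mer.
//
// Colors are characters '0'..'3'; '.' is a missing call that mismatches
// everything and is never indexed.

static const int KMER = 8;
static const int NKEYS = 1 << (2 * KMER); // 4^8

static inline uint8_t col_val(char c) {
  if (c >= '0' && c <= '3') return (uint8_t)(c - '0');
  return 4; // '.' or anything else: permanent mismatch
}

// [[Rcpp::export(name = ".cs_seed_align")]]
DataFrame cs_seed_align(CharacterVector refs, CharacterVector pats,
                        int max_mm, int min_offset) {
  int nref = refs.size();
  std::vector<int> ref_start(nref), ref_len(nref);
  size_t total = 0;
  for (int r = 0; r < nref; ++r) total += LENGTH(STRING_ELT(refs, r)) + 1;
  std::vector<uint8_t> cat;
  cat.reserve(total);
  std::vector<int32_t> refid(total);
  for (int r = 0; r < nref; ++r) {
    const char* s = CHAR(STRING_ELT(refs, r));
    int n = LENGTH(STRING_ELT(refs, r));
    ref_start[r] = (int)cat.size();
    ref_len[r] = n;
    for (int i = 0; i < n; ++i) {
      refid[cat.size()] = r;
      cat.push_back(col_val(s[i]));
    }
    refid[cat.size()] = -1;
    cat.push_back(5); // separator: breaks k-mers across references
  }
  int N = (int)cat.size();

  // k-mer index over positions whose next KMER colors are all valid
  std::vector<int32_t> key_at(N, -1);
  {
    int run = 0;
    uint32_t key = 0;
    const uint32_t mask = NKEYS - 1;
    for (int i = 0; i < N; ++i) {
      if (cat[i] < 4) {
        key = ((key << 2) | cat[i]) & mask;
        if (++run >= KMER) key_at[i - KMER + 1] = (int32_t)key;
      } else {
        run = 0;
        key = 0;
      }
    }
  }
  std::vector<int32_t> bucket_cnt(NKEYS + 1, 0);
  for (int i = 0; i < N; ++i)
    if (key_at[i] >= 0) bucket_cnt[key_at[i] + 1]++;
  for (int k = 0; k < NKEYS; ++k) bucket_cnt[k + 1] += bucket_cnt[k];
  std::vector<int32_t> bucket_pos(bucket_cnt[NKEYS]);
  {
    std::vector<int32_t> cursor(bucket_cnt.begin(), bucket_cnt.end() - 1);
    for (int i = 0; i < N; ++i)
      if (key_at[i] >= 0) bucket_pos[cursor[key_at[i]]++] = i;
  }

  std::vector<int> out_pat, out_ref, out_off, out_mm;
  std::vector<uint8_t> pv;
  std::unordered_set<int64_t> seen;

  int npat = pats.size();
  for (int pi = 0; pi < npat; ++pi) {
    const char* ps = CHAR(STRING_ELT(pats, pi));
    int Lp = LENGTH(STRING_ELT(pats, pi));
    if (Lp == 0) continue;
    pv.assign(Lp, 0);
    for (int i = 0; i < Lp; ++i) pv[i] = col_val(ps[i]);
    seen.clear();

    auto verify_emit = [&](int w) {
      // w: global window start; window must lie inside one reference
      if (w < 0 || w + Lp > N) return;
      int r = refid[w];
      if (r < 0) return;
      int local = w - ref_start[r];
      if (local < min_offset || local + Lp > ref_len[r]) return;
      if (seen.count(w)) return;
      int mm = 0;
      for (int i = 0; i < Lp; ++i) {
        uint8_t a = pv[i], b = cat[w + i];
        if (a > 3 || b > 3 || a != b) {
          if (++mm > max_mm) return;
        }
      }
      seen.insert(w);
      out_pat.push_back(pi + 1);
      out_ref.push_back(r + 1);
      out_off.push_back(local);
      out_mm.push_back(mm);
    };

    int nblocks = max_mm + 1;
    int base = Lp / nblocks;
    if (base < KMER) {
      // blocks too short to seed with the k-mer index: exhaustive scan
      for (int r = 0; r < nref; ++r)
        for (int local = min_offset; local + Lp <= ref_len[r]; ++local)
          verify_emit(ref_start[r] + local);
      continue;
    }
    int rem = Lp % nblocks;
    int s = 0;
    for (int b = 0; b < nblocks; ++b) {
      int blen = base + (b < rem ? 1 : 0);
      // seed = first KMER colors of the block
      bool ok = true;
      uint32_t key = 0;
      for (int i = 0; i < KMER; ++i) {
        if (pv[s + i] > 3) { ok = false; break; }
        key = (key << 2) | pv[s + i];
      }
      if (ok) {
        for (int32_t bi = bucket_cnt[key]; bi < bucket_cnt[key + 1]; ++bi)
          verify_emit(bucket_pos[bi] - s);
      }
      s += blen;
    }
  }

  return DataFrame::create(_["pat"] = out_pat, _["ref"] = out_ref,
                           _["offset"] = out_off, _["mm"] = out_mm);
}
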