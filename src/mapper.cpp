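// Deterministic short-tag alignment against an in-memory UTR database.
// Exact k-mer seeds (2-bit encoded) at up to three offsets, full-length
// verification with a substitution budget and no indels; unique-best-hit
// semantics (ties across distinct loci -> multimapped).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > SeedIndex;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  }
  return 'N';
}

// [[Rcpp::export]]
SEXP build_seed_index_cpp(CharacterVector db_seqs, int k) {
  if (k < 4 || k > 31) stop("seed length k must be in [4, 31]");
  SeedIndex *idx = new SeedIndex();
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int r = 0; r < db_seqs.size(); ++r) {
    const char *s = CHAR(STRING_ELT(db_seqs, r));
    int len = (int) std::strlen(s);
    uint64_t kmer = 0;
    int valid = 0;
    for (int i = 0; i < len; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t) b) & mask;
      if (++valid >= k) {
        uint64_t pos = (uint64_t) (i - k + 1);
        (*idx)[kmer].push_back(((uint64_t) r << 32) | pos);
      }
    }
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// status: 0 = mapped, 1 = unmapped, 2 = multimapped, 3 = too short
// [[Rcpp::export]]
DataFrame map_tags_cpp(CharacterVector tags, CharacterVector db_seqs,
                       SEXP index, int k, int max_mismatch,
                       bool reverse_complement) {
  XPtr<SeedIndex> idx(index);
  int n = tags.size();
  int nrec = db_seqs.size();
  std::vector<const char *> recs(nrec);
  std::vector<int> reclen(nrec);
  for (int r = 0; r < nrec; ++r) {
    recs[r] = CHAR(STRING_ELT(db_seqs, r));
    reclen[r] = (int) std::strlen(recs[r]);
  }
  IntegerVector out_rec(n), out_start(n), out_mm(n), out_status(n);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::string q;
  std::vector<uint64_t> cand;
  for (int i = 0; i < n; ++i) {
    const char *t = CHAR(STRING_ELT(tags, i));
    int L = (int) std::strlen(t);
    out_rec[i] = NA_INTEGER; out_start[i] = NA_INTEGER; out_mm[i] = NA_INTEGER;
    if (L < k) { out_status[i] = 3; continue; }
    q.assign((size_t) L, 'N');
    if (reverse_complement) {
      for (int j = 0; j < L; ++j) q[j] = comp_base(t[L - 1 - j]);
    } else {
      q.assign(t, (size_t) L);
    }
    // seed offsets: start, middle, end (deduplicated)
    int offs[3] = {0, (L - k) / 2, L - k};
    cand.clear();
    for (int oi = 0; oi < 3; ++oi) {
      int o = offs[oi];
      if (oi > 0 && o == offs[oi - 1]) continue;
      uint64_t kmer = 0; bool ok = true;
      for (int j = 0; j < k; ++j) {
        int b = base2bits(q[o + j]);
        if (b < 0) { ok = false; break; }
        kmer = ((kmer << 2) | (uint64_t) b) & mask;
      }
      if (!ok) continue;
      SeedIndex::const_iterator it = idx->find(kmer);
      if (it == idx->end()) continue;
      const std::vector<uint64_t> &hits = it->second;
      for (size_t h = 0; h < hits.size(); ++h) {
        int r = (int) (hits[h] >> 32);
        long long start = (long long) (hits[h] & 0xffffffffULL) - o;
        if (start < 0 || start + L > reclen[r]) continue;
        cand.push_back(((uint64_t) r << 32) | (uint64_t) start);
      }
    }
    if (cand.empty()) { out_status[i] = 1; continue; }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    int best_mm = max_mismatch + 1, n_best = 0, best_rec = -1, best_start = -1;
    for (size_t c = 0; c < cand.size(); ++c) {
      int r = (int) (cand[c] >> 32);
      int start = (int) (cand[c] & 0xffffffffULL);
      const char *s = recs[r] + start;
      int mm = 0;
      for (int j = 0; j < L && mm <= max_mismatch; ++j) {
        if (s[j] != q[j]) ++mm;
      }
      if (mm > max_mismatch) continue;
      if (mm < best_mm) {
        best_mm = mm; n_best = 1; best_rec = r; best_start = start;
      } else if (mm == best_mm) {
        ++n_best;
      }
    }
    if (best_mm > max_mismatch) { out_status[i] = 1; continue; }
    if (n_best > 1) { out_status[i] = 2; continue; }
    out_status[i] = 0;
    out_rec[i] = best_rec + 1;  // 1-based record index for R
    out_start[i] = best_start;  // 0-based offset within record
    out_mm[i] = best_mm;
  }
  return DataFrame::create(_["record"] = out_rec, _["start"] = out_start,
                           _["mismatches"] = out_mm, _["status"] = out_status);
}
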