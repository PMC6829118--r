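#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char cbase(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

static std::string rcseq(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = cbase(s[i]);
  return out;
}

// Forward-strand k-mer position index over a set of chromosomes. Minus-strand
// occurrences are resolved at query time by looking up the reverse complement,
// so each position is stored once.
struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<int> rank;  // lexicographic rank of each chromosome name
  std::vector<uint64_t> keys;
  std::vector<uint64_t> locs;  // (chrom << 32) | pos
};

static bool encode_kmer(const std::string &s, size_t off, int k, uint64_t &key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int v = b2i(s[off + i]);
    if (v < 0) return false;
    key = (key << 2) | (uint64_t)v;
  }
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  int n = names.size();
  for (int c = 0; c < n; ++c) {
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(as<std::string>(seqs[c]));
  }
  // lexicographic rank of chromosome names (tie-break order for placements)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return idx->names[a] < idx->names[b]; });
  idx->rank.resize(n);
  for (int r = 0; r < n; ++r) idx->rank[ord[r]] = r;

  std::vector<std::pair<uint64_t, uint64_t>> tab;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int c = 0; c < n; ++c) {
    const std::string &s = idx->seqs[c];
    uint64_t key = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int v = b2i(s[i]);
      if (v < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)v) & mask;
      if (++run >= k)
        tab.push_back({key, ((uint64_t)c << 32) | (uint64_t)(i - k + 1)});
    }
  }
  std::sort(tab.begin(), tab.end());
  idx->keys.resize(tab.size());
  idx->locs.resize(tab.size());
  for (size_t i = 0; i < tab.size(); ++i) {
    idx->keys[i] = tab[i].first;
    idx->locs[i] = tab[i].second;
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return idx->k;
}

// [[Rcpp::export]]
double cpp_index_size(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return (double)idx->keys.size();
}

static void lookup(const KmerIndex &idx, uint64_t key, std::vector<uint64_t> &hits) {
  auto lo = std::lower_bound(idx.keys.begin(), idx.keys.end(), key);
  for (auto it = lo; it != idx.keys.end() && *it == key; ++it)
    hits.push_back(idx.locs[it - idx.keys.begin()]);
}

// Occurrences of `kmer` on both strands: minus-strand hits are forward
// occurrences of its reverse complement over the same interval.
// [[Rcpp::export]]
DataFrame cpp_index_query(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal k");
  std::vector<int> chrom, pos;
  std::vector<std::string> strand;
  uint64_t key;
  std::vector<uint64_t> hits;
  if (encode_kmer(kmer, 0, idx->k, key)) {
    lookup(*idx, key, hits);
    for (uint64_t h : hits) {
      chrom.push_back((int)(h >> 32) + 1);
      pos.push_back((int)(h & 0xffffffffULL));
      strand.push_back("+");
    }
  }
  std::string kr = rcseq(kmer);
  if (kr != kmer && encode_kmer(kr, 0, idx->k, key)) {
    hits.clear();
    lookup(*idx, key, hits);
    for (uint64_t h : hits) {
      chrom.push_back((int)(h >> 32) + 1);
      pos.push_back((int)(h & 0xffffffffULL));
      strand.push_back("-");
    }
  } else if (kr == kmer) {
    // palindromic k-mer: every forward hit is also a minus-strand hit
    for (size_t i = 0; i < chrom.size(); ++i) {
      chrom.push_back(chrom[i]);
      pos.push_back(pos[i]);
      strand.push_back("-");
    }
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = pos, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Seed-and-extend single-end mapping of each read against the index.
// Seeds are non-overlapping k-mers (plus a final k-mer flush with the read
// end); extension is ungapped full-length Hamming comparison. Best placement
// = fewest mismatches; ties recorded as nbest > 1 with the lexicographically
// smallest (chrom name, pos, strand) kept.
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, int maxMismatch) {
  XPtr<KmerIndex> idx(xp);
  int k = idx->k;
  int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector chrom(n), pos(n), mism(n), nbest(n);
  CharacterVector strand(n);

  std::vector<uint64_t> hits;
  std::vector<uint64_t> cands;  // packed: strand<<56 | chrom<<32 | pos

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int L = (int)fwd.size();
    mapped[r] = false;
    chrom[r] = NA_INTEGER;
    pos[r] = NA_INTEGER;
    strand[r] = NA_STRING;
    mism[r] = NA_INTEGER;
    nbest[r] = 0;
    if (L < k) continue;
    std::string rev = rcseq(fwd);

    cands.clear();
    std::vector<int> offs;
    for (int off = 0; off + k <= L; off += k) offs.push_back(off);
    if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);

    for (int st = 0; st < 2; ++st) {
      const std::string &q = st == 0 ? fwd : rev;
      for (int off : offs) {
        uint64_t key;
        if (!encode_kmer(q, off, k, key)) continue;
        hits.clear();
        lookup(*idx, key, hits);
        for (uint64_t h : hits) {
          int c = (int)(h >> 32);
          long long p = (long long)(h & 0xffffffffULL) - off;
          if (p < 0 || p + L > (long long)idx->seqs[c].size()) continue;
          cands.push_back(((uint64_t)st << 56) | ((uint64_t)c << 32) | (uint64_t)p);
        }
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int bestMM = maxMismatch + 1, bestCount = 0;
    int bestChrom = -1, bestPos = -1, bestSt = 0, bestRank = -1;
    for (uint64_t cd : cands) {
      int st = (int)(cd >> 56);
      int c = (int)((cd >> 32) & 0xffffffULL);
      int p = (int)(cd & 0xffffffffULL);
      const std::string &q = st == 0 ? fwd : rev;
      const std::string &ref = idx->seqs[c];
      int mm = 0;
      for (int i = 0; i < L; ++i) {
        if (q[i] != ref[p + i] && ++mm > maxMismatch) break;
      }
      if (mm > maxMismatch) continue;
      if (mm < bestMM) {
        bestMM = mm;
        bestCount = 1;
        bestChrom = c; bestPos = p; bestSt = st; bestRank = idx->rank[c];
      } else if (mm == bestMM) {
        ++bestCount;
        int rk = idx->rank[c];
        if (rk < bestRank || (rk == bestRank && (p < bestPos || (p == bestPos && st < bestSt)))) {
          bestChrom = c; bestPos = p; bestSt = st; bestRank = rk;
        }
      }
    }
    if (bestCount > 0) {
      mapped[r] = true;
      chrom[r] = bestChrom + 1;
      pos[r] = bestPos;
      strand[r] = bestSt == 0 ? "+" : "-";
      mism[r] = bestMM;
      nbest[r] = bestCount;
    }
  }
  return DataFrame::create(_["mapped"] = mapped, _["chrom"] = chrom, _["pos"] = pos,
                           _["strand"] = strand, _["mismatches"] = mism,
                           _["nbest"] = nbest, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
int cpp_lcp(std::string a, std::string b) {
  size_t m = std::min(a.size(), b.size());
  size_t i = 0;
  while (i < m && a[i] == b[i]) ++i;
  return (int)i;
}

// [[Rcpp::export]]
int cpp_lcs(std::string a, std::string b) {
  size_t m = std::min(a.size(), b.size());
  size_t i = 0;
  while (i < m && a[a.size() - 1 - i] == b[b.size() - 1 - i]) ++i;
  return (int)i;
}

// Longest prefix of `cons` matching `ref` starting at any offset within
// [regStart, regEnd) (0-based). Returns (best offset, prefix length); ties go
// to the smallest offset.
// [[Rcpp::export]]
IntegerVector cpp_anchor_prefix(std::string cons, std::string ref, int regStart, int regEnd) {
  int L = (int)cons.size(), R = (int)ref.size();
  int lo = std::max(regStart, 0), hi = std::min(regEnd, R);
  int bestP = 0, bestPos = NA_INTEGER;
  for (int o = lo; o < hi; ++o) {
    int m = std::min(L, R - o);
    int i = 0;
    while (i < m && cons[i] == ref[o + i]) ++i;
    if (i > bestP) { bestP = i; bestPos = o; }
  }
  return IntegerVector::create(bestPos, bestP);
}

// Longest suffix of `cons` matching `ref` ending at any exclusive offset q
// within [regStart, regEnd] (0-based). Returns (best q, suffix length); ties
// go to the smallest q.
// [[Rcpp::export]]
IntegerVector cpp_anchor_suffix(std::string cons, std::string ref, int regStart, int regEnd) {
  int L = (int)cons.size(), R = (int)ref.size();
  int lo = std::max(regStart, 1), hi = std::min(regEnd, R);
  int bestS = 0, bestQ = NA_INTEGER;
  for (int q = lo; q <= hi; ++q) {
    int m = std::min(L, q);
    int i = 0;
    while (i < m && cons[L - 1 - i] == ref[q - 1 - i]) ++i;
    if (i > bestS) { bestS = i; bestQ = q; }
  }
  return IntegerVector::create(bestQ, bestS);
}

static int max_overlap(const std::string &a, const std::string &b, int minOv, int atLeast) {
  // longest suffix of a equal to a prefix of b, >= max(minOv, atLeast)
  int m = (int)std::min(a.size(), b.size());
  for (int ov = m; ov >= std::max(minOv, atLeast); --ov) {
    if (a.compare(a.size() - ov, ov, b, 0, ov) == 0) return ov;
  }
  return 0;
}

// Greedy maximal-exact-overlap assembly. Duplicate and contained fragments
// are absorbed; then the pair with the longest suffix/prefix overlap merges
// first (ties resolved by input order) until no overlap >= overlapMin
// remains. Returns surviving contigs and the read count absorbed into each.
// [[Rcpp::export]]
List cpp_assemble_greedy(CharacterVector reads, int overlapMin) {
  std::vector<std::string> frags;
  std::vector<int> counts;
  for (int i = 0; i < reads.size(); ++i) {
    frags.push_back(as<std::string>(reads[i]));
    counts.push_back(1);
  }

  bool changed = true;
  while (changed) {
    changed = false;
    // absorb contained fragments
    for (size_t i = 0; i < frags.size() && !changed; ++i) {
      for (size_t j = 0; j < frags.size(); ++j) {
        if (i == j) continue;
        if (frags[j].size() <= frags[i].size() && frags[i].find(frags[j]) != std::string::npos) {
          counts[i] += counts[j];
          frags.erase(frags.begin() + j);
          counts.erase(counts.begin() + j);
          changed = true;
          break;
        }
      }
    }
    if (changed) continue;
    // best suffix/prefix merge
    int bestOv = 0;
    size_t bi = 0, bj = 0;
    for (size_t i = 0; i < frags.size(); ++i) {
      for (size_t j = 0; j < frags.size(); ++j) {
        if (i == j) continue;
        int ov = max_overlap(frags[i], frags[j], overlapMin, bestOv + 1);
        if (ov > bestOv) { bestOv = ov; bi = i; bj = j; }
      }
    }
    if (bestOv >= overlapMin) {
      frags[bi] += frags[bj].substr(bestOv);
      counts[bi] += counts[bj];
      frags.erase(frags.begin() + bj);
      counts.erase(counts.begin() + bj);
      changed = true;
    }
  }
  return List::create(_["contigs"] = wrap(frags), _["counts"] = wrap(counts));
}
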