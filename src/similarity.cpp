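// Ungapped overlap-similarity engine for short reads.
//
// The contract implemented here: two reads share a "hit" when some ungapped
// overlap alignment (either orientation) has length >= min_overlap and
// matches/overlap >= min_identity, identity computed over the overlap only.
// cpp_find_hits() seeds candidate (pair, offset) combinations with shared
// exact k-mers; cpp_brute_hits() scans every offset and serves as the
// independent oracle. Both apply the identical verification and best-hit
// tie-breaking, so on any input their hit sets are comparable field by field.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and friends: never match anything
  }
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) enc(s[i]);
  return v;
}

static std::vector<int8_t> revcomp(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = b < 0 ? (int8_t) -1 : (int8_t) (3 - b);
  }
  return r;
}

struct Hit {
  int score;       // matches - mismatches over the overlap
  int matches;
  int overlap;
  int orientation; // 0 same, 1 reverse
  int offset;      // start of (oriented) B relative to A
  bool set;
  Hit() : score(0), matches(0), overlap(0), orientation(0), offset(0), set(false) {}
};

// deterministic total order on candidate hits for the same pair
static inline bool better(const Hit& h, const Hit& best) {
  if (!best.set) return true;
  if (h.score != best.score) return h.score > best.score;
  if (h.overlap != best.overlap) return h.overlap > best.overlap;
  if (h.orientation != best.orientation) return h.orientation < best.orientation;
  return h.offset < best.offset;
}

// Verify the overlap alignment of A vs oriented B at a given offset.
static bool verify(const int8_t* A, int la, const int8_t* B, int lb,
                   int off, int min_ov, double min_id,
                   int orientation, Hit& out) {
  int a0 = off > 0 ? off : 0;
  int a1 = std::min(la, off + lb);
  int L = a1 - a0;
  if (L < min_ov) return false;
  int allowed = (int) std::floor((1.0 - min_id) * L + 1e-9);
  int mm = 0;
  for (int t = a0; t < a1; ++t) {
    int8_t ca = A[t], cb = B[t - off];
    if (ca < 0 || cb < 0 || ca != cb) {
      if (++mm > allowed) return false;
    }
  }
  out.score = (L - mm) - mm;
  out.matches = L - mm;
  out.overlap = L;
  out.orientation = orientation;
  out.offset = off;
  out.set = true;
  return true;
}

struct Entry {
  uint64_t key;
  int32_t read;
  int32_t pos;
  int8_t strand;
};

static DataFrame hits_to_df(std::unordered_map<uint64_t, Hit>& best) {
  std::vector<uint64_t> keys;
  keys.reserve(best.size());
  for (auto& kv : best) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int n = (int) keys.size();
  IntegerVector a(n), b(n), ov(n), mat(n), ori(n), off(n);
  NumericVector id(n);
  for (int i = 0; i < n; ++i) {
    const Hit& h = best[keys[i]];
    a[i] = (int) (keys[i] >> 32) + 1;
    b[i] = (int) (keys[i] & 0xffffffffu) + 1;
    ov[i] = h.overlap;
    mat[i] = h.matches;
    id[i] = (double) h.matches / h.overlap;
    ori[i] = h.orientation;
    off[i] = h.offset;
  }
  return DataFrame::create(_["a"] = a, _["b"] = b, _["overlap"] = ov,
                           _["matches"] = mat, _["identity"] = id,
                           _["orientation"] = ori, _["offset"] = off);
}

// [[Rcpp::export]]
DataFrame cpp_find_hits(CharacterVector seqs, double min_identity,
                        int min_overlap, int seed_k) {
  int n = seqs.size();
  if (seed_k < 1 || seed_k > 31) stop("seed_k must be in [1, 31]");
  std::vector< std::vector<int8_t> > fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = encode(as<std::string>(seqs[i]));
    rev[i] = revcomp(fwd[i]);
  }
  // index k-mers of both strands of every read
  std::vector<Entry> entries;
  {
    size_t tot = 0;
    for (int i = 0; i < n; ++i)
      if ((int) fwd[i].size() >= seed_k) tot += 2 * (fwd[i].size() - seed_k + 1);
    entries.reserve(tot);
  }
  uint64_t mask = (seed_k >= 32) ? ~0ULL : ((1ULL << (2 * seed_k)) - 1);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < 2; ++s) {
      const std::vector<int8_t>& v = s == 0 ? fwd[i] : rev[i];
      int L = (int) v.size();
      uint64_t key = 0;
      int run = 0;  // consecutive valid bases ending here
      for (int p = 0; p < L; ++p) {
        if (v[p] < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) v[p]) & mask;
        if (++run >= seed_k) {
          Entry e; e.key = key; e.read = i; e.pos = p - seed_k + 1; e.strand = (int8_t) s;
          entries.push_back(e);
        }
      }
    }
  }
  std::sort(entries.begin(), entries.end(),
            [](const Entry& x, const Entry& y) { return x.key < y.key; });

  std::unordered_map<uint64_t, Hit> best;
  size_t i0 = 0, N = entries.size();
  while (i0 < N) {
    size_t i1 = i0 + 1;
    while (i1 < N && entries[i1].key == entries[i0].key) ++i1;
    for (size_t i = i0; i < i1; ++i) {
      for (size_t j = i + 1; j < i1; ++j) {
        const Entry* ea = &entries[i];
        const Entry* eb = &entries[j];
        if (ea->read == eb->read) continue;
        if (ea->read > eb->read) std::swap(ea, eb);
        // the (a reverse, b *) geometry re-occurs as (a forward, b flipped)
        // in the reverse-complement k-mer bucket; keep a's forward only
        if (ea->strand != 0) continue;
        int orientation = eb->strand;
        const std::vector<int8_t>& A = fwd[ea->read];
        const std::vector<int8_t>& B = orientation ? rev[eb->read] : fwd[eb->read];
        int off = ea->pos - eb->pos;
        Hit h;
        if (verify(A.data(), (int) A.size(), B.data(), (int) B.size(),
                   off, min_overlap, min_identity, orientation, h)) {
          uint64_t pk = ((uint64_t) (uint32_t) ea->read << 32) | (uint32_t) eb->read;
          Hit& cur = best[pk];
          if (better(h, cur)) cur = h;
        }
      }
    }
    i0 = i1;
  }
  return hits_to_df(best);
}

// [[Rcpp::export]]
DataFrame cpp_brute_hits(CharacterVector seqs, double min_identity,
                         int min_overlap) {
  int n = seqs.size();
  std::vector< std::vector<int8_t> > fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = encode(as<std::string>(seqs[i]));
    rev[i] = revcomp(fwd[i]);
  }
  std::unordered_map<uint64_t, Hit> best;
  for (int a = 0; a < n; ++a) {
    const std::vector<int8_t>& A = fwd[a];
    int la = (int) A.size();
    for (int b = a + 1; b < n; ++b) {
      Hit cur;
      for (int orientation = 0; orientation < 2; ++orientation) {
        const std::vector<int8_t>& B = orientation ? rev[b] : fwd[b];
        int lb = (int) B.size();
        for (int off = -(lb - min_overlap); off <= la - min_overlap; ++off) {
          Hit h;
          if (verify(A.data(), la, B.data(), lb, off, min_overlap,
                     min_identity, orientation, h) && better(h, cur))
            cur = h;
        }
      }
      if (cur.set) {
        uint64_t pk = ((uint64_t) (uint32_t) a << 32) | (uint32_t) b;
        best[pk] = cur;
      }
    }
  }
  return hits_to_df(best);
}

// Does any ungapped overlap of read vs ref (either orientation) reach
// min_identity over >= min_overlap bases?
// [[Rcpp::export]]
LogicalVector cpp_matches_ref(CharacterVector seqs, std::string ref,
                              double min_identity, int min_overlap) {
  std::vector<int8_t> R = encode(ref), Rrc = revcomp(R);
  int lr = (int) R.size();
  int n = seqs.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int8_t> A = encode(as<std::string>(seqs[i]));
    int la = (int) A.size();
    bool found = false;
    for (int orientation = 0; orientation < 2 && !found; ++orientation) {
      const std::vector<int8_t>& B = orientation ? Rrc : R;
      for (int off = -(lr - min_overlap); off <= la - min_overlap; ++off) {
        Hit h;
        if (verify(A.data(), la, B.data(), lr, off, min_overlap,
                   min_identity, orientation, h)) { found = true; break; }
      }
    }
    out[i] = found;
  }
  return out;
}

static void add_ref_kmers(const std::vector<int8_t>& v, int k,
                          std::unordered_set<uint64_t>& set) {
  uint64_t mask = (1ULL << (2 * k)) - 1, key = 0;
  int run = 0;
  for (size_t p = 0; p < v.size(); ++p) {
    if (v[p] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) v[p]) & mask;
    if (++run >= k) set.insert(key);
  }
}

// Per-read count of k-mers shared with a reference set (both ref strands).
// [[Rcpp::export]]
IntegerVector cpp_ref_kmer_counts(CharacterVector seqs, CharacterVector refs,
                                  int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> set;
  for (int r = 0; r < refs.size(); ++r) {
    std::vector<int8_t> v = encode(as<std::string>(refs[r]));
    add_ref_kmers(v, k, set);
    add_ref_kmers(revcomp(v), k, set);
  }
  int n = seqs.size();
  IntegerVector out(n);
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int i = 0; i < n; ++i) {
    std::vector<int8_t> v = encode(as<std::string>(seqs[i]));
    uint64_t key = 0;
    int run = 0, cnt = 0;
    for (size_t p = 0; p < v.size(); ++p) {
      if (v[p] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) v[p]) & mask;
      if (++run >= k && set.count(key)) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

// Per-read, per-lineage counts of k-mers shared with a labelled library
// (library k-mers indexed on both strands; at most 32 lineages).
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_votes(CharacterVector seqs, CharacterVector lib,
                             IntegerVector lineage0, int n_lineage, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (n_lineage > 32) stop("at most 32 lineages supported");
  std::unordered_map<uint64_t, uint32_t> map;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int r = 0; r < lib.size(); ++r) {
    uint32_t bit = 1u << lineage0[r];
    std::vector<int8_t> v = encode(as<std::string>(lib[r]));
    for (int s = 0; s < 2; ++s) {
      const std::vector<int8_t> w = s == 0 ? v : revcomp(v);
      uint64_t key = 0;
      int run = 0;
      for (size_t p = 0; p < w.size(); ++p) {
        if (w[p] < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) w[p]) & mask;
        if (++run >= k) map[key] |= bit;
      }
    }
  }
  int n = seqs.size();
  IntegerMatrix out(n, n_lineage);
  for (int i = 0; i < n; ++i) {
    std::vector<int8_t> v = encode(as<std::string>(seqs[i]));
    uint64_t key = 0;
    int run = 0;
    for (size_t p = 0; p < v.size(); ++p) {
      if (v[p] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) v[p]) & mask;
      if (++run >= k) {
        auto it = map.find(key);
        if (it != map.end()) {
          uint32_t bits = it->second;
          while (bits) {
            int l = __builtin_ctz(bits);
            out(i, l) += 1;
            bits &= bits - 1;
          }
        }
      }
    }
  }
  return out;
}
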