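#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; anything non-ACGT gets 4 and never matches.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return 4;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'U': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

// ---------------------------------------------------------------------------
// Bounded-mismatch substitution-only alignment of short tags against a set of
// reference sequences.  Strategy: pigeonhole seeding.  Each tag (and its
// reverse complement) is cut into (m+1) non-overlapping chunks; a placement
// with <= m substitutions must contain at least one error-free chunk, so every
// chunk is registered in a per-length exact-match dictionary and each
// reference is scanned once per distinct chunk length with a rolling 2-bit
// key.  Candidate placements are verified by direct Hamming count.
// ---------------------------------------------------------------------------

struct SeedEntry { int32_t tag; uint8_t chunk; uint8_t strand; };

// 2-bit packing of a sequence into little-endian 32-base words, with a
// validity flag per base (non-ACGT)
struct Packed {
  std::vector<uint64_t> words;
  std::vector<int32_t> bad_prefix; // # non-ACGT bases in [0, i)
  int n;
  void build(const std::string& s) {
    n = (int)s.size();
    words.assign(n / 32 + 2, 0ULL);
    bad_prefix.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      bad_prefix[i + 1] = bad_prefix[i] + (b > 3 ? 1 : 0);
      words[i >> 5] |= (uint64_t)(b & 3) << (2 * (i & 31));
    }
  }
  // 64-bit window of 32 bases starting at p (p + 32 may run past the end;
  // the caller masks)
  inline uint64_t window(int p) const {
    int w = p >> 5, o = 2 * (p & 31);
    uint64_t lo = words[w] >> o;
    if (o) lo |= words[w + 1] << (64 - o);
    return lo;
  }
  inline bool clean(int p, int len) const {
    return bad_prefix[p + len] == bad_prefix[p];
  }
};

// mismatching-base count between packed query (qw, length L) and the
// reference window at position p
static inline int packed_mismatch(const Packed& ref, int p,
                                  const uint64_t* qw, int L) {
  int mm = 0;
  for (int done = 0; done < L; done += 32) {
    int chunk = std::min(32, L - done);
    uint64_t x = ref.window(p + done) ^ qw[done >> 5];
    if (chunk < 32) x &= (1ULL << (2 * chunk)) - 1;
    x = (x | (x >> 1)) & 0x5555555555555555ULL;
    mm += __builtin_popcountll(x);
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_align_tags(CharacterVector ref_names, CharacterVector ref_seqs,
                         CharacterVector tags, int max_mismatch) {
  const int MAXCHUNK = 27; // 2 bits x 27 = 54 bits, fits a uint64 key
  int ntag = tags.size();
  int nref = ref_seqs.size();
  if (max_mismatch < 0) stop("max_mismatch must be >= 0");

  // chunk dictionaries keyed by chunk length
  std::unordered_map<int, std::unordered_map<uint64_t, std::vector<SeedEntry> > > dict;
  std::vector<std::string> fwd(ntag), rev(ntag);
  std::vector<int> chunk_len(ntag);
  // packed queries, forward and reverse-complement, 2 words each
  std::vector<uint64_t> qpack((size_t)ntag * 4, 0ULL);
  std::vector<char> qbad(ntag, 0);

  for (int t = 0; t < ntag; ++t) {
    fwd[t] = as<std::string>(tags[t]);
    rev[t] = revcomp(fwd[t]);
    int L = (int)fwd[t].size();
    if (L > 64) stop("tags longer than 64 nt are not supported");
    int cl = std::min(L / (max_mismatch + 1), MAXCHUNK);
    if (cl < 1) stop("tag shorter than max_mismatch + 1");
    chunk_len[t] = cl;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand == 0 ? fwd[t] : rev[t];
      for (int i = 0; i < L; ++i) {
        int b = base_code(s[i]);
        if (b > 3) qbad[t] = 1;
        qpack[(size_t)t * 4 + strand * 2 + (i >> 5)] |=
          (uint64_t)(b & 3) << (2 * (i & 31));
      }
      for (int c = 0; c <= max_mismatch; ++c) {
        int off = c * cl;
        if (off + cl > L) break;
        uint64_t key = 0; bool ok = true;
        for (int i = 0; i < cl; ++i) {
          int b = base_code(s[off + i]);
          if (b > 3) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        dict[cl][key].push_back(SeedEntry{t, (uint8_t)c, (uint8_t)strand});
      }
    }
  }

  // raw hit records (may contain duplicates from multiple seeds)
  std::vector<uint64_t> raw; // tag(22) | ref(10) | strand(1) | start(31)
  std::vector<std::string> refs_cache(nref);
  for (int r = 0; r < nref; ++r) refs_cache[r] = as<std::string>(ref_seqs[r]);

  for (int r = 0; r < nref; ++r) {
    const std::string& ref = refs_cache[r];
    int G = (int)ref.size();
    Packed pk; pk.build(ref);

    for (auto& kv : dict) {
      int cl = kv.first;
      if (G < cl) continue;
      auto& map_l = kv.second;
      uint64_t mask = (cl >= 32) ? ~0ULL : ((1ULL << (2 * cl)) - 1);
      uint64_t key = 0;
      int valid = 0; // run length of ACGT-only bases ending here
      for (int p = 0; p < G; ++p) {
        int b = base_code(ref[p]);
        if (b > 3) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++valid < cl) continue;
        auto it = map_l.find(key);
        if (it == map_l.end()) continue;
        int wstart = p - cl + 1; // chunk start on reference
        for (const SeedEntry& e : it->second) {
          int L = (int)fwd[e.tag].size();
          int start = wstart - (int)e.chunk * cl;
          if (start < 0 || start + L > G) continue;
          int mm;
          if (!qbad[e.tag] && pk.clean(start, L)) {
            mm = packed_mismatch(pk, start,
                                 &qpack[(size_t)e.tag * 4 + e.strand * 2], L);
          } else {
            const std::string& q = e.strand == 0 ? fwd[e.tag] : rev[e.tag];
            mm = 0;
            for (int i = 0; i < L && mm <= max_mismatch; ++i) {
              int cb = base_code(ref[start + i]);
              if (cb > 3 || cb != base_code(q[i])) ++mm;
            }
          }
          if (mm <= max_mismatch)
            raw.push_back(((uint64_t)e.tag << 42) | ((uint64_t)r << 32) |
                          ((uint64_t)e.strand << 31) | (uint64_t)start);
        }
      }
    }
  }

  std::sort(raw.begin(), raw.end());
  raw.erase(std::unique(raw.begin(), raw.end()), raw.end());

  int n = (int)raw.size();
  IntegerVector tag_i(n), start(n), end(n), mm_out(n);
  CharacterVector chrom(n), strand(n);
  for (int i = 0; i < n; ++i) {
    int t = (int)(raw[i] >> 42);
    int r = (int)((raw[i] >> 32) & 0x3FF);
    int st = (int)(raw[i] & 0x7FFFFFFF);
    int sd = (int)((raw[i] >> 31) & 1);
    int L = (int)fwd[t].size();
    // recompute mismatch count for the report
    const std::string& refseq = refs_cache[r];
    const std::string& q = sd == 0 ? fwd[t] : rev[t];
    int mm = 0;
    for (int k = 0; k < L; ++k) {
      int cb = base_code(refseq[st + k]);
      if (cb > 3 || cb != base_code(q[k])) ++mm;
    }
    tag_i[i] = t + 1;
    chrom[i] = ref_names[r];
    start[i] = st;
    end[i] = st + L;
    strand[i] = sd == 0 ? "+" : "-";
    mm_out[i] = mm;
  }
  return DataFrame::create(_["tag"] = tag_i, _["chrom"] = chrom,
                           _["start"] = start, _["end"] = end,
                           _["strand"] = strand, _["mismatches"] = mm_out,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// One greedy abundance-ranked error-correction pass.  Children are visited
// in increasing original-abundance order; each child with at least one
// currently-alive, strictly more abundant same-length parent within the
// mismatch budget is merged into the best such parent (minimal distance,
// then maximal current abundance, then lexicographically smallest
// sequence).  Returns the updated abundances, -1 for merged-away tags.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_correct_pass(CharacterVector seqs, NumericVector abundance,
                               IntegerVector pair_child, IntegerVector pair_parent,
                               IntegerVector pair_dist, IntegerVector order_idx) {
  int n = seqs.size();
  std::vector<double> ab(abundance.begin(), abundance.end());
  std::vector<char> alive(n, 1);
  // adjacency: candidate parents per child
  int np = pair_child.size();
  std::vector<int> head(n, -1), nxt(np, -1), padj(np), pdst(np);
  for (int i = 0; i < np; ++i) {
    int c = pair_child[i] - 1;
    padj[i] = pair_parent[i] - 1;
    pdst[i] = pair_dist[i];
    nxt[i] = head[c];
    head[c] = i;
  }
  for (int oi = 0; oi < n; ++oi) {
    int c = order_idx[oi] - 1;
    if (!alive[c]) continue;
    int best = -1, bestd = INT32_MAX;
    for (int e = head[c]; e != -1; e = nxt[e]) {
      int pa = padj[e];
      if (!alive[pa] || !(ab[pa] > ab[c])) continue;
      if (pdst[e] < bestd) { bestd = pdst[e]; best = pa; }
      else if (pdst[e] == bestd && best >= 0) {
        if (ab[pa] > ab[best] ||
            (ab[pa] == ab[best] &&
             strcmp(CHAR(STRING_ELT(seqs, pa)), CHAR(STRING_ELT(seqs, best))) < 0))
          best = pa;
      }
    }
    if (best >= 0) {
      ab[best] += ab[c];
      ab[c] = -1;
      alive[c] = 0;
    }
  }
  return NumericVector(ab.begin(), ab.end());
}

// ---------------------------------------------------------------------------
// Baseline secondary-structure folder: Nussinov-style dynamic program that
// minimises a per-pair energy (GC, AU, GU), nested structures only, with a
// minimum hairpin loop size.  Returns dot-bracket, total energy and the
// 0-based partner of every position (-1 = unpaired).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_fold_nussinov(std::string seq, double e_gc, double e_au, double e_gu,
                       int min_loop) {
  int n = (int)seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  auto pair_e = [&](int i, int j) -> double {
    int a = code[i], b = code[j];
    if (a > b) std::swap(a, b);
    if (a == 1 && b == 2) return e_gc;       // C-G
    if (a == 0 && b == 3) return e_au;       // A-U(T)
    if (a == 2 && b == 3) return e_gu;       // G-U(T)
    return 1.0;                              // not pairable
  };

  if (n == 0)
    return List::create(_["structure"] = "", _["energy"] = 0.0,
                        _["pairs"] = IntegerVector(0));

  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = E[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double pe = pair_e(i, k);
        if (pe >= 0) continue;
        double v = pe + (k > i + 1 ? E[i + 1][k - 1] : 0.0) +
                   (k < j ? E[k + 1][j] : 0.0);
        if (v < best) best = v;
      }
      E[i][j] = best;
    }
  }

  // traceback
  std::vector<int> partner(n, -1);
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  const double EPS = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (std::fabs(E[i][j] - E[i + 1][j]) < EPS && E[i][j] > -EPS) continue;
    // prefer pairing i when it achieves the optimum
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      double pe = pair_e(i, k);
      if (pe >= 0) continue;
      double v = pe + (k > i + 1 ? E[i + 1][k - 1] : 0.0) +
                 (k < j ? E[k + 1][j] : 0.0);
      if (std::fabs(v - E[i][j]) < EPS) {
        partner[i] = k; partner[k] = i;
        if (k > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  std::string db(n, '.');
  double energy = 0.0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      db[i] = '('; db[partner[i]] = ')';
      energy += pair_e(i, partner[i]);
    }
  }
  IntegerVector pr(n);
  for (int i = 0; i < n; ++i) pr[i] = partner[i];
  return List::create(_["structure"] = db, _["energy"] = energy,
                      _["pairs"] = pr);
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment score of each query against a reference
// set; linear gap penalty.  Returns the best score over references per query.
// ---------------------------------------------------------------------------

static double sw_score(const std::string& a, const std::string& b,
                       double match, double mismatch, double gap) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double s = (base_code(a[i - 1]) == base_code(b[j - 1])) ? match : mismatch;
      double v = prev[j - 1] + s;
      v = std::max(v, prev[j] + gap);
      v = std::max(v, cur[j - 1] + gap);
      v = std::max(v, 0.0);
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_sw_best(CharacterVector queries, CharacterVector refs,
                          double match, double mismatch, double gap) {
  int nq = queries.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int r = 0; r < nr; ++r) rs[r] = as<std::string>(refs[r]);
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    std::string qs = as<std::string>(queries[q]);
    double best = 0.0;
    for (int r = 0; r < nr; ++r)
      best = std::max(best, sw_score(qs, rs[r], match, mismatch, gap));
    out[q] = best;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sw_argbest(std::string query, CharacterVector refs,
                             double match, double mismatch, double gap) {
  int nr = refs.size();
  double best = -1.0; int arg = 0;
  for (int r = 0; r < nr; ++r) {
    double s = sw_score(query, as<std::string>(refs[r]), match, mismatch, gap);
    if (s > best) { best = s; arg = r + 1; }
  }
  return IntegerVector::create(arg, (int)std::lround(best));
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* x = CHAR(STRING_ELT(a, i));
    const char* y = CHAR(STRING_ELT(b, i));
    int d = 0, j = 0;
    for (; x[j] && y[j]; ++j) if (x[j] != y[j]) ++d;
    if (x[j] || y[j]) d = NA_INTEGER; // unequal lengths
    out[i] = d;
  }
  return out;
}
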