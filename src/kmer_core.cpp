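// Core sequence primitives: 2-bit k-mer encoding (k <= 63 via 128-bit words),
// canonical counting, unitig extraction, bubble walking on the colored de
// Bruijn graph, and a seed-and-extend read mapper with banded edit-distance
// extension and pileup accumulation.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

typedef unsigned __int128 u128;

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}
static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

struct U128Hash {
  size_t operator()(u128 x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL;
    h ^= hi + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    return (size_t)h;
  }
};

static inline u128 kmask(int k) {
  return (((u128)1) << (2 * k)) - 1;
}

static inline u128 revcomp_kmer(u128 x, int k) {
  u128 r = 0;
  for (int i = 0; i < k; i++) {
    r = (r << 2) | (u128)(3u - (unsigned)(x & 3));
    x >>= 2;
  }
  return r;
}

static inline u128 canon_kmer(u128 x, int k) {
  u128 r = revcomp_kmer(x, k);
  return r < x ? r : x;
}

static std::string decode_kmer(u128 x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; i--) {
    s[i] = CODE2BASE[(unsigned)(x & 3)];
    x >>= 2;
  }
  return s;
}

static bool encode_kmer(const char* s, int k, u128& out) {
  u128 x = 0;
  for (int i = 0; i < k; i++) {
    int c = base2code(s[i]);
    if (c < 0) return false;
    x = (x << 2) | (u128)(unsigned)c;
  }
  out = x;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); j++) {
      switch (r[j]) {
      case 'A': r[j] = 'T'; break; case 'a': r[j] = 't'; break;
      case 'C': r[j] = 'G'; break; case 'c': r[j] = 'g'; break;
      case 'G': r[j] = 'C'; break; case 'g': r[j] = 'c'; break;
      case 'T': r[j] = 'A'; break; case 't': r[j] = 'a'; break;
      default: break; // N and friends stay
      }
    }
    out[i] = r;
  }
  return out;
}

// Canonical k-mer counting over a set of reads; k-mers containing non-ACGT
// characters are skipped (rolling window resets at each invalid base).
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k) {
  if (k < 1 || k > 63) stop("k must be in [1, 63]");
  std::unordered_map<u128, int, U128Hash> tab;
  u128 mask = kmask(k);
  int shift_hi = 2 * (k - 1);
  for (int r = 0; r < reads.size(); r++) {
    if (reads[r] == NA_STRING) continue;
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)std::strlen(s);
    u128 fwd = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < len; i++) {
      int c = base2code(s[i]);
      if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (u128)(unsigned)c) & mask;
      rc = (rc >> 2) | ((u128)(unsigned)(3 - c) << shift_hi);
      if (++run >= k) {
        u128 key = fwd < rc ? fwd : rc;
        tab[key]++;
      }
    }
  }
  std::vector<u128> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int n = (int)keys.size();
  CharacterVector kmers(n);
  IntegerVector counts(n);
  for (int i = 0; i < n; i++) {
    kmers[i] = decode_kmer(keys[i], k);
    counts[i] = tab[keys[i]];
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// ---- graph helpers -------------------------------------------------------

typedef std::unordered_set<u128, U128Hash> KmerSet;

static inline int successors(const KmerSet& set, u128 x, int k, u128 mask,
                             u128* out) {
  int n = 0;
  u128 base = (x << 2) & mask;
  for (unsigned b = 0; b < 4; b++) {
    u128 y = base | (u128)b;
    if (set.count(canon_kmer(y, k))) out[n++] = y;
  }
  return n;
}

static inline int outdeg(const KmerSet& set, u128 x, int k, u128 mask) {
  u128 tmp[4];
  return successors(set, x, k, mask, tmp);
}

static inline int indeg(const KmerSet& set, u128 x, int k, u128 mask) {
  return outdeg(set, revcomp_kmer(x, k), k, mask);
}

// Maximal non-branching paths (unitigs), each emitted once in canonical
// orientation, with mean per-kmer coverage (summed over colors).
// [[Rcpp::export]]
List cpp_unitigs(CharacterVector kmers, NumericVector total_counts, int k) {
  int n = kmers.size();
  KmerSet set;
  std::unordered_map<u128, double, U128Hash> cov;
  std::vector<u128> sorted;
  sorted.reserve(n);
  for (int i = 0; i < n; i++) {
    u128 x;
    if (!encode_kmer(CHAR(STRING_ELT(kmers, i)), k, x)) stop("bad k-mer");
    u128 c = canon_kmer(x, k);
    set.insert(c);
    cov[c] = total_counts.size() == n ? total_counts[i] : 0.0;
    sorted.push_back(c);
  }
  std::sort(sorted.begin(), sorted.end());
  u128 mask = kmask(k);
  KmerSet visited;
  std::vector<std::string> seqs;
  std::vector<double> means;

  for (u128 start : sorted) {
    if (visited.count(start)) continue;
    std::vector<u128> path; // oriented k-mers
    path.push_back(start);
    visited.insert(start);
    // forward
    u128 cur = start;
    while (true) {
      u128 succ[4];
      if (successors(set, cur, k, mask, succ) != 1) break;
      u128 y = succ[0];
      if (indeg(set, y, k, mask) != 1) break;
      u128 cy = canon_kmer(y, k);
      if (visited.count(cy)) break;
      path.push_back(y);
      visited.insert(cy);
      cur = y;
    }
    // backward: walk forward from revcomp(start), then flip
    std::vector<u128> back;
    cur = revcomp_kmer(start, k);
    while (true) {
      u128 succ[4];
      if (successors(set, cur, k, mask, succ) != 1) break;
      u128 y = succ[0];
      if (indeg(set, y, k, mask) != 1) break;
      u128 cy = canon_kmer(y, k);
      if (visited.count(cy)) break;
      back.push_back(y);
      visited.insert(cy);
      cur = y;
    }
    std::vector<u128> full;
    for (auto it = back.rbegin(); it != back.rend(); ++it)
      full.push_back(revcomp_kmer(*it, k));
    for (u128 p : path) full.push_back(p);

    std::string seq = decode_kmer(full[0], k);
    double covsum = 0.0;
    for (size_t i = 0; i < full.size(); i++) {
      if (i > 0) seq.push_back(CODE2BASE[(unsigned)(full[i] & 3)]);
      covsum += cov[canon_kmer(full[i], k)];
    }
    // canonical orientation of the whole unitig
    std::string rcseq(seq.rbegin(), seq.rend());
    for (auto& ch : rcseq)
      ch = ch == 'A' ? 'T' : ch == 'C' ? 'G' : ch == 'G' ? 'C' : 'A';
    if (rcseq < seq) seq = rcseq;
    seqs.push_back(seq);
    means.push_back(covsum / (double)full.size());
  }
  // deterministic output order
  std::vector<int> ord(seqs.size());
  for (size_t i = 0; i < ord.size(); i++) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (seqs[a].size() != seqs[b].size()) return seqs[a].size() > seqs[b].size();
    return seqs[a] < seqs[b];
  });
  CharacterVector out_seq(seqs.size());
  NumericVector out_cov(seqs.size());
  for (size_t i = 0; i < ord.size(); i++) {
    out_seq[i] = seqs[ord[i]];
    out_cov[i] = means[ord[i]];
  }
  return List::create(_["sequence"] = out_seq, _["mean_coverage"] = out_cov);
}

// Walk one branch from oriented k-mer s until the first join node (indeg>=2).
// Returns true on success; interior holds the simple-path nodes, y the join.
static bool walk_branch(const KmerSet& set, u128 s, int k, u128 mask,
                        int max_branch, std::vector<u128>& interior, u128& y) {
  u128 cur = s;
  interior.clear();
  while (true) {
    if (indeg(set, cur, k, mask) >= 2) { y = cur; return !interior.empty(); }
    interior.push_back(cur);
    if ((int)interior.size() > max_branch) return false;
    u128 succ[4];
    if (successors(set, cur, k, mask, succ) != 1) return false;
    cur = succ[0];
  }
}

static std::string rc_string(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& ch : r)
    ch = ch == 'A' ? 'T' : ch == 'C' ? 'G' : ch == 'G' ? 'C' : 'A';
  return r;
}

// Bubble motifs: a fork node X with two simple-path branches reconverging at
// the same join node Y. Each bubble reported once (canonical representation).
// [[Rcpp::export]]
List cpp_find_bubbles(CharacterVector kmers, IntegerMatrix counts, int k,
                      int max_branch) {
  int n = kmers.size();
  int ns = counts.ncol();
  KmerSet set;
  std::unordered_map<u128, int, U128Hash> row;
  std::vector<u128> sorted;
  sorted.reserve(n);
  for (int i = 0; i < n; i++) {
    u128 x;
    if (!encode_kmer(CHAR(STRING_ELT(kmers, i)), k, x)) stop("bad k-mer");
    u128 c = canon_kmer(x, k);
    set.insert(c);
    row[c] = i;
    sorted.push_back(c);
  }
  std::sort(sorted.begin(), sorted.end());
  u128 mask = kmask(k);

  std::vector<std::string> f5, f3, ba, bb;
  std::vector<std::vector<double> > cova, covb;
  std::unordered_set<std::string> seen;

  for (u128 c : sorted) {
    for (int orient = 0; orient < 2; orient++) {
      u128 X = orient == 0 ? c : revcomp_kmer(c, k);
      if (orient == 1 && X == c) continue;
      u128 succ[4];
      int ns_out = successors(set, X, k, mask, succ);
      if (ns_out < 2) continue;
      // walk each branch
      std::vector<std::vector<u128> > ints(ns_out);
      std::vector<u128> joins(ns_out);
      std::vector<bool> ok(ns_out, false);
      for (int i = 0; i < ns_out; i++)
        ok[i] = walk_branch(set, succ[i], k, mask, max_branch, ints[i], joins[i]);
      for (int i = 0; i < ns_out; i++) {
        if (!ok[i]) continue;
        for (int j = i + 1; j < ns_out; j++) {
          if (!ok[j] || joins[i] != joins[j]) continue;
          // branch strings = appended bases of interior nodes
          std::string bi, bj;
          for (u128 p : ints[i]) bi.push_back(CODE2BASE[(unsigned)(p & 3)]);
          for (u128 p : ints[j]) bj.push_back(CODE2BASE[(unsigned)(p & 3)]);
          if (bi == bj) continue;
          std::string sa = bi, sb = bj;
          const std::vector<u128>* ia = &ints[i];
          const std::vector<u128>* ib = &ints[j];
          if (sb < sa) { std::swap(sa, sb); std::swap(ia, ib); }
          std::string s5 = decode_kmer(X, k);
          std::string s3 = decode_kmer(joins[i], k);
          std::string key = s5 + "|" + sa + "|" + sb + "|" + s3;
          // flipped representation: the reverse walk discovers the same
          // bubble with fork rc(flank3) and branch rc(full[1..m]) where
          // full = flank5 + branch + last(flank3)
          std::string r5 = rc_string(s3), r3 = rc_string(s5);
          std::string fulla = s5 + sa + s3.back();
          std::string fullb = s5 + sb + s3.back();
          std::string rsa = rc_string(fulla.substr(1, sa.size()));
          std::string rsb = rc_string(fullb.substr(1, sb.size()));
          if (rsb < rsa) std::swap(rsa, rsb);
          std::string fkey = r5 + "|" + rsa + "|" + rsb + "|" + r3;
          // first walk direction to find the bubble emits it; the reverse
          // direction computes the same canonical key and is skipped
          std::string canonkey = key <= fkey ? key : fkey;
          if (seen.count(canonkey)) continue;
          seen.insert(canonkey);
          std::vector<double> ca(ns, 0.0), cb(ns, 0.0);
          for (u128 p : *ia) {
            int rr = row[canon_kmer(p, k)];
            for (int s2 = 0; s2 < ns; s2++) ca[s2] += counts(rr, s2);
          }
          for (u128 p : *ib) {
            int rr = row[canon_kmer(p, k)];
            for (int s2 = 0; s2 < ns; s2++) cb[s2] += counts(rr, s2);
          }
          for (int s2 = 0; s2 < ns; s2++) {
            ca[s2] /= (double)ia->size();
            cb[s2] /= (double)ib->size();
          }
          f5.push_back(s5); f3.push_back(s3);
          ba.push_back(sa); bb.push_back(sb);
          cova.push_back(ca); covb.push_back(cb);
        }
      }
    }
  }
  int nb = (int)f5.size();
  std::vector<int> ord(nb);
  for (int i = 0; i < nb; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (f5[a] != f5[b]) return f5[a] < f5[b];
    return ba[a] < ba[b];
  });
  CharacterVector o5(nb), o3(nb), oa(nb), ob(nb);
  NumericMatrix mca(nb, ns), mcb(nb, ns);
  for (int i = 0; i < nb; i++) {
    int q = ord[i];
    o5[i] = f5[q]; o3[i] = f3[q]; oa[i] = ba[q]; ob[i] = bb[q];
    for (int s2 = 0; s2 < ns; s2++) {
      mca(i, s2) = cova[q][s2];
      mcb(i, s2) = covb[q][s2];
    }
  }
  return List::create(_["flank5"] = o5, _["flank3"] = o3,
                      _["branch_a"] = oa, _["branch_b"] = ob,
                      _["cov_a"] = mca, _["cov_b"] = mcb);
}

// ---- read mapping --------------------------------------------------------

struct Cand { int ref; int start; int strand; };

struct AlnResult {
  int ref = -1, start = -1, strand = 0, edits = -1;
  int read_start = 0; // first read base of the aligned core (prefix clip)
  std::string ops; // '=' match, 'X' mismatch, 'D' ref-only, 'I' read-only
};

// Semi-global alignment of read vs window (free leading/trailing ref).
// clip_den > 0 additionally allows soft-clipping the read ends at a cost of
// one edit per clip_den clipped bases; clipped bases emit no ops.
static bool align_window(const std::string& read, const char* ref, int ws,
                         int we, int band, AlnResult& res,
                         int clip_den = 0) {
  int m = (int)read.size();
  int nw = we - ws;
  if (nw < m) return false;
  const int INF = 1 << 28;
  auto clip = [&](int i) {
    return clip_den > 0 ? (i + clip_den - 1) / clip_den : (i == 0 ? 0 : INF);
  };
  std::vector<int> D((m + 1) * (nw + 1));
  int W = nw + 1;
  for (int j = 0; j <= nw; j++) D[j] = 0;
  for (int i = 1; i <= m; i++) D[i * W] = std::min(i, clip(i));
  for (int i = 1; i <= m; i++) {
    for (int j = 1; j <= nw; j++) {
      int diag = D[(i - 1) * W + j - 1] + (read[i - 1] == ref[ws + j - 1] &&
                                           base2code(read[i - 1]) >= 0 ? 0 : 1);
      int up = D[(i - 1) * W + j] + 1;   // read-only (insertion)
      int left = D[i * W + j - 1] + 1;   // ref-only (deletion)
      int best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      if (clip_den > 0 && clip(i) < best) best = clip(i); // fresh start
      D[i * W + j] = best;
    }
  }
  // scan end candidates preferring the longest alignment (largest i) on
  // cost ties, so soft clips never eat alignable read ends
  int besti = m, bestj = 0, beste = INT_MAX;
  for (int i = m; i >= (clip_den > 0 ? 0 : m); i--)
    for (int j = 0; j <= nw; j++) {
      int tot = D[i * W + j] + clip(m - i);
      if (tot < beste) { beste = tot; besti = i; bestj = j; }
    }
  if (beste > band) return false;
  // traceback with gap affinity: among equal-cost moves, prefer extending
  // the gap type just emitted, so an indel stays one contiguous event
  std::string ops;
  int i = besti, j = bestj;
  char last = 0;
  while (i > 0) {
    int cur = D[i * W + j];
    // if clipping the remaining read prefix is as cheap as the alignment
    // that produced it, clip: junk bases must not survive at the boundary
    if (clip_den > 0 && cur == clip(i)) break;
    bool can_diag = j > 0 &&
      D[(i - 1) * W + j - 1] +
          (read[i - 1] == ref[ws + j - 1] && base2code(read[i - 1]) >= 0
               ? 0 : 1) == cur;
    bool can_up = D[(i - 1) * W + j] + 1 == cur;           // 'I'
    bool can_left = j > 0 && D[i * W + j - 1] + 1 == cur;  // 'D'
    char op;
    if (last == 'D' && can_left) op = 'D';
    else if (last == 'I' && can_up) op = 'I';
    else if (can_diag) op = read[i - 1] == ref[ws + j - 1] ? '=' : 'X';
    else if (can_left) op = 'D';
    else if (can_up) op = 'I';
    else break; // prefix soft-clip start
    ops.push_back(op);
    last = op == '=' || op == 'X' ? 0 : op;
    if (op == '=' || op == 'X') { i--; j--; }
    else if (op == 'I') i--;
    else j--;
  }
  std::reverse(ops.begin(), ops.end());
  res.start = ws + j;
  res.read_start = i;
  res.edits = beste;
  res.ops = ops;
  return true;
}

// mod_period > 0 treats each reference as periodic with that period:
// placements congruent modulo the period are equivalent (tandem-repeat
// pileup onto one unit); pileup rows are folded onto [0, period).
// clip_den > 0 enables read-end soft clipping (one edit per clip_den bases).
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs, int k_anchor,
                   int band, bool do_pileup, int mod_period = 0,
                   int clip_den = 0) {
  int nr = reads.size(), nref = refs.size();
  if (nref < 1) stop("empty reference");
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; i++) R[i] = as<std::string>(refs[i]);
  u128 mask = kmask(k_anchor);
  int shift_hi = 2 * (k_anchor - 1);
  // index: forward k-mers of refs -> packed (ref, pos)
  std::unordered_map<u128, std::vector<int64_t>, U128Hash> index;
  for (int rI = 0; rI < nref; rI++) {
    const std::string& s = R[rI];
    u128 fwd = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); i++) {
      int c = base2code(s[i]);
      if (c < 0) { run = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (u128)(unsigned)c) & mask;
      if (++run >= k_anchor) {
        int pos = i - k_anchor + 1;
        index[fwd].push_back(((int64_t)rI << 32) | (int64_t)pos);
      }
    }
  }

  IntegerVector out_ref(nr, NA_INTEGER), out_pos(nr, NA_INTEGER),
      out_strand(nr, NA_INTEGER), out_edits(nr, NA_INTEGER);
  // pileup matrices: per ref, L x 8 (A C G T N del ins_n ins_bp)
  std::vector<IntegerMatrix> piles;
  if (do_pileup)
    for (int i = 0; i < nref; i++)
      piles.push_back(IntegerMatrix(
          mod_period > 0 ? std::min(mod_period, (int)R[i].size())
                         : (int)R[i].size(), 8));
  double aligned_bases = 0.0;
  const int MAX_CAND = 128;

  for (int r = 0; r < nr; r++) {
    std::string fwd = as<std::string>(reads[r]);
    int m = (int)fwd.size();
    if (m < k_anchor) continue;
    std::string rc(fwd.rbegin(), fwd.rend());
    for (auto& ch : rc)
      ch = ch == 'A' ? 'T' : ch == 'C' ? 'G' : ch == 'G' ? 'C' :
           ch == 'T' ? 'A' : ch;
    std::vector<Cand> cands;
    std::unordered_set<int64_t> ckeys;
    bool too_many = false;
    for (int strand = 0; strand < 2 && !too_many; strand++) {
      const std::string& s = strand == 0 ? fwd : rc;
      u128 roll = 0; int run = 0;
      for (int i = 0; i < m; i++) {
        int c = base2code(s[i]);
        if (c < 0) { run = 0; roll = 0; continue; }
        roll = ((roll << 2) | (u128)(unsigned)c) & mask;
        if (++run < k_anchor) continue;
        auto it = index.find(roll);
        if (it == index.end()) continue;
        int o = i - k_anchor + 1;
        for (int64_t packed : it->second) {
          int rI = (int)(packed >> 32);
          int p = (int)(packed & 0xffffffffLL);
          int start = p - o;
          int64_t key = ((int64_t)rI << 34) |
                        ((int64_t)(start + 2000000) << 1) | (int64_t)strand;
          if (ckeys.insert(key).second) {
            cands.push_back({rI, start, strand == 0 ? 1 : -1});
            if ((int)cands.size() > MAX_CAND) { too_many = true; break; }
          }
        }
        if (too_many) break;
      }
    }
    if (too_many || cands.empty()) continue;
    // evaluate candidates
    std::vector<AlnResult> best;
    int best_e = INT_MAX;
    for (const Cand& cd : cands) {
      const std::string& ref = R[cd.ref];
      const std::string& s = cd.strand > 0 ? fwd : rc;
      int L = (int)ref.size();
      AlnResult ar;
      ar.ref = cd.ref; ar.strand = cd.strand;
      bool got = false;
      if (cd.start >= 0 && cd.start + m <= L &&
          std::memcmp(s.data(), ref.data() + cd.start, m) == 0) {
        ar.start = cd.start; ar.edits = 0; ar.ops = std::string(m, '=');
        got = true;
      } else {
        int ws = std::max(0, cd.start - band);
        int we = std::min(L, cd.start + m + band);
        got = align_window(s, ref.data(), ws, we, band, ar, clip_den);
      }
      if (!got) continue;
      if (ar.edits < best_e) { best_e = ar.edits; best.clear(); best.push_back(ar); }
      else if (ar.edits == best_e) {
        bool dup = false;
        for (const AlnResult& b : best) {
          bool same_start = mod_period > 0
            ? (b.start % mod_period) == (ar.start % mod_period)
            : b.start == ar.start;
          if (b.ref == ar.ref && same_start && b.strand == ar.strand)
            { dup = true; break; }
        }
        if (!dup) best.push_back(ar);
      }
    }
    if (best.size() != 1) continue; // ambiguous tie or no placement
    const AlnResult& a = best[0];
    out_ref[r] = a.ref + 1;
    out_pos[r] = mod_period > 0 ? a.start % mod_period : a.start;
    out_strand[r] = a.strand;
    out_edits[r] = a.edits;
    if (do_pileup) {
      IntegerMatrix& P = piles[a.ref];
      const std::string& s = a.strand > 0 ? fwd : rc;
      int L = (int)R[a.ref].size();
      int Lp = P.nrow();
      auto fold = [&](int q) {
        int at = std::max(0, std::min(q, L - 1));
        return mod_period > 0 ? at % mod_period : at;
      };
      int q = a.start, ri = a.read_start;
      int ins_run = 0;
      for (char op : a.ops) {
        if (op == '=' || op == 'X') {
          if (ins_run > 0) {
            int at = fold(q);
            P(at, 6) += 1; P(at, 7) += ins_run;
            ins_run = 0;
          }
          if (q >= 0 && q < L) {
            int c = base2code(s[ri]);
            int at = fold(q);
            if (at < Lp) { P(at, c < 0 ? 4 : c) += 1; }
            aligned_bases += 1.0;
          }
          q++; ri++;
        } else if (op == 'D') {
          if (ins_run > 0) {
            int at = fold(q);
            P(at, 6) += 1; P(at, 7) += ins_run;
            ins_run = 0;
          }
          if (q >= 0 && q < L) P(fold(q), 5) += 1;
          q++;
        } else { // 'I'
          ins_run++;
          ri++;
        }
      }
      if (ins_run > 0) {
        int at = fold(q);
        P(at, 6) += 1; P(at, 7) += ins_run;
      }
    }
  }
  List pl = List(0);
  if (do_pileup) {
    pl = List(nref);
    for (int i = 0; i < nref; i++) pl[i] = piles[i];
  }
  return List::create(_["ref"] = out_ref, _["pos0"] = out_pos,
                      _["strand"] = out_strand, _["edits"] = out_edits,
                      _["pileup"] = pl, _["aligned_bases"] = aligned_bases);
}

// Exact shared k-mer seed matches between two sequences (both strands of a
// relative to forward b). Returns 0-based positions.
// [[Rcpp::export]]
List cpp_seed_matches(std::string a, std::string b, int k) {
  u128 mask = kmask(k);
  std::unordered_map<u128, std::vector<int>, U128Hash> bidx;
  {
    u128 roll = 0; int run = 0;
    for (int i = 0; i < (int)b.size(); i++) {
      int c = base2code(b[i]);
      if (c < 0) { run = 0; roll = 0; continue; }
      roll = ((roll << 2) | (u128)(unsigned)c) & mask;
      if (++run >= k) bidx[roll].push_back(i - k + 1);
    }
  }
  std::vector<int> pa, pb, st;
  for (int strand = 0; strand < 2; strand++) {
    std::string s = strand == 0 ? a : rc_string(a);
    u128 roll = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); i++) {
      int c = base2code(s[i]);
      if (c < 0) { run = 0; roll = 0; continue; }
      roll = ((roll << 2) | (u128)(unsigned)c) & mask;
      if (++run < k) continue;
      auto it = bidx.find(roll);
      if (it == bidx.end()) continue;
      int o = i - k + 1;
      int oa = strand == 0 ? o : (int)a.size() - o - k; // on forward a
      for (int p : it->second) {
        pa.push_back(oa); pb.push_back(p); st.push_back(strand == 0 ? 1 : -1);
      }
    }
  }
  return List::create(_["pos_a"] = wrap(pa), _["pos_b"] = wrap(pb),
                      _["strand"] = wrap(st));
}

// Banded global edit distance (unit costs); returns distance or -1 if it
// exceeds the band.
// [[Rcpp::export]]
int cpp_banded_edit(std::string a, std::string b, int band) {
  int m = (int)a.size(), n = (int)b.size();
  if (std::abs(m - n) > band) return -1;
  const int INF = 1 << 28;
  std::vector<int> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  prev[band] = 0;
  for (int d = 1; d <= band && d <= n; d++) prev[band + d] = d;
  for (int i = 1; i <= m; i++) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(1, i - band), jhi = std::min(n, i + band);
    if (i <= band) cur[band - i] = i; // j = 0
    for (int j = jlo; j <= jhi; j++) {
      int off = j - i + band;
      int best = INF;
      int diag = prev[off];
      if (diag < INF) best = diag + (a[i - 1] == b[j - 1] ? 0 : 1);
      if (off - 1 >= 0 && cur[off - 1] < INF) best = std::min(best, cur[off - 1] + 1);
      if (off + 1 <= 2 * band && prev[off + 1] < INF) best = std::min(best, prev[off + 1] + 1);
      cur[off] = best;
    }
    std::swap(prev, cur);
  }
  int off = n - m + band;
  if (off < 0 || off > 2 * band) return -1;
  int d = prev[off];
  return d >= (1 << 28) ? -1 : d;
}

// Unit-cost global alignment with deterministic traceback; returns the two
// aligned strings ('-' gaps). Intended for bubble-branch decomposition.
// [[Rcpp::export]]
CharacterVector cpp_global_align(std::string a, std::string b) {
  int m = (int)a.size(), n = (int)b.size();
  std::vector<int> D((m + 1) * (n + 1));
  int W = n + 1;
  for (int j = 0; j <= n; j++) D[j] = j;
  for (int i = 1; i <= m; i++) D[i * W] = i;
  for (int i = 1; i <= m; i++)
    for (int j = 1; j <= n; j++) {
      int best = D[(i - 1) * W + j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      best = std::min(best, D[(i - 1) * W + j] + 1);
      best = std::min(best, D[i * W + j - 1] + 1);
      D[i * W + j] = best;
    }
  std::string aa, bb;
  int i = m, j = n;
  char last = 0; // gap affinity, as in the mapper traceback
  while (i > 0 || j > 0) {
    int cur = D[i * W + j];
    bool can_diag = i > 0 && j > 0 &&
      D[(i - 1) * W + j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1) == cur;
    bool can_up = i > 0 && D[(i - 1) * W + j] + 1 == cur;   // gap in b
    bool can_left = j > 0 && D[i * W + j - 1] + 1 == cur;   // gap in a
    char op;
    if (last == 'U' && can_up) op = 'U';
    else if (last == 'L' && can_left) op = 'L';
    else if (can_diag) op = 'M';
    else if (can_up) op = 'U';
    else op = 'L';
    last = op == 'M' ? 0 : op;
    if (op == 'M') {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); i--; j--;
    } else if (op == 'U') {
      aa.push_back(a[i - 1]); bb.push_back('-'); i--;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); j--;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return CharacterVector::create(aa, bb);
}
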