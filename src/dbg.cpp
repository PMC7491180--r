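// k-mer counting and unitig compaction for the bidirected de Bruijn graph.
// k-mers are 2-bit encoded (A=0, C=1, G=2, T=3) in a uint64, so k <= 31
// (k+1-mers then fit in 64 bits as well).  All tables are keyed by the
// canonical (lexicographically smaller of forward / reverse complement)
// encoding; k must be odd so no k-mer equals its own reverse complement.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

struct KmerTable {
  int k;
  std::unordered_map<uint64_t, double> counts;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t x, int k) {
  x = ~x;
  x = ((x >> 2) & 0x3333333333333333ULL) | ((x & 0x3333333333333333ULL) << 2);
  x = ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL) | ((x & 0x0F0F0F0F0F0F0F0FULL) << 4);
  x = ((x >> 8) & 0x00FF00FF00FF00FFULL) | ((x & 0x00FF00FF00FF00FFULL) << 8);
  x = ((x >> 16) & 0x0000FFFF0000FFFFULL) | ((x & 0x0000FFFF0000FFFFULL) << 16);
  x = (x >> 32) | (x << 32);
  return x >> (64 - 2 * k);
}

static inline uint64_t canon_code(uint64_t x, int k) {
  uint64_t r = revcomp_code(x, k);
  return x < r ? x : r;
}

static std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[x & 3ULL];
    x >>= 2;
  }
  return s;
}

static bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    x = (x << 2) | (uint64_t)b;
  }
  out = x;
  return true;
}

// [[Rcpp::export(name = ".cpp_kmer_table")]]
SEXP cpp_kmer_table(CharacterVector seqs, CharacterVector quals, int k,
                    bool weighted) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  bool use_quals = weighted && quals.size() == seqs.size();
  KmerTable* tab = new KmerTable();
  tab->k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<double> logq;
  std::vector<int> zeros;

  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int n = (int)LENGTH(STRING_ELT(seqs, r));
    if (n < k) continue;
    const char* q = nullptr;
    if (use_quals) {
      q = CHAR(STRING_ELT(quals, r));
      if ((int)LENGTH(STRING_ELT(quals, r)) != n)
        stop("quality string length does not match read length");
      // prefix sums of log base weights; zero weights tracked separately
      logq.assign(n + 1, 0.0);
      zeros.assign(n + 1, 0);
      for (int i = 0; i < n; ++i) {
        int phred = (int)q[i] - 33;
        if (phred < 0) phred = 0;
        double w = 1.0 - std::pow(10.0, -phred / 10.0);
        logq[i + 1] = logq[i] + (w > 0 ? std::log(w) : 0.0);
        zeros[i + 1] = zeros[i] + (w > 0 ? 0 : 1);
      }
    }
    uint64_t x = 0;
    int run = 0;  // length of current valid-base run
    for (int i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; continue; }
      x = ((x << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      uint64_t key = canon_code(x, k);
      double w = 1.0;
      if (use_quals) {
        int lo = i - k + 1;
        if (zeros[i + 1] - zeros[lo] > 0) w = 0.0;
        else w = std::exp(logq[i + 1] - logq[lo]);
      }
      tab->counts[key] += w;
    }
  }
  XPtr<KmerTable> ptr(tab, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_table_k")]]
int cpp_table_k(SEXP tabp) { return XPtr<KmerTable>(tabp)->k; }

// [[Rcpp::export(name = ".cpp_table_size")]]
double cpp_table_size(SEXP tabp) {
  return (double)XPtr<KmerTable>(tabp)->counts.size();
}

// Counts of the canonical forms of the given k-mers (0 when absent).
// [[Rcpp::export(name = ".cpp_table_counts_of")]]
NumericVector cpp_table_counts_of(SEXP tabp, CharacterVector kmers) {
  XPtr<KmerTable> tab(tabp);
  int k = tab->k;
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) stop("k-mer of wrong length");
    uint64_t x;
    if (!encode_kmer(s, k, x)) { out[i] = 0; continue; }
    auto it = tab->counts.find(canon_code(x, k));
    out[i] = (it == tab->counts.end()) ? 0.0 : it->second;
  }
  return out;
}

// Per-sequence vectors of consecutive k-mer counts (canonical lookup).
// [[Rcpp::export(name = ".cpp_seq_kmer_counts")]]
List cpp_seq_kmer_counts(SEXP tabp, CharacterVector seqs) {
  XPtr<KmerTable> tab(tabp);
  int k = tab->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  List out(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int n = (int)LENGTH(STRING_ELT(seqs, r));
    int nk = n - k + 1;
    if (nk < 1) { out[r] = NumericVector(0); continue; }
    NumericVector v(nk);
    uint64_t x = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; if (i >= k - 1) v[i - k + 1] = NA_REAL; continue; }
      x = ((x << 2) | (uint64_t)b) & mask;
      if (++run < k) { if (i >= k - 1) v[i - k + 1] = NA_REAL; continue; }
      auto it = tab->counts.find(canon_code(x, k));
      v[i - k + 1] = (it == tab->counts.end()) ? 0.0 : it->second;
    }
    out[r] = v;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_table_values")]]
NumericVector cpp_table_values(SEXP tabp) {
  XPtr<KmerTable> tab(tabp);
  NumericVector out(tab->counts.size());
  R_xlen_t i = 0;
  for (auto& kv : tab->counts) out[i++] = kv.second;
  return out;
}

// ---------------------------------------------------------------------------
// Unitig compaction.
//
// Oriented k-mers are walked in the directed graph whose edges are the
// observed k+1-mers with both constituent k-mers surviving the abundance
// filter.  A unitig is a maximal path along which every internal junction has
// out-degree 1 (at its tail) and in-degree 1 (at its head).  The in-degree of
// an oriented k-mer equals the out-degree of its reverse complement.

struct Walker {
  int k;
  uint64_t mask_k, mask_k1;
  const std::unordered_set<uint64_t>* kset;    // canonical surviving k-mers
  const std::unordered_set<uint64_t>* k1set;   // canonical arc k+1-mers

  int outdeg(uint64_t u, uint64_t* succ) const {
    int d = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t k1 = ((u << 2) | b) & mask_k1;
      if (k1set->count(canon_code(k1, k + 1))) {
        if (succ && d == 0) *succ = k1 & mask_k;
        ++d;
      }
    }
    return d;
  }
  int indeg(uint64_t u) const { return outdeg(revcomp_code(u, k), nullptr); }

  bool is_start(uint64_t u) const {
    uint64_t pred_rc;
    uint64_t urc = revcomp_code(u, k);
    int din = outdeg(urc, &pred_rc);
    if (din != 1) return true;
    uint64_t pred = revcomp_code(pred_rc, k);
    return outdeg(pred, nullptr) != 1;
  }
};

// [[Rcpp::export(name = ".cpp_build_unitigs")]]
List cpp_build_unitigs(SEXP ktabp, SEXP k1tabp, double abundance_min) {
  XPtr<KmerTable> ktab(ktabp);
  XPtr<KmerTable> k1tab(k1tabp);
  int k = ktab->k;
  if (k1tab->k != k + 1) stop("second table must hold k+1-mers");
  if (k % 2 == 0) stop("k must be odd");

  std::unordered_set<uint64_t> kset;
  kset.reserve(ktab->counts.size());
  for (auto& kv : ktab->counts)
    if (kv.second >= abundance_min) kset.insert(kv.first);
  if (kset.empty()) stop("empty graph: no k-mer reaches the abundance threshold");

  std::unordered_set<uint64_t> k1set;
  const uint64_t mask_k = (1ULL << (2 * k)) - 1;
  for (auto& kv : k1tab->counts) {
    uint64_t c = kv.first;
    uint64_t pre = c >> 2, suf = c & mask_k;
    if (kset.count(canon_code(pre, k)) && kset.count(canon_code(suf, k)))
      k1set.insert(c);
  }

  Walker W{k, mask_k, (1ULL << (2 * (k + 1))) - 1, &kset, &k1set};

  std::unordered_set<uint64_t> visited;
  visited.reserve(kset.size());
  std::vector<std::string> useqs;

  auto walk = [&](uint64_t start, bool circular_sweep) {
    std::string seq = decode_kmer(start, k);
    visited.insert(canon_code(start, k));
    uint64_t cur = start;
    for (;;) {
      uint64_t nxt;
      if (W.outdeg(cur, &nxt) != 1) break;
      if (W.indeg(nxt) != 1) break;
      uint64_t cn = canon_code(nxt, k);
      if (visited.count(cn)) break;  // also terminates circular walks
      if (cn == canon_code(cur, k)) break;  // hairpin / self successor
      visited.insert(cn);
      seq.push_back(BASES[nxt & 3ULL]);
      cur = nxt;
    }
    (void)circular_sweep;
    // canonical unitig orientation: lexicographic minimum of seq and its RC
    std::string rc(seq.rbegin(), seq.rend());
    for (auto& ch : rc) {
      switch (ch) {
        case 'A': ch = 'T'; break; case 'T': ch = 'A'; break;
        case 'C': ch = 'G'; break; case 'G': ch = 'C'; break;
      }
    }
    useqs.push_back(seq < rc ? seq : rc);
  };

  // pass 1: walks from non-linear starts, in both orientations
  for (auto& c : kset) {
    if (visited.count(c)) continue;
    uint64_t fwd = c, rev = revcomp_code(c, k);
    if (W.is_start(fwd)) walk(fwd, false);
    else if (W.is_start(rev)) walk(rev, false);
  }
  // pass 2: leftover perfect cycles
  for (auto& c : kset) {
    if (!visited.count(c)) walk(c, true);
  }

  std::sort(useqs.begin(), useqs.end());

  // endpoint maps: oriented k-mer -> (unitig id, side)
  // exit: leaving the unitig; entry: entering it.  side 0 = left, 1 = right.
  struct End { int id; int side; };
  std::unordered_map<uint64_t, End> exit_map, entry_map;
  int nu = (int)useqs.size();
  for (int i = 0; i < nu; ++i) {
    const std::string& s = useqs[i];
    uint64_t f, l;
    encode_kmer(s.c_str(), k, f);
    encode_kmer(s.c_str() + (s.size() - k), k, l);
    exit_map[l] = {i + 1, 1};
    exit_map[revcomp_code(f, k)] = {i + 1, 0};
    entry_map[f] = {i + 1, 0};
    entry_map[revcomp_code(l, k)] = {i + 1, 1};
  }

  std::vector<int> a_from, a_fside, a_to, a_tside;
  std::vector<std::string> a_k1;
  std::vector<double> a_cov;
  for (auto& c : k1set) {
    uint64_t x = c >> 2, y = c & mask_k;
    auto ex = exit_map.find(x);
    auto en = entry_map.find(y);
    if (ex == exit_map.end() || en == entry_map.end()) continue;  // compacted
    a_from.push_back(ex->second.id);
    a_fside.push_back(ex->second.side);
    a_to.push_back(en->second.id);
    a_tside.push_back(en->second.side);
    a_k1.push_back(decode_kmer(c, k + 1));
    auto it = k1tab->counts.find(c);
    a_cov.push_back(it == k1tab->counts.end() ? 0.0 : it->second);
  }

  return List::create(
    _["seq"] = wrap(useqs),
    _["from"] = wrap(a_from), _["from_side"] = wrap(a_fside),
    _["to"] = wrap(a_to), _["to_side"] = wrap(a_tside),
    _["k1mer"] = wrap(a_k1), _["cov"] = wrap(a_cov));
}

// ---------------------------------------------------------------------------
// Read-error simulation helper: substitutes bases at the given rate and draws
// per-base Phred scores (high for correct calls, low for erroneous ones).
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".cpp_apply_read_errors")]]
List cpp_apply_read_errors(CharacterVector reads, double error_rate,
                           double phred_correct, double phred_error,
                           double phred_sd) {
  RNGScope scope;
  R_xlen_t n = reads.size();
  CharacterVector seqs(n), quals(n);
  IntegerVector nerr(n);
  std::string s, q;
  for (R_xlen_t r = 0; r < n; ++r) {
    const char* src = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    s.assign(src, len);
    q.assign(len, '!');
    int ne = 0;
    for (int i = 0; i < len; ++i) {
      double mu = phred_correct;
      if (error_rate > 0 && unif_rand() < error_rate) {
        int b = base_code(s[i]);
        if (b >= 0) {
          int nb = (b + 1 + (int)(unif_rand() * 3)) & 3;
          s[i] = BASES[nb];
          ++ne;
          mu = phred_error;
        }
      }
      double ph = mu + norm_rand() * phred_sd;
      int p = (int)std::lround(ph);
      if (p < 2) p = 2;
      if (p > 40) p = 40;
      q[i] = (char)(33 + p);
    }
    seqs[r] = s;
    quals[r] = q;
    nerr[r] = ne;
  }
  return List::create(_["seq"] = seqs, _["qual"] = quals, _["n_errors"] = nerr);
}
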