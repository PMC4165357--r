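#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Bounded Levenshtein distance with a diagonal band of half-width k.
// Returns k+1 as soon as the true distance is known to exceed k.
// An 'N' never matches anything (an ambiguous base cannot certify identity).
// Caller supplies the two DP rows (hot loop: millions of calls).
static int bounded_lev_buf(const char* a, int n, const char* b, int m, int k,
                           std::vector<int>& prev, std::vector<int>& cur) {
  if (n - m > k || m - n > k) return k + 1;
  const int INF = k + 1;
  if ((int)prev.size() < m + 1) { prev.resize(m + 1); cur.resize(m + 1); }
  std::fill(prev.begin(), prev.begin() + m + 1, INF);
  for (int j = 0; j <= std::min(m, k); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.begin() + m + 1, INF);
    int lo = std::max(1, i - k), hi = std::min(m, i + k);
    int rowmin = INF;
    if (i <= k) { cur[0] = i; rowmin = i; }
    for (int j = lo; j <= hi; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      int cost = (ca == cb && ca != 'N') ? 0 : 1;
      int v = prev[j - 1] + cost;
      if (prev[j] + 1 < v) v = prev[j] + 1;
      if (cur[j - 1] + 1 < v) v = cur[j - 1] + 1;
      if (v > INF) v = INF;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin >= INF) return INF;
    std::swap(prev, cur);
  }
  return std::min(prev[m], INF);
}

static int bounded_lev(const char* a, int n, const char* b, int m, int k) {
  std::vector<int> prev, cur;
  return bounded_lev_buf(a, n, b, m, k, prev, cur);
}

// [[Rcpp::export]]
int cpp_bounded_levenshtein(std::string a, std::string b, int max_dist) {
  return bounded_lev(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(), max_dist);
}

// For each prefix, scan all candidates and report the minimal bounded
// distance, the (1-based) index of the minimal candidate, and whether the
// minimum is tied between two or more candidates. Distances greater than
// max_dist are reported as max_dist + 1 with index NA.
// [[Rcpp::export]]
IntegerMatrix cpp_match_prefixes(CharacterVector prefixes, CharacterVector candidates,
                                 int max_dist) {
  int np = prefixes.size(), nc = candidates.size();
  std::vector<std::string> cand(nc);
  for (int j = 0; j < nc; ++j) cand[j] = as<std::string>(candidates[j]);
  IntegerMatrix out(np, 3);
  colnames(out) = CharacterVector::create("dist", "index", "tie");
  std::vector<int> prev, cur;
  for (int i = 0; i < np; ++i) {
    std::string p = as<std::string>(prefixes[i]);
    int best = max_dist + 1, idx = NA_INTEGER, ties = 0;
    for (int j = 0; j < nc; ++j) {
      int d = (p == cand[j]) ? 0
        : bounded_lev_buf(p.c_str(), (int)p.size(), cand[j].c_str(),
                          (int)cand[j].size(), max_dist, prev, cur);
      if (d <= max_dist) {
        if (d < best) { best = d; idx = j + 1; ties = 1; }
        else if (d == best) { ++ties; }
      }
    }
    out(i, 0) = best;
    out(i, 1) = (best <= max_dist) ? idx : NA_INTEGER;
    out(i, 2) = (best <= max_dist && ties > 1) ? 1 : 0;
  }
  return out;
}

// All bounded distances of one prefix against every candidate.
// [[Rcpp::export]]
IntegerVector cpp_prefix_distances(std::string prefix, CharacterVector candidates,
                                   int max_dist) {
  int nc = candidates.size();
  IntegerVector out(nc);
  for (int j = 0; j < nc; ++j) {
    std::string c = as<std::string>(candidates[j]);
    out[j] = bounded_lev(prefix.c_str(), (int)prefix.size(), c.c_str(),
                         (int)c.size(), max_dist);
  }
  return out;
}

// First pair (1-based i, j) of windows closer than min_dist, else empty.
// [[Rcpp::export]]
IntegerVector cpp_check_separation(CharacterVector windows, int min_dist) {
  int n = windows.size(), k = min_dist - 1;
  std::vector<std::string> w(n);
  for (int i = 0; i < n; ++i) w[i] = as<std::string>(windows[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = bounded_lev(w[i].c_str(), (int)w[i].size(), w[j].c_str(),
                          (int)w[j].size(), k);
      if (d <= k) return IntegerVector::create(i + 1, j + 1);
    }
  }
  return IntegerVector(0);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return c;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) r[j] = comp_base(s[s.size() - 1 - j]);
    out[i] = r;
  }
  return out;
}

// Independent per-base substitution errors; uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector x, double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = x.size();
  if (error_rate <= 0) return clone(x);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < error_rate) {
        char orig = s[j];
        char sub;
        do {
          sub = bases[(int)(unif_rand() * 4) & 3];
        } while (sub == orig);
        s[j] = sub;
      }
    }
    out[i] = s;
  }
  return out;
}

// Element-wise Hamming distance between equal-length strings.
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  int n = a.size();
  if (b.size() != n) stop("hamming: vectors differ in length");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    if (x.size() != y.size()) stop("hamming: strings differ in length");
    int d = 0;
    for (size_t j = 0; j < x.size(); ++j) if (x[j] != y[j]) ++d;
    out[i] = d;
  }
  return out;
}
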