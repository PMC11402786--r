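#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Levenshtein distance, banded with a cap: returns min(d(a, b), cap + 1).
// Cells with |i - j| > cap cannot lie on a path of cost <= cap, so only the
// diagonal band is evaluated; rows whose band minimum exceeds the cap abandon
// early.  cap + 1 therefore means "greater than cap", not an exact distance.
// ---------------------------------------------------------------------------
static int lev_capped(const char *a, int n, const char *b, int m, int cap) {
  if (cap < 0) cap = 0;
  if (std::abs(n - m) > cap) return cap + 1;
  const int INF = cap + 1;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  for (int j = 0; j <= std::min(m, cap); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - cap), hi = std::min(m, i + cap);
    std::fill(cur.begin(), cur.end(), INF);
    if (i <= cap) cur[0] = i;
    int rowmin = cur[0];
    for (int j = lo; j <= hi; ++j) {
      int v = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
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

// [[Rcpp::export]]
IntegerVector cpp_edit_distance(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(a, i % a.size()));
    const char *sb = CHAR(STRING_ELT(b, i % b.size()));
    int la = (int)std::strlen(sa), lb = (int)std::strlen(sb);
    out[i] = lev_capped(sa, la, sb, lb, std::max(la, lb));
  }
  return out;
}

// Capped distance from every read to every reference; used by the classifier.
// Values equal the true distance when <= cap and cap + 1 otherwise, which is
// sufficient for the argmin + margin decision rule (cap >= max allowed
// distance + margin).
// [[Rcpp::export]]
IntegerMatrix cpp_distance_matrix(CharacterVector reads, CharacterVector refs,
                                  int cap) {
  int nr = (int)reads.size(), nf = (int)refs.size();
  IntegerMatrix out(nr, nf);
  std::vector<const char *> rf(nf);
  std::vector<int> rl(nf);
  for (int j = 0; j < nf; ++j) {
    rf[j] = CHAR(STRING_ELT(refs, j));
    rl[j] = (int)std::strlen(rf[j]);
  }
  for (int i = 0; i < nr; ++i) {
    const char *sr = CHAR(STRING_ELT(reads, i));
    int lr = (int)std::strlen(sr);
    for (int j = 0; j < nf; ++j)
      out(i, j) = lev_capped(sr, lr, rf[j], rl[j], cap);
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Anchored edit distance: align the whole pattern against text, optionally
// letting the alignment start (free_start) and/or end (free_end) anywhere in
// the text at no cost.  free_start + free_end gives infix search; free_end
// alone gives "pattern is an edited prefix of text".
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
int cpp_anchored_distance(std::string pattern, std::string text,
                          bool free_start, bool free_end) {
  int m = (int)pattern.size(), n = (int)text.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = free_start ? 0 : j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int v = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      if (prev[j] + 1 < v) v = prev[j] + 1;
      if (cur[j - 1] + 1 < v) v = cur[j - 1] + 1;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  if (free_end) return *std::min_element(prev.begin(), prev.end());
  return prev[n];
}

// ---------------------------------------------------------------------------
// Overlap-consensus merging of a read pair.  rev must already be
// reverse-complemented (amplicon orientation).  Scans overlap lengths from
// the longest candidate down and accepts the first whose mismatch fraction
// is within tolerance.  Consensus at overlap mismatches takes the forward
// base unless qualities are supplied and the reverse base is better.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector rev_rc,
                     int min_overlap, double max_mismatch_frac,
                     CharacterVector qual_fwd, CharacterVector qual_rev_rc) {
  int n = (int)fwd.size();
  bool use_qual = qual_fwd.size() == n && qual_rev_rc.size() == n;
  LogicalVector merged(n);
  CharacterVector seq(n);
  IntegerVector overlap(n), mism(n);
  for (int i = 0; i < n; ++i) {
    const char *f = CHAR(STRING_ELT(fwd, i));
    const char *r = CHAR(STRING_ELT(rev_rc, i));
    int nf = (int)std::strlen(f), nr = (int)std::strlen(r);
    int best_o = -1, best_mm = 0;
    for (int o = std::min(nf, nr); o >= min_overlap; --o) {
      int allowed = (int)std::floor(max_mismatch_frac * o + 1e-9);
      int mm = 0;
      const char *fs = f + nf - o;
      for (int k = 0; k < o; ++k) {
        if (fs[k] != r[k] && ++mm > allowed) break;
      }
      if (mm <= allowed) { best_o = o; best_mm = mm; break; }
    }
    if (best_o < 0) {
      merged[i] = false;
      seq[i] = NA_STRING;
      overlap[i] = NA_INTEGER;
      mism[i] = NA_INTEGER;
    } else {
      std::string s(f, nf);
      if (best_mm > 0 && use_qual) {
        const char *qf = CHAR(STRING_ELT(qual_fwd, i));
        const char *qr = CHAR(STRING_ELT(qual_rev_rc, i));
        if ((int)std::strlen(qf) == nf && (int)std::strlen(qr) == nr) {
          for (int k = 0; k < best_o; ++k) {
            int pf = nf - best_o + k;
            if (f[pf] != r[k] && qr[k] > qf[pf]) s[pf] = r[k];
          }
        }
      }
      s.append(r + best_o, nr - best_o);
      merged[i] = true;
      seq[i] = s;
      overlap[i] = best_o;
      mism[i] = best_mm;
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["merged"] = merged, _["sequence"] = seq,
                      _["overlap_len"] = overlap,
                      _["mismatches_in_overlap"] = mism);
}

// ---------------------------------------------------------------------------
// Maximum base-pair folding (Nussinov-style DP).  Allowed pairs: AU, UA, GC,
// CG, GU, UG (T treated as U); hairpin loops must contain >= min_loop
// unpaired bases.  Ties are broken deterministically in the traceback:
// leaving the rightmost base unpaired is preferred, otherwise the leftmost
// admissible partner is taken.
// ---------------------------------------------------------------------------
static inline bool can_pair(char x, char y) {
  if (x == 'T') x = 'U';
  if (y == 'T') y = 'U';
  return (x == 'A' && y == 'U') || (x == 'U' && y == 'A') ||
         (x == 'G' && y == 'C') || (x == 'C' && y == 'G') ||
         (x == 'G' && y == 'U') || (x == 'U' && y == 'G');
}

// [[Rcpp::export]]
std::string cpp_nussinov(std::string seq, int min_loop) {
  int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    char c = std::toupper(seq[i]);
    seq[i] = (c == 'T') ? 'U' : c;
  }
  if (n == 0) return std::string();
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int v = 1 + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) +
                (k > i ? M[i][k - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  std::string db(n, '.');
  // iterative traceback with explicit stack; prefer j unpaired, then
  // smallest partner k
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(seq[k], seq[j])) continue;
      int v = 1 + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) +
              (k > i ? M[i][k - 1] : 0);
      if (v == M[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return db;
}

// [[Rcpp::export]]
int cpp_max_pairs(std::string seq, int min_loop) {
  // pair count of the optimal structure (same DP, no traceback)
  int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    char c = std::toupper(seq[i]);
    seq[i] = (c == 'T') ? 'U' : c;
  }
  if (n == 0) return 0;
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len)
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k)
        if (can_pair(seq[k], seq[j])) {
          int v = 1 + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) +
                  (k > i ? M[i][k - 1] : 0);
          if (v > best) best = v;
        }
      M[i][j] = best;
    }
  return M[0][n - 1];
}

// ---------------------------------------------------------------------------
// Ordered tree edit distance (Zhang & Shasha), unit costs: insert 1,
// delete 1, relabel 1 when labels differ else 0.  Trees are passed as
// postorder label vectors plus, for each node, the postorder index of its
// leftmost leaf (both 1-based).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
int cpp_tree_edit_distance(IntegerVector lab1, IntegerVector lml1,
                           IntegerVector lab2, IntegerVector lml2) {
  int n1 = (int)lab1.size(), n2 = (int)lab2.size();
  if (n1 == 0) return n2;
  if (n2 == 0) return n1;
  // keyroots: nodes with no left sibling on their root path, i.e. the
  // highest node for each distinct leftmost-leaf value
  std::vector<int> kr1, kr2;
  {
    std::vector<char> seen(n1 + 1, 0);
    for (int i = n1; i >= 1; --i)
      if (!seen[lml1[i - 1]]) { seen[lml1[i - 1]] = 1; kr1.push_back(i); }
    std::sort(kr1.begin(), kr1.end());
    std::vector<char> seen2(n2 + 1, 0);
    for (int i = n2; i >= 1; --i)
      if (!seen2[lml2[i - 1]]) { seen2[lml2[i - 1]] = 1; kr2.push_back(i); }
    std::sort(kr2.begin(), kr2.end());
  }
  std::vector<std::vector<int> > td(n1 + 1, std::vector<int>(n2 + 1, 0));
  std::vector<std::vector<int> > fd(n1 + 2, std::vector<int>(n2 + 2, 0));
  for (size_t a = 0; a < kr1.size(); ++a) {
    int i = kr1[a], li = lml1[i - 1];
    for (size_t b = 0; b < kr2.size(); ++b) {
      int j = kr2[b], lj = lml2[j - 1];
      fd[li - 1][lj - 1] = 0;
      for (int di = li; di <= i; ++di) fd[di][lj - 1] = fd[di - 1][lj - 1] + 1;
      for (int dj = lj; dj <= j; ++dj) fd[li - 1][dj] = fd[li - 1][dj - 1] + 1;
      for (int di = li; di <= i; ++di) {
        for (int dj = lj; dj <= j; ++dj) {
          if (lml1[di - 1] == li && lml2[dj - 1] == lj) {
            int ren = (lab1[di - 1] == lab2[dj - 1]) ? 0 : 1;
            int v = fd[di - 1][dj - 1] + ren;
            if (fd[di - 1][dj] + 1 < v) v = fd[di - 1][dj] + 1;
            if (fd[di][dj - 1] + 1 < v) v = fd[di][dj - 1] + 1;
            fd[di][dj] = v;
            td[di][dj] = v;
          } else {
            int v = fd[lml1[di - 1] - 1][lml2[dj - 1] - 1] + td[di][dj];
            if (fd[di - 1][dj] + 1 < v) v = fd[di - 1][dj] + 1;
            if (fd[di][dj - 1] + 1 < v) v = fd[di][dj - 1] + 1;
            fd[di][dj] = v;
          }
        }
      }
    }
  }
  return td[n1][n2];
}

// ---------------------------------------------------------------------------
// Per-base substitution errors using R's RNG (reproducible under set.seed).
// Each base mutates independently with probability error_rate to one of the
// three other bases of the read alphabet.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
CharacterVector cpp_apply_substitutions(CharacterVector seqs,
                                        double error_rate,
                                        std::string alphabet) {
  int n = (int)seqs.size();
  int na = (int)alphabet.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < error_rate) {
        // pick uniformly among the alphabet letters other than the current
        int cur = -1;
        for (int q = 0; q < na; ++q)
          if (alphabet[q] == s[p]) { cur = q; break; }
        int pick = (int)std::floor(unif_rand() * (cur >= 0 ? na - 1 : na));
        if (cur >= 0 && pick >= cur) ++pick;
        s[p] = alphabet[pick % na];
      }
    }
    out[i] = s;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
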