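#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else = 4 (N; never matches).
static inline int code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = code(s[i]);
  return v;
}

static inline int subscore(int a, int b, int match, int mismatch) {
  return (a == b && a < 4) ? match : mismatch;
}

// Smith-Waterman score-only scan with linear gap penalty.
// Returns, for each subject position j (1-based column), the best score of a
// local alignment ending at that subject position. Memory is O(query length),
// so the scan runs over whole contigs.
// [[Rcpp::export]]
IntegerVector cpp_colmax(std::string query, std::string subject,
                         int match, int mismatch, int gap) {
  std::vector<int> q = encode(query), s = encode(subject);
  const int n = (int)q.size(), m = (int)s.size();
  IntegerVector colmax(m);
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int j = 1; j <= m; ++j) {
    int best = 0;
    const int sj = s[j - 1];
    cur[0] = 0;
    for (int i = 1; i <= n; ++i) {
      int h = prev[i - 1] + subscore(q[i - 1], sj, match, mismatch);
      int up = cur[i - 1] + gap;   // gap in subject
      int left = prev[i] + gap;    // gap in query
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      cur[i] = h;
      if (h > best) best = h;
    }
    colmax[j - 1] = best;
    std::swap(prev, cur);
  }
  return colmax;
}

// Full Smith-Waterman on a window with traceback and greedy extraction of
// non-overlapping (in the subject) local alignments. After each extraction
// the spanned subject columns are masked (forced to score 0) and the DP is
// recomputed, until no cell reaches min_score. Ties are broken toward the
// smallest subject end, then the smallest query end. Traceback prefers
// diagonal over subject-gap over query-gap moves.
// [[Rcpp::export]]
DataFrame cpp_sw_hits(std::string query, std::string subject,
                      int match, int mismatch, int gap, int min_score,
                      int max_hits = 1000000) {
  std::vector<int> q = encode(query), s = encode(subject);
  const int n = (int)q.size(), m = (int)s.size();
  if ((double)(n + 1) * (double)(m + 1) > 6e7)
    stop("alignment window too large (%d x %d)", n, m);
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<char> masked(m + 1, 0);
  auto at = [&](int i, int j) -> int& { return H[(size_t)i * (m + 1) + j]; };

  std::vector<int> r_score, r_qs, r_qe, r_ss, r_se, r_match, r_len;

  for (int iter = 0; iter < max_hits; ++iter) {
    // (re)compute DP with masked subject columns forced to zero
    int best = 0, bi = 0, bj = 0;
    for (int j = 1; j <= m; ++j) {
      if (masked[j]) {
        for (int i = 1; i <= n; ++i) at(i, j) = 0;
        continue;
      }
      const int sj = s[j - 1];
      for (int i = 1; i <= n; ++i) {
        int h = at(i - 1, j - 1) + subscore(q[i - 1], sj, match, mismatch);
        int up = at(i - 1, j) + gap;
        int left = at(i, j - 1) + gap;
        if (up > h) h = up;
        if (left > h) h = left;
        if (h < 0) h = 0;
        at(i, j) = h;
        if (h > best || (h == best && best > 0 && (j < bj || (j == bj && i < bi)))) {
          best = h; bi = i; bj = j;
        }
      }
    }
    if (best < min_score || best <= 0) break;
    // traceback from (bi, bj)
    int i = bi, j = bj, nm = 0, len = 0;
    while (i > 0 && j > 0 && at(i, j) > 0) {
      int h = at(i, j);
      int diag = at(i - 1, j - 1) + subscore(q[i - 1], s[j - 1], match, mismatch);
      if (h == diag) {
        if (subscore(q[i - 1], s[j - 1], match, mismatch) == match) ++nm;
        --i; --j; ++len;
      } else if (h == at(i - 1, j) + gap) {
        --i; ++len;
      } else {
        --j; ++len;
      }
    }
    r_score.push_back(best);
    r_qs.push_back(i + 1); r_qe.push_back(bi);
    r_ss.push_back(j + 1); r_se.push_back(bj);
    r_match.push_back(nm); r_len.push_back(len);
    for (int jj = j + 1; jj <= bj; ++jj) masked[jj] = 1;
  }
  return DataFrame::create(
    _["score"] = r_score,
    _["q_start"] = r_qs, _["q_end"] = r_qe,
    _["s_start"] = r_ss, _["s_end"] = r_se,
    _["matches"] = r_match, _["aln_len"] = r_len);
}
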