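#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).  A gap of length
// L scores gap_open + L * gap_extend (BLASTN-style existence/extension).
//
// Deterministic tie-breaks, mirrored by the plain-R oracle in the test suite:
//  * best end cell: highest score, then smaller query end, then smaller
//    subject end, then state preference M > X > Y;
//  * diagonal predecessor: M > X > Y > local start when tied;
//  * gap predecessor: open (from M) preferred over extend when tied.
// X consumes a query base (gap in the subject), Y consumes a subject base.
// Predecessors are re-derived from the score matrices during traceback with
// exactly these preference orders, so no pointer matrices are stored.

struct AlnResult {
  int score;
  int q_start, q_end, s_start, s_end;  // 1-based, 0 when alignment is empty
  int matches, columns;
};

static const int NEG_INF = INT_MIN / 4;

static AlnResult sw_core(const std::string& q, const std::string& s,
                         int match, int mismatch, int gap_open, int gap_extend,
                         std::vector<int>& M, std::vector<int>& X,
                         std::vector<int>& Y) {
  const int n = (int)q.size(), m = (int)s.size();
  const int W = m + 1;
  const size_t need = (size_t)(n + 1) * (size_t)W;
  if (M.size() < need) { M.resize(need); X.resize(need); Y.resize(need); }
  const int go = gap_open + gap_extend, ge = gap_extend;
  for (int j = 0; j <= m; ++j) { M[j] = X[j] = Y[j] = NEG_INF; }
  int best = 0, bi = 0, bj = 0, bst = 0;
  for (int i = 1; i <= n; ++i) {
    int* Mr = &M[(size_t)i * W]; int* Xr = &X[(size_t)i * W];
    int* Yr = &Y[(size_t)i * W];
    const int* Mp = Mr - W; const int* Xp = Xr - W; const int* Yp = Yr - W;
    Mr[0] = Xr[0] = Yr[0] = NEG_INF;
    const char qc = q[i - 1];
    int m_left = NEG_INF, y_left = NEG_INF;  // Mr[j-1], Yr[j-1]
    for (int j = 1; j <= m; ++j) {
      const int sub = (qc == s[j - 1]) ? match : mismatch;
      int db = Mp[j - 1];
      if (Xp[j - 1] > db) db = Xp[j - 1];
      if (Yp[j - 1] > db) db = Yp[j - 1];
      if (0 > db) db = 0;
      const int mv = db + sub;
      const int xo = Mp[j] + go, xe = Xp[j] + ge;
      const int xv = (xo >= xe) ? xo : xe;
      const int yo = m_left + go, ye = y_left + ge;
      const int yv = (yo >= ye) ? yo : ye;
      Mr[j] = mv; Xr[j] = xv; Yr[j] = yv;
      m_left = mv; y_left = yv;
      int v = mv, st = 1;
      if (xv > v) { v = xv; st = 2; }
      if (yv > v) { v = yv; st = 3; }
      if (v > best) { best = v; bi = i; bj = j; bst = st; }
    }
  }
  AlnResult r; r.score = best; r.matches = 0; r.columns = 0;
  r.q_start = r.q_end = r.s_start = r.s_end = 0;
  if (best <= 0) { r.score = 0; return r; }
  r.q_end = bi; r.s_end = bj;
  int i = bi, j = bj, st = bst;
  for (;;) {
    const int* Mr = &M[(size_t)i * W]; const int* Xr = &X[(size_t)i * W];
    const int* Yr = &Y[(size_t)i * W];
    const int* Mp = Mr - W; const int* Xp = Xr - W; const int* Yp = Yr - W;
    if (st == 1) {
      ++r.columns;
      if (q[i - 1] == s[j - 1]) ++r.matches;
      const int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      const int db = Mr[j] - sub;
      int p;
      if (db == Mp[j - 1]) p = 1;
      else if (db == Xp[j - 1]) p = 2;
      else if (db == Yp[j - 1]) p = 3;
      else p = 0;  // db == 0: local start
      --i; --j;
      if (p == 0) { r.q_start = i + 1; r.s_start = j + 1; break; }
      st = p;
    } else if (st == 2) {
      ++r.columns;
      st = (Xr[j] == Mp[j] + go) ? 1 : 2;
      --i;
    } else {
      ++r.columns;
      st = (Yr[j] == Mr[j - 1] + go) ? 1 : 3;
      --j;
    }
  }
  return r;
}

static List result_to_list(const AlnResult& r, int qlen) {
  const double identity = (r.columns > 0) ? 100.0 * r.matches / r.columns : 0.0;
  const double coverage = (r.score > 0)
      ? 100.0 * (r.q_end - r.q_start + 1) / (double)qlen : 0.0;
  return List::create(
      _["score"] = r.score, _["q_start"] = r.q_start, _["q_end"] = r.q_end,
      _["s_start"] = r.s_start, _["s_end"] = r.s_end,
      _["matches"] = r.matches, _["columns"] = r.columns,
      _["identity"] = identity, _["coverage"] = coverage);
}

// [[Rcpp::export(name = ".sw_pair_cpp")]]
List sw_pair_cpp(std::string query, std::string subject,
                 int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<int> M, X, Y;
  AlnResult r = sw_core(query, subject, match, mismatch, gap_open, gap_extend,
                        M, X, Y);
  return result_to_list(r, (int)query.size());
}

// [[Rcpp::export(name = ".sw_batch_cpp")]]
List sw_batch_cpp(CharacterVector queries, CharacterVector subjects,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int nq = queries.size(), ns = subjects.size();
  NumericMatrix score(nq, ns), identity(nq, ns), coverage(nq, ns);
  std::vector<std::string> subj(ns);
  for (int j = 0; j < ns; ++j) subj[j] = as<std::string>(subjects[j]);
  std::vector<int> M, X, Y;
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < ns; ++j) {
      AlnResult r = sw_core(q, subj[j], match, mismatch, gap_open, gap_extend,
                            M, X, Y);
      score(i, j) = r.score;
      identity(i, j) = (r.columns > 0) ? 100.0 * r.matches / r.columns : 0.0;
      coverage(i, j) = (r.score > 0)
          ? 100.0 * (r.q_end - r.q_start + 1) / (double)q.size() : 0.0;
    }
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["identity"] = identity,
                      _["coverage"] = coverage);
}
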