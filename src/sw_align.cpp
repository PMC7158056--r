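#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// Gap of length L costs gap_open + L * gap_extend (BLAST 11/1 convention).
// a, b: 0-based integer codes indexing rows/cols of sub.
// Tie-breaks: best cell chosen as the earliest maximum in row-major order
// over (i, j); traceback prefers diagonal > up (gap in b) > left (gap in a).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  const int m = a.size(), n = b.size();
  const int gfirst = gap_open + gap_extend;  // cost of the first gap residue
  const int NEG = INT_MIN / 4;

  // full matrices so the traceback can re-derive decisions
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);  // gap in a (left moves)
  std::vector<int> F((m + 1) * (n + 1), NEG);  // gap in b (up moves)
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[idx(i, j - 1)] - gfirst, E[idx(i, j - 1)] - gap_extend);
      int f = std::max(H[idx(i - 1, j)] - gfirst, F[idx(i - 1, j)] - gap_extend);
      int d = H[idx(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }  // strict > keeps earliest
    }
  }

  int identities = 0, aln_len = 0;
  int ai0 = bi, bj0 = bj;  // 0-based start of spans (half-open [start, end))
  if (best > 0) {
    int i = bi, j = bj;
    char state = 'H';
    while (true) {
      if (state == 'H') {
        int h = H[idx(i, j)];
        if (h == 0) break;
        int d = H[idx(i - 1, j - 1)] + sub(a[i - 1], b[j - 1]);
        if (i > 0 && j > 0 && h == d) {
          ++aln_len;
          if (a[i - 1] == b[j - 1]) ++identities;
          --i; --j;
        } else if (h == F[idx(i, j)]) {
          state = 'F';
        } else {
          state = 'E';
        }
      } else if (state == 'F') {  // consume a[i-1] against a gap
        ++aln_len;
        int f = F[idx(i, j)];
        bool open = (f == H[idx(i - 1, j)] - gfirst);
        --i;
        if (open) state = 'H';
      } else {  // 'E': consume b[j-1] against a gap
        ++aln_len;
        int e = E[idx(i, j)];
        bool open = (e == H[idx(i, j - 1)] - gfirst);
        --j;
        if (open) state = 'H';
      }
    }
    ai0 = i; bj0 = j;
  }

  return List::create(
    _["score"] = best,
    _["aligned_length"] = aln_len,
    _["identities"] = identities,
    _["query_start"] = ai0, _["query_end"] = (best > 0) ? bi : ai0,
    _["subject_start"] = bj0, _["subject_end"] = (best > 0) ? bj : bj0);
}
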