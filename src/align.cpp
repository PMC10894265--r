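#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global affine-gap aligner (Needleman-Wunsch, three-state Gotoh).
// Gap of length k scores gap_open + (k - 1) * gap_extend.
// Traceback tie-break: diagonal first, then gap in the reference row
// (read insertion), then gap in the read row (deletion). Deterministic.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List cpp_affine_align(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = read.size();   // rows
  const int m = ref.size();    // cols
  // state 0 = M (diagonal), 1 = GQ (gap in ref row, read base consumed),
  // state 2 = GR (gap in read row, ref base consumed)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GQ((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GR((n + 1) * (m + 1), NEG_INF);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j)
    GR[idx(0, j)] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i)
    GQ[idx(i, 0)] = gap_open + (i - 1) * gap_extend;

  // NEG_INF entries stay effectively -inf under finite additions, so no
  // reachability guards are needed in the recurrences.
  for (int i = 1; i <= n; ++i) {
    const char ri = read[i - 1];
    const double *Mp = &M[idx(i - 1, 0)], *Qp = &GQ[idx(i - 1, 0)],
                 *Rp = &GR[idx(i - 1, 0)];
    double *Mc = &M[idx(i, 0)], *Qc = &GQ[idx(i, 0)],
           *Rc = &GR[idx(i, 0)];
    for (int j = 1; j <= m; ++j) {
      const double s = (ri == ref[j - 1]) ? match : mismatch;
      // M: best predecessor in preference order M > GQ > GR
      Mc[j] = std::max(Mp[j - 1], std::max(Qp[j - 1], Rp[j - 1])) + s;
      // GQ: consume read base, gap char in ref row
      Qc[j] = std::max(Mp[j] + gap_open,
                       std::max(Qp[j] + gap_extend, Rp[j] + gap_open));
      // GR: consume ref base, gap char in read row
      Rc[j] = std::max(Mc[j - 1] + gap_open,
                       std::max(Rc[j - 1] + gap_extend,
                                Qc[j - 1] + gap_open));
    }
  }

  // terminal state, preference M > GQ > GR on ties
  int state = 0;
  double score = M[idx(n, m)];
  if (GQ[idx(n, m)] > score) { score = GQ[idx(n, m)]; state = 1; }
  if (GR[idx(n, m)] > score) { score = GR[idx(n, m)]; state = 2; }

  std::string ra, fa;  // reversed aligned read / ref
  ra.reserve(n + m); fa.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error in M state");
      const double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      const double need = M[idx(i, j)] - s;
      ra.push_back(read[i - 1]); fa.push_back(ref[j - 1]);
      --i; --j;
      if (std::abs(M[idx(i, j)] - need) < eps) state = 0;
      else if (std::abs(GQ[idx(i, j)] - need) < eps) state = 1;
      else state = 2;
      if (i == 0 && j == 0) break;
    } else if (state == 1) {  // gap in ref row: read base consumed
      if (i == 0) stop("traceback error in GQ state");
      const double cur = GQ[idx(i, j)];
      ra.push_back(read[i - 1]); fa.push_back('-');
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M[idx(i, j)] + gap_open - cur) < eps) state = 0;
      else if (std::abs(GQ[idx(i, j)] + gap_extend - cur) < eps) state = 1;
      else state = 2;
    } else {  // gap in read row: ref base consumed
      if (j == 0) stop("traceback error in GR state");
      const double cur = GR[idx(i, j)];
      ra.push_back('-'); fa.push_back(ref[j - 1]);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[idx(i, j)] + gap_open - cur) < eps) state = 0;
      else if (std::abs(GR[idx(i, j)] + gap_extend - cur) < eps) state = 2;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(fa.begin(), fa.end());
  return List::create(_["score"] = score,
                      _["read_aln"] = ra,
                      _["ref_aln"] = fa);
}

// Mismatch count of the length-L suffix of a against the length-L prefix
// of b, for every candidate overlap length L in [min_overlap, min(|a|,|b|)].
// [[Rcpp::export]]
IntegerMatrix cpp_overlap_scan(std::string a, std::string b, int min_overlap) {
  const int na = a.size(), nb = b.size();
  const int lmax = std::min(na, nb);
  if (lmax < min_overlap) return IntegerMatrix(0, 2);
  IntegerMatrix out(lmax - min_overlap + 1, 2);
  int row = 0;
  for (int L = min_overlap; L <= lmax; ++L, ++row) {
    int mm = 0;
    const int off = na - L;
    for (int k = 0; k < L; ++k)
      if (a[off + k] != b[k]) ++mm;
    out(row, 0) = L;
    out(row, 1) = mm;
  }
  return out;
}
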