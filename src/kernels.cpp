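#include <Rcpp.h>
using namespace Rcpp;

// Pairwise clamped weighted peptide similarity.
// Q: nq x L query windows, R: np x L reference windows, both 1-based indices
// into the 22-symbol alphabet. M: 22 x 22 substitution scores (query residue
// indexes rows, reference residue indexes columns). w: length-L position
// weights. Each pair score is sum_i w[i] * M[Q(q,i), R(p,i)], clamped to 0.
// [[Rcpp::export]]
NumericMatrix score_pairs_cpp(IntegerMatrix Q, IntegerMatrix R,
                              NumericMatrix M, NumericVector w) {
  const int nq = Q.nrow(), np = R.nrow(), L = Q.ncol();
  if (R.ncol() != L || w.size() != L)
    stop("window length mismatch between queries, references and weights");
  NumericMatrix S(nq, np);
  for (int p = 0; p < np; ++p) {
    for (int q = 0; q < nq; ++q) {
      double s = 0.0;
      for (int i = 0; i < L; ++i)
        s += w[i] * M(Q(q, i) - 1, R(p, i) - 1);
      S(q, p) = s > 0.0 ? s : 0.0;
    }
  }
  return S;
}

// Model scores: row means of the clamped pair-score matrix, with optional
// per-query exclusion of one reference (leave-one-out by origin identity).
// exclude: length-nq, 1-based reference index to skip, or 0 for none.
// [[Rcpp::export]]
NumericVector model_scores_cpp(IntegerMatrix Q, IntegerMatrix R,
                               NumericMatrix M, NumericVector w,
                               IntegerVector exclude) {
  const int nq = Q.nrow(), np = R.nrow(), L = Q.ncol();
  if (exclude.size() != nq) stop("exclude must have one entry per query");
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const int ex = exclude[q];
    double total = 0.0;
    int used = 0;
    for (int p = 0; p < np; ++p) {
      if (p + 1 == ex) continue;
      double s = 0.0;
      for (int i = 0; i < L; ++i)
        s += w[i] * M(Q(q, i) - 1, R(p, i) - 1);
      total += (s > 0.0 ? s : 0.0);
      ++used;
    }
    if (used == 0) stop("no reference peptides left after exclusion");
    out[q] = total / used;
  }
  return out;
}

// Per-position contribution stack: out[q + nq*p + nq*np*i] = M(Q(q,i), R(p,i)).
// Lets the weight-training loop update pair scores incrementally when a
// single position weight changes.
// [[Rcpp::export]]
NumericVector position_contrib_cpp(IntegerMatrix Q, IntegerMatrix R,
                                   NumericMatrix M) {
  const int nq = Q.nrow(), np = R.nrow(), L = Q.ncol();
  NumericVector out(static_cast<R_xlen_t>(nq) * np * L);
  R_xlen_t k = 0;
  for (int i = 0; i < L; ++i)
    for (int p = 0; p < np; ++p)
      for (int q = 0; q < nq; ++q)
        out[k++] = M(Q(q, i) - 1, R(p, i) - 1);
  out.attr("dim") = IntegerVector::create(nq, np, L);
  return out;
}

// Weighted sum of contribution slices: S_raw = sum_i w[i] * C[,,i]
// [[Rcpp::export]]
NumericMatrix weighted_contrib_sum_cpp(NumericVector C, NumericVector w) {
  IntegerVector dim = C.attr("dim");
  const int nq = dim[0], np = dim[1], L = dim[2];
  if (w.size() != L) stop("weight length mismatch");
  NumericMatrix S(nq, np);
  const R_xlen_t slice = static_cast<R_xlen_t>(nq) * np;
  for (int i = 0; i < L; ++i) {
    const double wi = w[i];
    if (wi == 0.0) continue;
    const double *src = &C[slice * i];
    double *dst = &S[0];
    for (R_xlen_t k = 0; k < slice; ++k) dst[k] += wi * src[k];
  }
  return S;
}

// Add delta * C[,,i] to S_raw (returns a new matrix, input untouched).
// [[Rcpp::export]]
NumericMatrix add_contrib_cpp(NumericMatrix S, NumericVector C, int i,
                              double delta) {
  IntegerVector dim = C.attr("dim");
  const int nq = dim[0], np = dim[1];
  if (S.nrow() != nq || S.ncol() != np) stop("dimension mismatch");
  NumericMatrix out(nq, np);
  const R_xlen_t slice = static_cast<R_xlen_t>(nq) * np;
  const double *src = &C[slice * (i - 1)];
  for (R_xlen_t k = 0; k < slice; ++k) out[k] = S[k] + delta * src[k];
  return out;
}

// Clamp raw pair sums at 0 and average per query, skipping one excluded
// reference per query (0 = none).
// [[Rcpp::export]]
NumericVector clamped_rowmeans_cpp(NumericMatrix S, IntegerVector exclude) {
  const int nq = S.nrow(), np = S.ncol();
  if (exclude.size() != nq) stop("exclude must have one entry per query");
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const int ex = exclude[q];
    double total = 0.0;
    int used = 0;
    for (int p = 0; p < np; ++p) {
      if (p + 1 == ex) continue;
      const double s = S(q, p);
      total += (s > 0.0 ? s : 0.0);
      ++used;
    }
    if (used == 0) stop("no reference peptides left after exclusion");
    out[q] = total / used;
  }
  return out;
}

// Model scores for every ASP(m, n) sub-window of full ASP(mmax, nmax)
// windows, using unit weights. Qf/Rf hold the full windows; column mmax
// (0-based) is the central lysine. Per pair, clamping is applied to each
// sub-window sum via upstream/downstream prefix sums before averaging.
// Returns an nq x (mmax * nmax) matrix; combo (m, n) is column
// (m - 1) * nmax + (n - 1) (1-based m, n).
// [[Rcpp::export]]
NumericMatrix length_scan_scores_cpp(IntegerMatrix Qf, IntegerMatrix Rf,
                                     NumericMatrix M, IntegerVector exclude,
                                     int mmax, int nmax) {
  const int nq = Qf.nrow(), np = Rf.nrow(), L = Qf.ncol();
  if (L != mmax + 1 + nmax) stop("full window length must be mmax + 1 + nmax");
  const int ncombo = mmax * nmax;
  NumericMatrix total(nq, ncombo);
  IntegerVector used(nq);
  std::vector<double> up(mmax + 1), down(nmax + 1);
  for (int q = 0; q < nq; ++q) {
    const int ex = exclude[q];
    int cnt = 0;
    for (int p = 0; p < np; ++p) {
      if (p + 1 == ex) continue;
      ++cnt;
      // prefix sums away from the center column
      up[0] = 0.0;
      for (int m = 1; m <= mmax; ++m)
        up[m] = up[m - 1] + M(Qf(q, mmax - m) - 1, Rf(p, mmax - m) - 1);
      down[0] = M(Qf(q, mmax) - 1, Rf(p, mmax) - 1);  // center included
      for (int n = 1; n <= nmax; ++n)
        down[n] = down[n - 1] + M(Qf(q, mmax + n) - 1, Rf(p, mmax + n) - 1);
      for (int m = 1; m <= mmax; ++m) {
        const double u = up[m];
        for (int n = 1; n <= nmax; ++n) {
          const double s = u + down[n];
          if (s > 0.0) total(q, (m - 1) * nmax + (n - 1)) += s;
        }
      }
    }
    used[q] = cnt;
  }
  for (int q = 0; q < nq; ++q) {
    if (used[q] == 0) stop("no reference peptides left after exclusion");
    for (int c = 0; c < ncombo; ++c) total(q, c) /= used[q];
  }
  return total;
}
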