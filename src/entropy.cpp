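#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in (maximum-likelihood) Shannon entropies of small column tuples.
//
// Symbols are 0-based integer codes < nsym. A tuple of k columns is folded
// into a single code per sequence (base-nsym positional encoding, k <= 4 so
// the code fits easily in a 32-bit int for nsym = 21). Counting uses a
// scratch array indexed by code; only the codes actually touched are visited
// and re-zeroed, so the cost per tuple is O(N), not O(nsym^k).

namespace {

// H in bits from the codes of one tuple; `counts` must be all-zero on entry
// and is restored to all-zero on exit.
double entropy_of_codes(const std::vector<int>& codes,
                        std::vector<int>& counts,
                        std::vector<int>& touched) {
  touched.clear();
  for (int c : codes) {
    if (counts[c]++ == 0) touched.push_back(c);
  }
  const double n = static_cast<double>(codes.size());
  double s = 0.0;
  for (int c : touched) {
    const double k = static_cast<double>(counts[c]);
    s += k * std::log2(k);
    counts[c] = 0;
  }
  return std::log2(n) - s / n;
}

// column-major copy of the 1-based R matrix into 0-based symbol vectors
std::vector<std::vector<int>> split_columns(const IntegerMatrix& mat) {
  const int n = mat.nrow(), L = mat.ncol();
  std::vector<std::vector<int>> cols(L, std::vector<int>(n));
  for (int j = 0; j < L; ++j)
    for (int r = 0; r < n; ++r)
      cols[j][r] = mat(r, j) - 1;
  return cols;
}

inline void fold2(const std::vector<int>& a, const std::vector<int>& b,
                  int nsym, std::vector<int>& out) {
  const int n = (int) a.size();
  for (int r = 0; r < n; ++r) out[r] = a[r] * nsym + b[r];
}

inline void fold_add(const std::vector<int>& base, const std::vector<int>& c,
                     int nsym, std::vector<int>& out) {
  const int n = (int) base.size();
  for (int r = 0; r < n; ++r) out[r] = base[r] * nsym + c[r];
}

inline long long comb2(long long x) { return x * (x - 1) / 2; }
inline long long comb3(long long x) { return x * (x - 1) * (x - 2) / 6; }

} // namespace

// [[Rcpp::export]]
double cpp_joint_entropy(const IntegerMatrix& mat, const IntegerVector& cols,
                         int nsym) {
  const int n = mat.nrow(), k = cols.size();
  int nstates = 1;
  for (int j = 0; j < k; ++j) nstates *= nsym;
  std::vector<int> codes(n), touched;
  std::vector<int> counts(nstates, 0);
  for (int r = 0; r < n; ++r) {
    int code = 0;
    for (int j = 0; j < k; ++j) code = code * nsym + (mat(r, cols[j] - 1) - 1);
    codes[r] = code;
  }
  return entropy_of_codes(codes, counts, touched);
}

// [[Rcpp::export]]
NumericVector cpp_h1(const IntegerMatrix& mat, int nsym) {
  const int L = mat.ncol();
  auto cols = split_columns(mat);
  std::vector<int> counts(nsym, 0), touched;
  NumericVector h1(L);
  for (int j = 0; j < L; ++j) h1[j] = entropy_of_codes(cols[j], counts, touched);
  return h1;
}

// full L x L matrix of pairwise joint entropies (diagonal = H1)
// [[Rcpp::export]]
NumericMatrix cpp_h2(const IntegerMatrix& mat, int nsym) {
  const int n = mat.nrow(), L = mat.ncol();
  auto cols = split_columns(mat);
  std::vector<int> counts((size_t) nsym * nsym, 0), touched, codes(n);
  NumericMatrix h2(L, L);
  std::vector<int> c1(nsym, 0);
  for (int i = 0; i < L; ++i)
    h2(i, i) = entropy_of_codes(cols[i], c1, touched);
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      fold2(cols[i], cols[j], nsym, codes);
      h2(i, j) = h2(j, i) = entropy_of_codes(codes, counts, touched);
    }
  }
  return h2;
}

// [[Rcpp::export]]
NumericMatrix cpp_map_2d(const IntegerMatrix& mat, int nsym) {
  const int L = mat.ncol();
  NumericMatrix h2 = cpp_h2(mat, nsym);
  NumericMatrix mi(L, L);
  std::fill(mi.begin(), mi.end(), NA_REAL);
  for (int i = 0; i < L; ++i)
    for (int j = i + 1; j < L; ++j)
      mi(i, j) = mi(j, i) = h2(i, i) + h2(j, j) - h2(i, j);
  return mi;
}

// 3D map: scores[i][j] = mean over k of
//   H(Xi,Xk) - H(Xi,Xk,Xj) - H(Xk) + H(Xk,Xj)
// One pass over ordered triples a < b < c; each triple contributes one
// conditional-MI term to each of its three pairs.
// [[Rcpp::export]]
NumericMatrix cpp_map_3d(const IntegerMatrix& mat, int nsym) {
  const int n = mat.nrow(), L = mat.ncol();
  auto cols = split_columns(mat);
  NumericMatrix h2 = cpp_h2(mat, nsym);
  std::vector<double> h1(L);
  for (int j = 0; j < L; ++j) h1[j] = h2(j, j);

  std::vector<int> counts((size_t) nsym * nsym * nsym, 0), touched;
  std::vector<int> cab(n), codes(n);
  NumericMatrix acc(L, L); // zero-initialised

  for (int a = 0; a < L; ++a) {
    for (int b = a + 1; b < L; ++b) {
      fold2(cols[a], cols[b], nsym, cab);
      for (int c = b + 1; c < L; ++c) {
        fold_add(cab, cols[c], nsym, codes);
        const double h3 = entropy_of_codes(codes, counts, touched);
        // pair (a,b), third = c
        acc(a, b) += h2(a, c) - h3 - h1[c] + h2(c, b);
        // pair (a,c), third = b
        acc(a, c) += h2(a, b) - h3 - h1[b] + h2(b, c);
        // pair (b,c), third = a
        acc(b, c) += h2(b, a) - h3 - h1[a] + h2(a, c);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix out(L, L);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double denom = L - 2;
  for (int i = 0; i < L; ++i)
    for (int j = i + 1; j < L; ++j)
      out(i, j) = out(j, i) = acc(i, j) / denom;
  return out;
}

// 4D map: scores[i][j] = mean over unordered {k,l} disjoint from {i,j} of
//   -H(Xk,Xl) + H(Xi,Xk,Xl) + H(Xj,Xk,Xl) - H(Xi,Xj,Xk,Xl)
// The summand is symmetric in (k,l) and the inner average over l has the
// same number of terms for every k, so the two-stage mean (over l, then k)
// equals the flat mean over unordered {k,l}.
// [[Rcpp::export]]
NumericMatrix cpp_map_4d(const IntegerMatrix& mat, int nsym) {
  const int n = mat.nrow(), L = mat.ncol();
  auto cols = split_columns(mat);
  NumericMatrix h2 = cpp_h2(mat, nsym);

  // all triple entropies, indexed by the combinatorial number system
  const long long ntrip = comb3(L);
  std::vector<double> h3((size_t) ntrip);
  {
    std::vector<int> counts((size_t) nsym * nsym * nsym, 0), touched;
    std::vector<int> cab(n), codes(n);
    for (int a = 0; a < L; ++a)
      for (int b = a + 1; b < L; ++b) {
        fold2(cols[a], cols[b], nsym, cab);
        for (int c = b + 1; c < L; ++c) {
          fold_add(cab, cols[c], nsym, codes);
          h3[(size_t)(comb3(c) + comb2(b) + a)] =
              entropy_of_codes(codes, counts, touched);
        }
      }
  }
  auto H3 = [&](int x, int y, int z) {
    int a = x, b = y, c = z; // sort the three indices
    if (a > b) std::swap(a, b);
    if (b > c) std::swap(b, c);
    if (a > b) std::swap(a, b);
    return h3[(size_t)(comb3(c) + comb2(b) + a)];
  };

  std::vector<int> counts((size_t) nsym * nsym * nsym * nsym, 0), touched;
  std::vector<int> cab(n), cabc(n), codes(n);
  NumericMatrix acc(L, L);

  for (int a = 0; a < L; ++a) {
    for (int b = a + 1; b < L; ++b) {
      fold2(cols[a], cols[b], nsym, cab);
      for (int c = b + 1; c < L; ++c) {
        fold_add(cab, cols[c], nsym, cabc);
        for (int d = c + 1; d < L; ++d) {
          fold_add(cabc, cols[d], nsym, codes);
          const double h4 = entropy_of_codes(codes, counts, touched);
          // the six pair / conditioning-set splits of {a,b,c,d}
          acc(a, b) += -h2(c, d) + H3(a, c, d) + H3(b, c, d) - h4;
          acc(a, c) += -h2(b, d) + H3(a, b, d) + H3(c, b, d) - h4;
          acc(a, d) += -h2(b, c) + H3(a, b, c) + H3(d, b, c) - h4;
          acc(b, c) += -h2(a, d) + H3(b, a, d) + H3(c, a, d) - h4;
          acc(b, d) += -h2(a, c) + H3(b, a, c) + H3(d, a, c) - h4;
          acc(c, d) += -h2(a, b) + H3(c, a, b) + H3(d, a, b) - h4;
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix out(L, L);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double denom = static_cast<double>(comb2(L - 2));
  for (int i = 0; i < L; ++i)
    for (int j = i + 1; j < L; ++j)
      out(i, j) = out(j, i) = acc(i, j) / denom;
  return out;
}
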