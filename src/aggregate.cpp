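// Neighborhood max-aggregation kernel for the GCN encoder.
// The graph is passed in CSR form over target nodes: indptr (length N+1)
// and indices (0-based source node ids). Representations are passed
// feature-major (d x N) so each node's feature vector is a contiguous
// column. Isolated nodes get the zero vector and argmax NA, matching the
// empty-neighborhood convention.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List neighbor_max_fwd(IntegerVector indptr, IntegerVector indices,
                      NumericMatrix Ht) {
  const int d = Ht.nrow();
  const int N = indptr.size() - 1;
  NumericMatrix Mt(d, N);
  IntegerMatrix amaxt(d, N);
  std::fill(amaxt.begin(), amaxt.end(), NA_INTEGER);
  for (int v = 0; v < N; ++v) {
    double *mv = &Mt(0, v);
    int *av = &amaxt(0, v);
    for (int e = indptr[v]; e < indptr[v + 1]; ++e) {
      const int u = indices[e];
      const double *hu = &Ht(0, u);
      if (av[0] == NA_INTEGER) {
        for (int f = 0; f < d; ++f) { mv[f] = hu[f]; av[f] = u; }
      } else {
        for (int f = 0; f < d; ++f) {
          if (hu[f] > mv[f]) { mv[f] = hu[f]; av[f] = u; }
        }
      }
    }
  }
  return List::create(_["max"] = Mt, _["amax"] = amaxt);
}

// Backward pass: route each d(out)/d(max) entry to its argmax source.
// [[Rcpp::export]]
NumericMatrix neighbor_max_bwd(IntegerMatrix amaxt, NumericMatrix dAt) {
  const int d = amaxt.nrow();
  const int N = amaxt.ncol();
  NumericMatrix dHt(d, N);
  for (int v = 0; v < N; ++v) {
    const int *av = &amaxt(0, v);
    const double *gv = &dAt(0, v);
    for (int f = 0; f < d; ++f) {
      const int u = av[f];
      if (u != NA_INTEGER) dHt(f, u) += gv[f];
    }
  }
  return dHt;
}
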