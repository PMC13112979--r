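// Parameter-tree utilities: gather the double-precision leaves of a nested
// list into one vector and write such a vector back, preserving structure
// and dim attributes. Traversal order matches the R-level walk (depth
// first, list order; only REALSXP leaves count).

#include <Rcpp.h>

using namespace Rcpp;

static void countLeaves(SEXP x, R_xlen_t& n) {
  if (TYPEOF(x) == REALSXP) n += Rf_xlength(x);
  else if (TYPEOF(x) == VECSXP) {
    const R_xlen_t m = Rf_xlength(x);
    for (R_xlen_t i = 0; i < m; ++i) countLeaves(VECTOR_ELT(x, i), n);
  }
}

static void gatherLeaves(SEXP x, double* out, R_xlen_t& pos) {
  if (TYPEOF(x) == REALSXP) {
    const R_xlen_t n = Rf_xlength(x);
    std::copy(REAL(x), REAL(x) + n, out + pos);
    pos += n;
  } else if (TYPEOF(x) == VECSXP) {
    const R_xlen_t m = Rf_xlength(x);
    for (R_xlen_t i = 0; i < m; ++i) gatherLeaves(VECTOR_ELT(x, i), out, pos);
  }
}

// [[Rcpp::export(name = ".treeGather")]]
NumericVector treeGather(SEXP tree) {
  R_xlen_t n = 0;
  countLeaves(tree, n);
  NumericVector out(n);
  R_xlen_t pos = 0;
  gatherLeaves(tree, out.begin(), pos);
  return out;
}

static SEXP scatterLeaves(SEXP x, const double* src, R_xlen_t& pos) {
  if (TYPEOF(x) == REALSXP) {
    const R_xlen_t n = Rf_xlength(x);
    SEXP leaf = PROTECT(Rf_duplicate(x));
    std::copy(src + pos, src + pos + n, REAL(leaf));
    pos += n;
    UNPROTECT(1);
    return leaf;
  }
  if (TYPEOF(x) == VECSXP) {
    const R_xlen_t m = Rf_xlength(x);
    SEXP out = PROTECT(Rf_shallow_duplicate(x));
    for (R_xlen_t i = 0; i < m; ++i)
      SET_VECTOR_ELT(out, i, scatterLeaves(VECTOR_ELT(x, i), src, pos));
    UNPROTECT(1);
    return out;
  }
  return x;
}

// [[Rcpp::export(name = ".treeScatter")]]
SEXP treeScatter(SEXP tree, NumericVector values) {
  R_xlen_t n = 0;
  countLeaves(tree, n);
  if (n != values.size()) stop("value vector does not match the tree");
  R_xlen_t pos = 0;
  return scatterLeaves(tree, values.begin(), pos);
}
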