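#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Density of z at each variant from its (already weighted) characteristic
// function sampled on a 1-D t-grid: f_j = sum_i W[pat_j, i] * cos(t_i * z_j).
// W rows are unique LD-neighbourhood patterns; pattern is a 0-based row index.
// [[Rcpp::export]]
NumericVector cpp_uni_density(const arma::mat& W, const arma::vec& tgrid,
                              const arma::vec& z, const IntegerVector& pattern) {
    const int m = z.n_elem, nt = tgrid.n_elem;
    NumericVector f(m);
    for (int j = 0; j < m; ++j) {
        const double* w = W.colptr(0) + pattern[j];  // row start (stride = n_rows)
        const int stride = W.n_rows;
        double acc = 0.0, zj = z[j];
        for (int i = 0; i < nt; ++i) acc += w[(size_t)i * stride] * std::cos(tgrid[i] * zj);
        f[j] = acc;
    }
    return f;
}

// 2-D analogue on a half-plane grid (t1 >= 0 doubled on the R side through the
// weights). W has one row per unique pattern and nt1*nt2 columns in
// column-major (i + l*nt1) layout. Uses cos(a+b) = cos a cos b - sin a sin b.
// [[Rcpp::export]]
NumericVector cpp_biv_density(const arma::mat& W, const arma::vec& t1, const arma::vec& t2,
                              const arma::vec& z1, const arma::vec& z2,
                              const IntegerVector& pattern) {
    const int m = z1.n_elem, nt1 = t1.n_elem, nt2 = t2.n_elem;
    NumericVector f(m);
    arma::vec c1(nt1), s1(nt1);
    for (int j = 0; j < m; ++j) {
        const double z1j = z1[j], z2j = z2[j];
        for (int i = 0; i < nt1; ++i) { c1[i] = std::cos(t1[i] * z1j); s1[i] = std::sin(t1[i] * z1j); }
        const int stride = W.n_rows;
        const double* w0 = W.colptr(0) + pattern[j];
        double acc = 0.0;
        for (int l = 0; l < nt2; ++l) {
            const double* w = w0 + (size_t)l * nt1 * stride;
            double u = 0.0, v = 0.0;
            for (int i = 0; i < nt1; ++i) {
                const double wv = w[(size_t)i * stride];
                u += wv * c1[i];
                v += wv * s1[i];
            }
            acc += u * std::cos(t2[l] * z2j) - v * std::sin(t2[l] * z2j);
        }
        f[j] = acc;
    }
    return f;
}

// Random pruning over a sparse symmetric correlation matrix in CSC triplet
// slots (p, i, x). Visit variants in the given 0-based order; keep a variant
// iff no already-kept variant correlates with it at r^2 > r2thresh.
// [[Rcpp::export]]
LogicalVector cpp_random_prune(const IntegerVector& p, const IntegerVector& i,
                               const NumericVector& x, const IntegerVector& order,
                               double r2thresh) {
    const int m = p.size() - 1;
    std::vector<bool> blocked(m, false), keep(m, false);
    for (int oi = 0; oi < order.size(); ++oi) {
        const int j = order[oi];
        if (blocked[j]) continue;
        keep[j] = true;
        for (int k = p[j]; k < p[j + 1]; ++k) {
            const int row = i[k];
            if (row != j && x[k] * x[k] > r2thresh) blocked[row] = true;
        }
    }
    LogicalVector out(m);
    for (int j = 0; j < m; ++j) out[j] = keep[j];
    return out;
}

// Greedy clumping: candOrder lists candidate variant indices (0-based), most
// significant first (ties pre-broken by position). Each unassigned candidate
// becomes a representative and absorbs unassigned candidates with
// r^2 >= r2thresh. Returns the 0-based representative index per variant
// (-1 for non-candidates).
// [[Rcpp::export]]
IntegerVector cpp_greedy_clump(const IntegerVector& p, const IntegerVector& i,
                               const NumericVector& x, const IntegerVector& candOrder,
                               const LogicalVector& isCand, double r2thresh) {
    const int m = p.size() - 1;
    IntegerVector repOf(m, -1);
    std::vector<bool> assigned(m, false);
    for (int oi = 0; oi < candOrder.size(); ++oi) {
        const int j = candOrder[oi];
        if (assigned[j]) continue;
        assigned[j] = true;
        repOf[j] = j;
        for (int k = p[j]; k < p[j + 1]; ++k) {
            const int row = i[k];
            if (!assigned[row] && isCand[row] && x[k] * x[k] >= r2thresh) {
                assigned[row] = true;
                repOf[row] = j;
            }
        }
    }
    return repOf;
}
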