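#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Weighted linear least-squares tensor fit on log-signals.
// logS: n_vol x n_vox matrix of log signal; X: n_vol x 7 design
// ([1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]).
// One OLS pass, then `reweight` passes with weights = squared predicted
// signal (exp(2 * X beta)), the usual WLS heuristic for log-linear fits.
// Returns 7 x n_vox coefficients.
// [[Rcpp::export]]
arma::mat cpp_wls_fit(const arma::mat& logS, const arma::mat& X, int reweight) {
  const arma::uword p = X.n_cols, V = logS.n_cols;
  arma::mat beta = arma::solve(X, logS);   // OLS, all voxels at once
  for (int it = 0; it < reweight; ++it) {
    for (arma::uword v = 0; v < V; ++v) {
      arma::vec w = arma::exp(2.0 * (X * beta.col(v)));
      arma::mat Xw = X.each_col() % w;
      arma::mat A = X.t() * Xw;            // X' W X
      arma::vec b = Xw.t() * logS.col(v);  // X' W y
      arma::vec sol;
      if (arma::solve(sol, A, b, arma::solve_opts::no_approx))
        beta.col(v) = sol;
      // else keep previous pass estimate for this voxel
    }
  }
  (void)p;
  return beta;
}

// Symmetric 3x3 eigendecomposition per voxel.
// D: 6 x n_vox, rows = (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) (lower-triangular order).
// Returns list: lambda (3 x n_vox, descending), vectors (9 x n_vox, columns
// of e1,e2,e3 stacked).
// [[Rcpp::export]]
List cpp_eig3(const arma::mat& D) {
  const arma::uword V = D.n_cols;
  arma::mat lam(3, V), vec(9, V);
  arma::mat33 M;
  arma::vec eval;
  arma::mat evec;
  for (arma::uword v = 0; v < V; ++v) {
    M(0,0) = D(0,v); M(0,1) = D(1,v); M(0,2) = D(3,v);
    M(1,0) = D(1,v); M(1,1) = D(2,v); M(1,2) = D(4,v);
    M(2,0) = D(3,v); M(2,1) = D(4,v); M(2,2) = D(5,v);
    arma::eig_sym(eval, evec, M);          // ascending
    for (int k = 0; k < 3; ++k) {
      lam(k, v) = eval(2 - k);
      vec(3*k + 0, v) = evec(0, 2 - k);
      vec(3*k + 1, v) = evec(1, 2 - k);
      vec(3*k + 2, v) = evec(2, 2 - k);
    }
  }
  return List::create(_["lambda"] = lam, _["vectors"] = vec);
}

// ---- TFCE on an arbitrary adjacency graph (the skeleton) ----------------
//
// values: statistic per node (one-sided: non-positive contributes nothing);
// indptr/indices: CSR adjacency (0-based);
// E, H: extent and height exponents; nsteps: number of threshold steps.
// dh = max(values)/nsteps, thresholds h = dh, 2dh, ..., max.
// At each h, connected clusters of {v : values_v >= h} are found by
// union-find and every member accrues extent^E * h^H * dh.

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector values, IntegerVector indptr,
                       IntegerVector indices, double E, double H, int nsteps) {
  const int V = values.size();
  NumericVector out(V);
  double vmax = 0.0;
  for (int i = 0; i < V; ++i) if (values[i] > vmax) vmax = values[i];
  if (vmax <= 0.0 || nsteps < 1) return out;
  const double dh = vmax / nsteps;

  std::vector<int> parent(V), size(V);
  std::vector<char> active(V);
  for (int s = 1; s <= nsteps; ++s) {
    const double h = dh * (s - 0.5);   // midpoint rule in h
    for (int i = 0; i < V; ++i) {
      active[i] = values[i] >= h;
      parent[i] = i; size[i] = 1;
    }
    for (int i = 0; i < V; ++i) {
      if (!active[i]) continue;
      for (int k = indptr[i]; k < indptr[i + 1]; ++k) {
        int j = indices[k];
        if (j <= i || !active[j]) continue;
        int ri = uf_find(parent, i), rj = uf_find(parent, j);
        if (ri != rj) {
          if (size[ri] < size[rj]) std::swap(ri, rj);
          parent[rj] = ri; size[ri] += size[rj];
        }
      }
    }
    const double hH = std::pow(h, H);
    for (int i = 0; i < V; ++i) {
      if (!active[i]) continue;
      int r = uf_find(parent, i);
      out[i] += std::pow((double)size[r], E) * hH * dh;
    }
  }
  return out;
}
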