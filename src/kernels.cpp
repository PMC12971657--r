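// Compiled hot paths: batched matrix products used by windowed attention and
// the selective state-space scan (forward + analytic reverse pass).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batched matrix multiply over the third dimension.
// A: (ra x ca x n), B: (rb x cb x n); transA/transB transpose each slice.
// [[Rcpp::export]]
arma::cube cpp_bmm(const arma::cube& A, const arma::cube& B,
                   const bool transA, const bool transB) {
  const arma::uword n = A.n_slices;
  if (B.n_slices != n) stop("cpp_bmm: slice count mismatch");
  const arma::uword r = transA ? A.n_cols : A.n_rows;
  const arma::uword kA = transA ? A.n_rows : A.n_cols;
  const arma::uword kB = transB ? B.n_cols : B.n_rows;
  const arma::uword c = transB ? B.n_rows : B.n_cols;
  if (kA != kB) stop("cpp_bmm: inner dimension mismatch");
  arma::cube out(r, c, n);
  for (arma::uword s = 0; s < n; ++s) {
    if (!transA && !transB)      out.slice(s) = A.slice(s) * B.slice(s);
    else if (!transA && transB)  out.slice(s) = A.slice(s) * B.slice(s).t();
    else if (transA && !transB)  out.slice(s) = A.slice(s).t() * B.slice(s);
    else                         out.slice(s) = A.slice(s).t() * B.slice(s).t();
  }
  return out;
}

// Selective scan (S6) forward.
//   x, delta: (C x L x B); Bm, Cm: (N x L x B); A: (C x N); D: length C.
// Recurrence per batch b, channel c, state n:
//   h_t = exp(delta_t * A) h_{t-1} + delta_t * B_t * x_t,  h_0 = 0
//   y_t = sum_n C_t[n] h_t[n] + D[c] x_t
// Returns y (C x L x B), the state trajectory H (N x C x L x B) for the
// backward pass, and a multiply-add count (linear in L).
// [[Rcpp::export]]
List cpp_sscan_fwd(const arma::cube& x, const arma::cube& delta,
                   const arma::cube& Bm, const arma::cube& Cm,
                   const arma::mat& A, const arma::vec& D) {
  const arma::uword C = x.n_rows, L = x.n_cols, Bn = x.n_slices;
  const arma::uword N = Bm.n_rows;
  if (delta.n_rows != C || delta.n_cols != L || delta.n_slices != Bn)
    stop("cpp_sscan_fwd: delta shape mismatch");
  if (Cm.n_rows != N || Bm.n_cols != L || Cm.n_cols != L)
    stop("cpp_sscan_fwd: B/C shape mismatch");
  if (A.n_rows != C || A.n_cols != N || D.n_elem != C)
    stop("cpp_sscan_fwd: A/D shape mismatch");

  arma::cube y(C, L, Bn, arma::fill::zeros);
  NumericVector Hout(N * C * L * Bn);
  double* Hp = REAL(Hout);
  arma::vec h(N);
  for (arma::uword b = 0; b < Bn; ++b) {
    for (arma::uword c = 0; c < C; ++c) {
      h.zeros();
      for (arma::uword t = 0; t < L; ++t) {
        const double dt = delta(c, t, b);
        const double xt = x(c, t, b);
        double acc = 0.0;
        const double dx = dt * xt;
        double* hslab = Hp + (size_t)N * (c + (size_t)C * (t + (size_t)L * b));
        for (arma::uword n = 0; n < N; ++n) {
          const double ab = std::exp(dt * A(c, n));
          const double hn = ab * h(n) + dx * Bm(n, t, b);
          h(n) = hn;
          hslab[n] = hn;
          acc += Cm(n, t, b) * hn;
        }
        y(c, t, b) = acc + D(c) * xt;
      }
    }
  }
  Hout.attr("dim") = IntegerVector::create((int)N, (int)C, (int)L, (int)Bn);
  // ~6 multiply-adds per (b, c, t, n) inner step plus the skip term
  const double ops = 6.0 * (double)Bn * (double)C * (double)L * (double)N +
                     2.0 * (double)Bn * (double)C * (double)L;
  return List::create(_["y"] = y, _["H"] = Hout, _["ops"] = ops);
}

// Selective scan backward. gy: (C x L x B) upstream gradient; H: trajectory
// from the forward pass. Returns gradients for x, delta, Bm, Cm, A, D.
// [[Rcpp::export]]
List cpp_sscan_bwd(const arma::cube& x, const arma::cube& delta,
                   const arma::cube& Bm, const arma::cube& Cm,
                   const arma::mat& A, const arma::vec& D,
                   const NumericVector& H, const arma::cube& gy) {
  const arma::uword C = x.n_rows, L = x.n_cols, Bn = x.n_slices;
  const arma::uword N = Bm.n_rows;
  const double* Hp = REAL(H);

  arma::cube gx(C, L, Bn, arma::fill::zeros);
  arma::cube gdelta(C, L, Bn, arma::fill::zeros);
  arma::cube gB(N, L, Bn, arma::fill::zeros);
  arma::cube gC(N, L, Bn, arma::fill::zeros);
  arma::mat gA(C, N, arma::fill::zeros);
  arma::vec gD(C, arma::fill::zeros);

  arma::vec gh(N);
  for (arma::uword b = 0; b < Bn; ++b) {
    for (arma::uword c = 0; c < C; ++c) {
      gh.zeros();
      for (arma::uword tt = L; tt-- > 0;) {
        const arma::uword t = tt;
        const double dt = delta(c, t, b);
        const double xt = x(c, t, b);
        const double gyv = gy(c, t, b);
        const double* hslab = Hp + (size_t)N * (c + (size_t)C * (t + (size_t)L * b));
        const double* hprev = (t > 0)
          ? Hp + (size_t)N * (c + (size_t)C * ((t - 1) + (size_t)L * b))
          : nullptr;
        gD(c) += gyv * xt;
        double gxv = D(c) * gyv;
        double gdt = 0.0;
        for (arma::uword n = 0; n < N; ++n) {
          double g = gh(n) + gyv * Cm(n, t, b);
          gC(n, t, b) += gyv * hslab[n];
          const double ab = std::exp(dt * A(c, n));
          const double hp = hprev ? hprev[n] : 0.0;
          const double bn = Bm(n, t, b);
          gA(c, n) += g * hp * dt * ab;
          gdt += g * (hp * A(c, n) * ab + bn * xt);
          gB(n, t, b) += g * dt * xt;
          gxv += g * dt * bn;
          gh(n) = g * ab; // propagate to t-1
        }
        gdelta(c, t, b) = gdt;
        gx(c, t, b) += gxv;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gdelta"] = gdelta, _["gB"] = gB,
                      _["gC"] = gC, _["gA"] = gA, _["gD"] = gD);
}
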