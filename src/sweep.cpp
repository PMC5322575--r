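#include <Rcpp.h>
using namespace Rcpp;

// Tolerance under which an edge crossing (omega . n) is treated as
// non-coupling; must match the tie tolerance of the upwind ordering.
static const double TIE_TOL = 1e-12;

// Solve a 3x3 linear system in place (partial pivoting).
static inline void solve3(double A[3][3], double b[3], double x[3]) {
  int piv[3] = {0, 1, 2};
  for (int c = 0; c < 2; ++c) {
    int p = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(A[piv[r]][c]) > std::fabs(A[piv[p]][c])) p = r;
    std::swap(piv[c], piv[p]);
    double d = A[piv[c]][c];
    for (int r = c + 1; r < 3; ++r) {
      double f = A[piv[r]][c] / d;
      for (int k = c; k < 3; ++k) A[piv[r]][k] -= f * A[piv[c]][k];
      b[piv[r]] -= f * b[piv[c]];
    }
  }
  x[2] = b[piv[2]] / A[piv[2]][2];
  x[1] = (b[piv[1]] - A[piv[1]][2] * x[2]) / A[piv[1]][1];
  x[0] = (b[piv[0]] - A[piv[0]][1] * x[1] - A[piv[0]][2] * x[2]) / A[piv[0]][0];
}

// One exact upwind-DG transport sweep: for every direction, solve
// (omega . grad + sigma_t) u = src with the given boundary inflow,
// visiting elements in upwind order so each local 3x3 solve only needs
// already-computed neighbour traces.
//
// src holds nodal source values (3N x n_dir); inflow holds boundary
// moments  integral_e g lambda_a ds  and  ... lambda_b ds  as rows
// (2*b-1, 2*b) of a (2*n_bedge) x n_dir matrix.
// [[Rcpp::export]]
NumericMatrix cpp_sweep(IntegerMatrix tri, NumericVector area,
                        NumericMatrix grad,
                        IntegerMatrix nb_el, IntegerMatrix nb_la,
                        IntegerMatrix nb_lb,
                        NumericMatrix elen, NumericMatrix nnx,
                        NumericMatrix nny, IntegerMatrix bid,
                        NumericMatrix dirs, IntegerMatrix order,
                        NumericVector sigma_t,
                        NumericMatrix src, NumericMatrix inflow) {
  const int N = tri.nrow();
  const int n_dir = dirs.nrow();
  NumericMatrix u(3 * N, n_dir);

  for (int p = 0; p < n_dir; ++p) {
    const double sx = dirs(p, 0), sy = dirs(p, 1);
    for (int idx = 0; idx < N; ++idx) {
      const int e = order(idx, p) - 1;
      const double ar = area[e];
      double A[3][3], rhs[3];
      // convection (integrated by parts) + attenuation mass term
      for (int i = 0; i < 3; ++i) {
        const double ci = -(grad(e, 2 * i) * sx + grad(e, 2 * i + 1) * sy) * ar / 3.0;
        for (int j = 0; j < 3; ++j) A[i][j] = ci;
      }
      const double mf = sigma_t[e] * ar / 12.0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) A[i][j] += (i == j) ? 2.0 * mf : mf;
      // source moments  M q
      const double q0 = src(3 * e, p), q1 = src(3 * e + 1, p), q2 = src(3 * e + 2, p);
      rhs[0] = ar / 12.0 * (2.0 * q0 + q1 + q2);
      rhs[1] = ar / 12.0 * (q0 + 2.0 * q1 + q2);
      rhs[2] = ar / 12.0 * (q0 + q1 + 2.0 * q2);
      // edge fluxes
      for (int l = 0; l < 3; ++l) {
        const int a = l, b = (l + 1) % 3;
        const double s = sx * nnx(e, l) + sy * nny(e, l);
        if (s > TIE_TOL) {           // outflow: upwind trace is ours
          const double f = s * elen(e, l) / 6.0;
          A[a][a] += 2.0 * f; A[a][b] += f;
          A[b][a] += f;       A[b][b] += 2.0 * f;
        } else if (s < -TIE_TOL) {   // inflow: neighbour or boundary data
          const double f = -s * elen(e, l) / 6.0;
          const int nb = nb_el(e, l);
          if (nb > 0) {
            const double ua = u(3 * (nb - 1) + nb_la(e, l) - 1, p);
            const double ub = u(3 * (nb - 1) + nb_lb(e, l) - 1, p);
            rhs[a] += f * (2.0 * ua + ub);
            rhs[b] += f * (ua + 2.0 * ub);
          } else {
            const int be = bid(e, l);
            rhs[a] += (-s) * inflow(2 * (be - 1), p);
            rhs[b] += (-s) * inflow(2 * be - 1, p);
          }
        }
      }
      double x[3];
      solve3(A, rhs, x);
      u(3 * e, p) = x[0]; u(3 * e + 1, p) = x[1]; u(3 * e + 2, p) = x[2];
    }
  }
  return u;
}

// Per-element angular inner product  sum_p w_p  u(:,p)' M_K phi(:,p)
// of two DG radiance fields (phi already direction-matched), used for
// the adjoint Jacobian columns:  column_k = -value_k.
// [[Rcpp::export]]
NumericVector cpp_field_product(NumericMatrix u, NumericMatrix phi,
                                NumericVector area, NumericVector w) {
  const int n_dir = u.ncol();
  const int N = u.nrow() / 3;
  NumericVector out(N);
  for (int p = 0; p < n_dir; ++p) {
    const double wp = w[p];
    for (int e = 0; e < N; ++e) {
      const double u0 = u(3 * e, p), u1 = u(3 * e + 1, p), u2 = u(3 * e + 2, p);
      const double f0 = phi(3 * e, p), f1 = phi(3 * e + 1, p), f2 = phi(3 * e + 2, p);
      // u' M phi with M = area/12 (I + ones)
      out[e] += wp * area[e] / 12.0 *
        (u0 * f0 + u1 * f1 + u2 * f2 + (u0 + u1 + u2) * (f0 + f1 + f2));
    }
  }
  return out;
}
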