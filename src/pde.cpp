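#include <Rcpp.h>
using namespace Rcpp;

// Explicit Euler advance of the reaction-diffusion system on an n x n grid
// with zero-flux (mirrored ghost cell) boundaries and a five-point Laplacian.
// Negative values are clipped to zero and counted. Fields are updated from a
// frozen copy each step (plain explicit Euler, no Gauss-Seidel sweep).
// [[Rcpp::export]]
List euler_advance_cpp(NumericMatrix x, NumericMatrix y,
                       double l, double beta, double a, double b, double d,
                       bool allee,
                       double d1, double d2, double h, double dt,
                       int nsteps) {
  const int n = x.nrow(), m = x.ncol();
  if (y.nrow() != n || y.ncol() != m)
    stop("prey and predator fields must have identical shape");
  // work on copies: never mutate the caller's matrices in place
  x = clone(x);
  y = clone(y);
  NumericMatrix xn(n, m), yn(n, m);
  const double ih2 = 1.0 / (h * h);
  long clip = 0;
  for (int s = 0; s < nsteps; ++s) {
    for (int j = 0; j < m; ++j) {
      const int jl = (j == 0) ? 0 : j - 1;
      const int jr = (j == m - 1) ? m - 1 : j + 1;
      for (int i = 0; i < n; ++i) {
        const int iu = (i == 0) ? 0 : i - 1;
        const int id = (i == n - 1) ? n - 1 : i + 1;
        const double u = x(i, j), v = y(i, j);
        const double lapx = (x(iu, j) + x(id, j) + x(i, jl) + x(i, jr)
                             - 4.0 * u) * ih2;
        const double lapy = (y(iu, j) + y(id, j) + y(i, jl) + y(i, jr)
                             - 4.0 * v) * ih2;
        const double pred = beta * u * v / ((1.0 + a * u) * (1.0 + b * v));
        const double growth = allee ? u * (1.0 - u) * (u - l)
                                    : u * (1.0 - u);
        double un = u + dt * (growth - pred + d1 * lapx);
        double vn = v + dt * (pred - d * v + d2 * lapy);
        if (un < 0.0) { un = 0.0; ++clip; }
        if (vn < 0.0) { vn = 0.0; ++clip; }
        if (!R_finite(un) || !R_finite(vn) || un > 1e6 || vn > 1e6)
          stop("numerical instability at step %d: field value not finite "
               "or exceeds 1e6", s + 1);
        xn(i, j) = un;
        yn(i, j) = vn;
      }
    }
    std::copy(xn.begin(), xn.end(), x.begin());
    std::copy(yn.begin(), yn.end(), y.begin());
  }
  return List::create(_["x"] = x, _["y"] = y, _["clipped"] = (double)clip);
}

// 4-connected component labelling of a logical mask (iterative flood fill).
// Returns an integer matrix of labels (0 outside the mask).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int n = mask.nrow(), m = mask.ncol();
  IntegerMatrix lab(n, m);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j0 = 0; j0 < m; ++j0)
    for (int i0 = 0; i0 < n; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.push_back(std::make_pair(i0, j0));
      lab(i0, j0) = next;
      while (!stack.empty()) {
        const int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int ii = i + di[k], jj = j + dj[k];
          if (ii < 0 || ii >= n || jj < 0 || jj >= m) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}
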