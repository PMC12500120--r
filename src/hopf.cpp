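#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of N coupled Stuart-Landau oscillators with
// diffusive coupling on both components. Noise uses R's RNG (norm_rand), so
// runs are reproducible under set.seed() on the R side.
//
// Per node i:
//   dx_i = [a_i x_i - r2_i x_i - w x_i_rot ... ] see R docs. The amplitude
//   term is (x^2 + y^2) for the supercritical Hopf normal form; the
//   "printed_bracket" flag switches to (x^2 - y^2) for auditing.
// [[Rcpp::export]]
List hopf_integrate_cpp(NumericMatrix M, NumericVector a, double omega,
                        double G, double gamma, double dt, int nsteps,
                        NumericVector x0, NumericVector y0,
                        bool printed_bracket) {
  const int N = M.ncol();
  NumericMatrix X(nsteps, N), Y(nsteps, N);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> rowsum(N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) rowsum[i] += M(i, j);
  const double sqdt = std::sqrt(dt);
  RNGScope scope;
  for (int t = 0; t < nsteps; ++t) {
    std::vector<double> mx(N, 0.0), my(N, 0.0);
    for (int i = 0; i < N; ++i) {
      double sx = 0.0, sy = 0.0;
      for (int j = 0; j < N; ++j) {
        sx += M(i, j) * x[j];
        sy += M(i, j) * y[j];
      }
      mx[i] = sx;
      my[i] = sy;
    }
    for (int i = 0; i < N; ++i) {
      const double xi = x[i], yi = y[i];
      const double amp = printed_bracket ? (xi * xi - yi * yi)
                                         : (xi * xi + yi * yi);
      const double cx = G * (mx[i] - rowsum[i] * xi);
      const double cy = G * (my[i] - rowsum[i] * yi);
      const double dx = (a[i] - amp) * xi - omega * yi + cx;
      const double dy = (a[i] - amp) * yi + omega * xi + cy;
      x[i] = xi + dt * dx + gamma * sqdt * norm_rand();
      y[i] = yi + dt * dy + gamma * sqdt * norm_rand();
      if (std::fabs(x[i]) > 1e6 || std::fabs(y[i]) > 1e6) {
        return List::create(_["diverged"] = true, _["step"] = t + 1);
      }
      X(t, i) = x[i];
      Y(t, i) = y[i];
    }
  }
  return List::create(_["diverged"] = false, _["x"] = X, _["y"] = Y);
}
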