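#include <Rcpp.h>
using namespace Rcpp;

// Euclidean distance matrix of an n x 2 configuration (symmetric fill)
static void plane_dist(const NumericMatrix& x, NumericMatrix& d) {
  int n = x.nrow();
  for (int i = 0; i < n; ++i) {
    d(i, i) = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1);
      double v = std::sqrt(dx * dx + dy * dy);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
}

static double raw_stress(const NumericMatrix& dx, const NumericMatrix& delta) {
  int n = dx.nrow();
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double e = dx(i, j) - delta(i, j);
      s += e * e;
    }
  return 2.0 * s; // sum over ordered pairs (2x the unordered sum)
}

// One SMACOF majorization run: Guttman-transform updates until the
// relative stress decrease falls below eps or max_iter is reached.
// [[Rcpp::export(name = ".smacof_engine")]]
List smacof_engine(NumericMatrix delta, NumericMatrix x0, int max_iter,
                   double eps) {
  int n = delta.nrow();
  NumericMatrix x = clone(x0);
  NumericMatrix dx(n, n);
  std::vector<double> nx(n), ny(n), diag(n);
  plane_dist(x, dx);
  double stress = raw_stress(dx, delta);
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    std::fill(nx.begin(), nx.end(), 0.0);
    std::fill(ny.begin(), ny.end(), 0.0);
    std::fill(diag.begin(), diag.end(), 0.0);
    // accumulate B(X) %*% X without forming B, using symmetry of b_ij
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double b = (dx(i, j) > 0.0) ? delta(i, j) / dx(i, j) : 0.0;
        diag[i] += b;
        diag[j] += b;
        nx[i] -= b * x(j, 0); ny[i] -= b * x(j, 1);
        nx[j] -= b * x(i, 0); ny[j] -= b * x(i, 1);
      }
    }
    for (int i = 0; i < n; ++i) {
      double xi = (nx[i] + diag[i] * x(i, 0)) / n;
      double yi = (ny[i] + diag[i] * x(i, 1)) / n;
      x(i, 0) = xi;
      x(i, 1) = yi;
    }
    plane_dist(x, dx);
    double new_stress = raw_stress(dx, delta);
    double drop = stress - new_stress;
    stress = new_stress;
    if (drop < eps * std::max(stress, 1e-300)) break;
  }
  return List::create(_["coords"] = x, _["stress"] = stress,
                      _["iterations"] = it + 1);
}
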