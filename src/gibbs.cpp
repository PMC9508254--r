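#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Count points of (xs, ys) within distance rg of (u, v), skipping index `skip`
// (pass -1 to count against all points).
static int n_close(const std::vector<double>& xs, const std::vector<double>& ys,
                   double u, double v, double rg2, int skip) {
  int m = 0;
  const int n = xs.size();
  for (int k = 0; k < n; ++k) {
    if (k == skip) continue;
    const double dx = xs[k] - u, dy = ys[k] - v;
    if (dx * dx + dy * dy < rg2) ++m;
  }
  return m;
}

// Birth-death Metropolis-Hastings for a pairwise-interaction (Strauss) process
// with activity beta and interaction gamma at range rg; gamma = 0 is the
// hard-core process. Uses R's RNG, so results are reproducible via set.seed().
// [[Rcpp::export]]
NumericMatrix gibbs_birth_death(NumericMatrix start,
                                double xmin, double xmax,
                                double ymin, double ymax,
                                double beta, double gamma, double rg,
                                int n_steps) {
  const double area = (xmax - xmin) * (ymax - ymin);
  const double rg2 = rg * rg;
  std::vector<double> xs, ys;
  xs.reserve(start.nrow() + 64);
  ys.reserve(start.nrow() + 64);
  for (int i = 0; i < start.nrow(); ++i) {
    xs.push_back(start(i, 0));
    ys.push_back(start(i, 1));
  }
  for (int step = 0; step < n_steps; ++step) {
    if (unif_rand() < 0.5) { // birth
      const double u = xmin + unif_rand() * (xmax - xmin);
      const double v = ymin + unif_rand() * (ymax - ymin);
      const int t = n_close(xs, ys, u, v, rg2, -1);
      double a;
      if (gamma == 0.0) {
        a = (t == 0) ? beta * area / (xs.size() + 1.0) : 0.0;
      } else {
        a = beta * area * std::pow(gamma, t) / (xs.size() + 1.0);
      }
      if (unif_rand() < a) {
        xs.push_back(u);
        ys.push_back(v);
      }
    } else if (!xs.empty()) { // death
      const int n = xs.size();
      const int i = std::min<int>(n - 1, (int)(unif_rand() * n));
      const int t = n_close(xs, ys, xs[i], ys[i], rg2, i);
      double a;
      if (gamma == 0.0) {
        // removing a point that violates the hard core is always favourable
        a = (t == 0) ? n / (beta * area) : 2.0;
      } else {
        a = n / (beta * area * std::pow(gamma, t));
      }
      if (unif_rand() < a) {
        xs[i] = xs.back();
        ys[i] = ys.back();
        xs.pop_back();
        ys.pop_back();
      }
    }
  }
  NumericMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
  }
  return out;
}

// Fixed-n relocation chain: each step removes a uniformly chosen point and
// proposes a uniform replacement, accepted with the Metropolis ratio
// gamma^(t_new - t_old); for gamma = 0 a proposal is accepted only if
// conflict-free, so violations of the hard core can only decrease.
// [[Rcpp::export]]
NumericMatrix gibbs_relocate(NumericMatrix start,
                             double xmin, double xmax,
                             double ymin, double ymax,
                             double gamma, double rg,
                             int n_steps) {
  const double rg2 = rg * rg;
  const int n = start.nrow();
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = start(i, 0);
    ys[i] = start(i, 1);
  }
  if (n == 0) return start;
  for (int step = 0; step < n_steps; ++step) {
    const int i = std::min(n - 1, (int)(unif_rand() * n));
    const double u = xmin + unif_rand() * (xmax - xmin);
    const double v = ymin + unif_rand() * (ymax - ymin);
    const int t_new = n_close(xs, ys, u, v, rg2, i);
    bool accept;
    if (gamma == 0.0) {
      accept = (t_new == 0);
    } else {
      const int t_old = n_close(xs, ys, xs[i], ys[i], rg2, i);
      accept = unif_rand() < std::pow(gamma, t_new - t_old);
    }
    if (accept) {
      xs[i] = u;
      ys[i] = v;
    }
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
  }
  return out;
}

// Number of unordered pairs closer than rg (used for convergence checks).
// [[Rcpp::export]]
int count_close_pairs(NumericMatrix pts, double rg) {
  const double rg2 = rg * rg;
  int m = 0;
  for (int i = 0; i < pts.nrow(); ++i) {
    for (int j = i + 1; j < pts.nrow(); ++j) {
      const double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1);
      if (dx * dx + dy * dy < rg2) ++m;
    }
  }
  return m;
}
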