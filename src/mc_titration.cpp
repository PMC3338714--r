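#include <Rcpp.h>
using namespace Rcpp;

// Single-site-flip Metropolis sampling of protonation microstates at one pH.
// eps: per-site ionization penalties (kcal/mol); M: dense symmetric coupling
// matrix with zero diagonal. Uses R's RNG so set.seed() in the caller fixes
// the stream. Returns the mean ionization <x_i> over the post-burn-in steps.
// [[Rcpp::export]]
NumericVector mc_titration_chain(NumericVector eps, NumericMatrix M,
                                 int steps, double kT, double burn_in) {
  const int n = eps.size();
  if (M.nrow() != n || M.ncol() != n)
    stop("coupling matrix does not match number of sites");
  std::vector<int> x(n, 0);
  // field[i] = sum_j x_j M(i,j): energy cost of ionizing i given the rest
  std::vector<double> field(n, 0.0);
  std::vector<double> acc(n, 0.0);
  const int burn = (int)std::floor(steps * burn_in);
  long kept = 0;

  for (int s = 0; s < steps; ++s) {
    int i = (int)std::floor(unif_rand() * n);
    if (i == n) i = n - 1;
    // dE of flipping site i
    double dE = (x[i] == 0 ? 1.0 : -1.0) * (eps[i] + field[i]);
    if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) {
      int delta = (x[i] == 0) ? 1 : -1;
      x[i] += delta;
      for (int j = 0; j < n; ++j) field[j] += delta * M(j, i);
    }
    if (s >= burn) {
      ++kept;
      for (int j = 0; j < n; ++j) acc[j] += x[j];
    }
  }
  NumericVector out(n);
  for (int j = 0; j < n; ++j) out[j] = kept > 0 ? acc[j] / kept : NA_REAL;
  return out;
}
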