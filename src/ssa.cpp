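#include <Rcpp.h>
using namespace Rcpp;

// Direct-method Gillespie SSA for stochastic mass-action kinetics.
// alpha, nu: n x m reactant-coefficient and stoichiometric matrices.
// Propensities follow the at-most-bimolecular mass-action forms; the
// homogeneous bimolecular channel fires at kappa * x * (x - 1) (no 1/2).
// Uses R's RNG so that set.seed() fixes the realization.

static double channel_propensity(const IntegerMatrix& alpha,
                                 const NumericVector& kappa,
                                 const IntegerVector& x, int j) {
  double a = kappa[j];
  int n = alpha.nrow();
  for (int i = 0; i < n; ++i) {
    int c = alpha(i, j);
    if (c == 0) continue;
    if (x[i] < c) return 0.0;
    if (c == 1) a *= x[i];
    else a *= (double)x[i] * (x[i] - 1);
  }
  return a;
}

// [[Rcpp::export]]
List ssa_core(IntegerMatrix alpha, IntegerMatrix nu, NumericVector kappa,
              IntegerVector x0, double t_end, int max_steps) {
  int n = alpha.nrow(), m = alpha.ncol();
  IntegerVector x = clone(x0);
  std::vector<double> times;
  std::vector<int> rxn;
  times.reserve(1024);
  rxn.reserve(1024);
  double t = 0.0;
  NumericVector a(m);
  RNGScope scope;
  for (int step = 0; step < max_steps; ++step) {
    double a0 = 0.0;
    for (int j = 0; j < m; ++j) {
      a[j] = channel_propensity(alpha, kappa, x, j);
      a0 += a[j];
    }
    if (a0 <= 0.0) break;  // absorbing state
    double tau = R::rexp(1.0 / a0);
    if (t + tau > t_end) break;
    t += tau;
    double u = R::runif(0.0, a0);
    double acc = 0.0;
    int h = m - 1;
    for (int j = 0; j < m; ++j) {
      acc += a[j];
      if (u <= acc) { h = j; break; }
    }
    for (int i = 0; i < n; ++i) x[i] += nu(i, h);
    times.push_back(t);
    rxn.push_back(h + 1);  // 1-based for R
  }
  return List::create(_["times"] = wrap(times), _["rxn"] = wrap(rxn),
                      _["x_final"] = x);
}
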