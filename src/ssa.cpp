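#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of a mass-action
// network with piecewise-constant parameters: one designated reaction (the
// input's basal production) takes a segment-specific rate constant.
// Propensities are monomials c_j * prod_i x_i^{e_ij}; exponents are 0/1/2.
//
// The state is recorded at the supplied sample times (value immediately
// before the first event at or after each sample time), which is the exact
// value of the jump process at that time.
//
// [[Rcpp::export]]
NumericMatrix ssa_run_cpp(IntegerMatrix stoich, IntegerMatrix expo,
                          NumericVector rates, NumericVector x0,
                          int input_rx, NumericVector seg_rates,
                          NumericVector seg_ends, NumericVector sample_times) {
  const int n = stoich.nrow(), m = stoich.ncol();
  const int n_seg = seg_rates.size(), n_samp = sample_times.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(m);
  NumericMatrix out(n, n_samp);

  double t = 0.0;
  int seg = 0, samp = 0;

  // per-reaction participating species for fast propensity evaluation
  std::vector< std::vector<int> > part(m);
  std::vector< std::vector<int> > pow_(m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      if (expo(i, j) > 0) { part[j].push_back(i); pow_[j].push_back(expo(i, j)); }

  while (samp < n_samp) {
    double a0 = 0.0;
    for (int j = 0; j < m; ++j) {
      double aj = (j == input_rx) ? seg_rates[seg] : rates[j];
      for (size_t k = 0; k < part[j].size(); ++k) {
        double xi = x[part[j][k]];
        aj *= (pow_[j][k] == 1) ? xi : xi * xi;
      }
      a[j] = aj;
      a0 += aj;
    }

    double t_next;
    if (a0 <= 0.0) {
      // absorbing until the next segment boundary
      t_next = (seg < n_seg - 1) ? seg_ends[seg] : R_PosInf;
    } else {
      double u = unif_rand();
      if (u <= 0.0) u = 1e-300;
      t_next = t + (-std::log(u)) / a0;
    }

    // segment boundary crossed before the event fires: re-draw there
    if (seg < n_seg - 1 && t_next >= seg_ends[seg]) {
      while (samp < n_samp && sample_times[samp] < seg_ends[seg]) {
        for (int i = 0; i < n; ++i) out(i, samp) = x[i];
        ++samp;
      }
      t = seg_ends[seg];
      ++seg;
      continue;
    }
    if (!R_FINITE(t_next)) {
      for (; samp < n_samp; ++samp)
        for (int i = 0; i < n; ++i) out(i, samp) = x[i];
      break;
    }

    while (samp < n_samp && sample_times[samp] < t_next) {
      for (int i = 0; i < n; ++i) out(i, samp) = x[i];
      ++samp;
    }
    if (samp >= n_samp) break;

    // choose the firing reaction
    double target = unif_rand() * a0, acc = 0.0;
    int r = m - 1;
    for (int j = 0; j < m; ++j) {
      acc += a[j];
      if (target <= acc) { r = j; break; }
    }
    for (int i = 0; i < n; ++i) x[i] += stoich(i, r);
    t = t_next;
  }
  return out;
}
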