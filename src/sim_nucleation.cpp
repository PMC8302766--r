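#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact event-driven birth-death simulation of n_sites cluster seeds sharing
// one monomer pool. Rates:
//   empty site:     k_dimer = dimer_penalty * D * R(1) * c_inf   (needs M >= 2)
//   occupied site:  k_plus  = D * R(N) * c_inf                   (needs M >= 1)
//                   k_minus = D * R(N) * c_sat * (1 +/- 2*Gamma/R(N))
// with R(N) = (3N / (4*pi*c_den))^(1/3) and c_inf = M / V recomputed after
// every event. A cluster shrinking to size 1 dissolves back into the pool.
// Uses R's RNG (unif_rand / exp_rand) so set.seed() governs determinism.

// [[Rcpp::export]]
List sim_nucleation_cpp(double D, double c_sat, double c_den, double Gamma,
                        int M0, double V, IntegerVector sizes0,
                        int N_threshold, double t_max,
                        NumericVector out_times, double dimer_penalty,
                        bool printed_sign, bool record_events,
                        double max_events) {
  const int n_sites = sizes0.size();
  std::vector<long> size(n_sites);
  long M = M0;
  double total = (double)M0;
  for (int i = 0; i < n_sites; ++i) {
    size[i] = sizes0[i];
    total += sizes0[i];
  }
  const double r1 = std::cbrt(3.0 / (4.0 * M_PI * c_den));
  const int n_out = out_times.size();
  NumericVector out_mass(n_out);
  IntegerVector out_nabove(n_out);
  int out_idx = 0;

  std::vector<double> ev_t, ev_free, ev_size;
  if (record_events) {
    size_t cap = (size_t)std::min(max_events, 2.0e6);
    ev_t.reserve(cap); ev_free.reserve(cap); ev_size.reserve(cap);
  }

  std::vector<double> rate(2 * (size_t)n_sites);
  double t = 0.0;
  double n_events = 0.0;
  bool exhausted = false;

  auto radius = [&](long N) { return r1 * std::cbrt((double)N); };
  auto snapshot = [&](int idx) {
    double mass = 0.0; int nab = 0;
    for (int i = 0; i < n_sites; ++i) {
      if (size[i] > N_threshold) { mass += size[i]; ++nab; }
    }
    out_mass[idx] = (total > 0) ? mass / total : 0.0;
    out_nabove[idx] = nab;
  };

  while (t < t_max && n_events < max_events) {
    const double cinf = (double)M / V;
    double tot = 0.0;
    for (int i = 0; i < n_sites; ++i) {
      double kp = 0.0, km = 0.0;
      if (size[i] == 0) {
        if (M >= 2) kp = dimer_penalty * D * radius(1) * cinf;
      } else {
        const double R = radius(size[i]);
        if (M >= 1) kp = D * R * cinf;
        const double curv = 2.0 * Gamma / R;
        km = printed_sign ? D * R * c_sat * (1.0 - curv)
                          : D * R * c_sat * (1.0 + curv);
        if (km < 0.0) km = 0.0;
      }
      rate[2 * i] = kp;
      rate[2 * i + 1] = km;
      tot += kp + km;
    }
    if (tot <= 0.0) { exhausted = true; break; }

    const double dt = exp_rand() / tot;
    const double t_new = t + dt;
    while (out_idx < n_out && out_times[out_idx] <= t_new) {
      snapshot(out_idx);
      ++out_idx;
    }
    t = t_new;
    if (t >= t_max) break;

    double u = unif_rand() * tot;
    int ch = 2 * n_sites - 1;
    for (int j = 0; j < 2 * n_sites; ++j) {
      u -= rate[j];
      if (u <= 0.0) { ch = j; break; }
    }
    const int i = ch / 2;
    if (ch % 2 == 0) {            // attachment / dimerization
      if (size[i] == 0) { size[i] = 2; M -= 2; }
      else              { size[i] += 1; M -= 1; }
    } else {                      // detachment
      size[i] -= 1; M += 1;
      if (size[i] == 1) { size[i] = 0; M += 1; }  // dissolve
    }
    n_events += 1.0;
    if (record_events) {
      ev_t.push_back(t);
      ev_free.push_back((double)M);
      ev_size.push_back((double)size[0]);
    }
    if (n_events == max_events) break;
  }

  while (out_idx < n_out) { snapshot(out_idx); ++out_idx; }

  IntegerVector final_sizes(n_sites);
  for (int i = 0; i < n_sites; ++i) final_sizes[i] = (int)size[i];

  List out = List::create(
    _["mass_frac"] = out_mass,
    _["n_above"] = out_nabove,
    _["n_events"] = n_events,
    _["exhausted"] = exhausted,
    _["final_sizes"] = final_sizes,
    _["final_free"] = (double)M);
  if (record_events) {
    out["ev_time"] = NumericVector(ev_t.begin(), ev_t.end());
    out["ev_free"] = NumericVector(ev_free.begin(), ev_free.end());
    out["ev_size"] = NumericVector(ev_size.begin(), ev_size.end());
  }
  return out;
}
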