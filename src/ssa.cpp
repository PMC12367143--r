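#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct-method simulation of an enzyme-state reaction scheme.
//
// Enzyme copies move between n_states states via reversible steps; each
// direction may consume or release one substrate-pool species. Pool species
// flagged as baths are held at fixed concentration (pseudo-first-order
// treatment); the rest are discrete counts. An optional zero-order drain
// converts pool species `drain_from` to `drain_to` at `drain_rate`
// molecules/s while at least one molecule is present (the translation-demand
// stand-in).
//
// conv = molecules per uM at the simulation volume (V_L * 6.02214e17), used
// to turn discrete pool counts into concentrations for bimolecular
// propensities.
//
// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(int n_states,
             IntegerVector from, IntegerVector to,
             NumericVector kf, NumericVector kb,
             IntegerVector consume_f, IntegerVector release_f,
             IntegerVector init_states,
             NumericVector pool_init,
             NumericVector bath_conc,
             LogicalVector is_bath,
             double conv,
             NumericVector sample_times,
             double drain_rate, int drain_from, int drain_to,
             double max_events) {
  const int n_steps = from.size();
  const int n_pools = pool_init.size();
  const int n_samp = sample_times.size();

  std::vector<double> state(n_states);
  for (int i = 0; i < n_states; ++i) state[i] = init_states[i];
  std::vector<double> pool(n_pools);
  for (int i = 0; i < n_pools; ++i) pool[i] = pool_init[i];

  std::vector<double> cum_f(n_steps, 0.0), cum_b(n_steps, 0.0);
  double cum_drain = 0.0;

  NumericMatrix out_states(n_samp, n_states);
  NumericMatrix out_pools(n_samp, n_pools);
  NumericMatrix out_fire_f(n_samp, n_steps);
  NumericMatrix out_fire_b(n_samp, n_steps);
  NumericVector out_drain(n_samp);

  std::vector<double> prop(2 * n_steps + 1);
  double t = 0.0, events = 0.0;
  int samp = 0;
  bool exhausted = false;

  auto conc = [&](int sp) -> double {
    if (sp < 0) return 1.0;
    return is_bath[sp] ? bath_conc[sp] : pool[sp] / conv;
  };

  auto record_until = [&](double tnow) {
    while (samp < n_samp && sample_times[samp] <= tnow) {
      for (int i = 0; i < n_states; ++i) out_states(samp, i) = state[i];
      for (int i = 0; i < n_pools; ++i) out_pools(samp, i) = pool[i];
      for (int i = 0; i < n_steps; ++i) {
        out_fire_f(samp, i) = cum_f[i];
        out_fire_b(samp, i) = cum_b[i];
      }
      out_drain[samp] = cum_drain;
      ++samp;
    }
  };

  const double t_end = sample_times[n_samp - 1];

  while (t < t_end) {
    double a0 = 0.0;
    for (int i = 0; i < n_steps; ++i) {
      double pf = state[from[i]] * kf[i] * conc(consume_f[i]);
      double pb = state[to[i]] * kb[i] * conc(release_f[i]);
      prop[i] = pf;
      prop[n_steps + i] = pb;
      a0 += pf + pb;
    }
    double pd = 0.0;
    if (drain_rate > 0.0 && drain_from >= 0 && pool[drain_from] >= 1.0)
      pd = drain_rate;
    prop[2 * n_steps] = pd;
    a0 += pd;

    if (a0 <= 0.0) { exhausted = true; break; }

    double tau = -std::log(unif_rand()) / a0;
    double tnext = t + tau;
    if (tnext >= t_end) { t = t_end; break; }
    record_until(tnext);
    t = tnext;

    double r = unif_rand() * a0, acc = 0.0;
    int j = 2 * n_steps;  // default: drain channel
    for (int i = 0; i <= 2 * n_steps; ++i) {
      acc += prop[i];
      if (r <= acc) { j = i; break; }
    }

    if (j < n_steps) {                       // forward firing of step j
      state[from[j]] -= 1.0; state[to[j]] += 1.0;
      if (consume_f[j] >= 0 && !is_bath[consume_f[j]]) pool[consume_f[j]] -= 1.0;
      if (release_f[j] >= 0 && !is_bath[release_f[j]]) pool[release_f[j]] += 1.0;
      cum_f[j] += 1.0;
    } else if (j < 2 * n_steps) {            // backward firing
      int s = j - n_steps;
      state[to[s]] -= 1.0; state[from[s]] += 1.0;
      if (release_f[s] >= 0 && !is_bath[release_f[s]]) pool[release_f[s]] -= 1.0;
      if (consume_f[s] >= 0 && !is_bath[consume_f[s]]) pool[consume_f[s]] += 1.0;
      cum_b[s] += 1.0;
    } else {                                 // demand drain
      if (!is_bath[drain_from]) pool[drain_from] -= 1.0;
      if (drain_to >= 0 && !is_bath[drain_to]) pool[drain_to] += 1.0;
      cum_drain += 1.0;
    }

    if (++events >= max_events)
      stop("SSA event budget exceeded (%.0f events)", max_events);
  }

  record_until(t_end);

  return List::create(_["states"] = out_states, _["pools"] = out_pools,
                      _["fire_f"] = out_fire_f, _["fire_b"] = out_fire_b,
                      _["drain"] = out_drain, _["exhausted"] = exhausted,
                      _["events"] = events);
}
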