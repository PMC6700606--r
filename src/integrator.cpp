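#include <random>

#include "models.h"

using namespace Rcpp;

// BAOAB splitting of underdamped Langevin dynamics: velocity half-kick,
// half-drift, Ornstein-Uhlenbeck velocity update, half-drift, half-kick.
// gamma = 0 reduces exactly to velocity Verlet (NVE). Positions are sampled
// every `sample_every` steps (plus the initial frame); integration stops
// early if a FENE bond overstretches or coordinates become non-finite.
static List run_langevin(const lf::Model& model, NumericMatrix pos0, double dt,
                         long n_steps, int sample_every, double temperature,
                         double gamma, double mass, int seed) {
  const int N = model.n_beads();
  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos0(i, c);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // Maxwell-Boltzmann initial velocities
  const double vscale = std::sqrt(temperature / mass);
  for (int k = 0; k < 3 * N; ++k) v[k] = vscale * gauss(rng);

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * vscale;
  const bool thermostat = gamma > 0.0;

  lf::EnergyBreakdown e;
  bool ok = model.eval(x, f, e);
  long n_samples = n_steps / sample_every + 1;
  NumericVector times(n_samples), energies(n_samples), kinetic(n_samples);
  NumericVector frames(n_samples * 3 * N);  // dim set below
  long isamp = 0;
  long diverged_step = -1;

  auto record = [&](long step) {
    times[isamp] = step * dt;
    energies[isamp] = e.total();
    double ke = 0.0;
    for (int k = 0; k < 3 * N; ++k) ke += v[k] * v[k];
    kinetic[isamp] = 0.5 * mass * ke;
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c)
        frames[isamp * 3 * N + 3 * i + c] = x[3 * i + c];
    ++isamp;
  };

  if (!ok) {
    diverged_step = 0;
  } else {
    record(0);
    for (long step = 1; step <= n_steps; ++step) {
      const double hdt = 0.5 * dt / mass;
      for (int k = 0; k < 3 * N; ++k) v[k] += hdt * f[k];
      for (int k = 0; k < 3 * N; ++k) x[k] += 0.5 * dt * v[k];
      if (thermostat)
        for (int k = 0; k < 3 * N; ++k) v[k] = c1 * v[k] + c2 * gauss(rng);
      for (int k = 0; k < 3 * N; ++k) x[k] += 0.5 * dt * v[k];
      ok = model.eval(x, f, e);
      if (!ok) {
        diverged_step = step;
        break;
      }
      for (int k = 0; k < 3 * N; ++k) v[k] += hdt * f[k];
      if (step % sample_every == 0) {
        bool finite = true;
        for (int k = 0; k < 3 * N && finite; ++k)
          finite = std::isfinite(x[k]);
        if (!finite || !std::isfinite(e.total())) {
          diverged_step = step;
          break;
        }
        record(step);
      }
    }
  }

  // trim to recorded samples
  NumericVector t_out(isamp), e_out(isamp), k_out(isamp), fr_out(isamp * 3 * N);
  for (long s = 0; s < isamp; ++s) {
    t_out[s] = times[s];
    e_out[s] = energies[s];
    k_out[s] = kinetic[s];
    for (int k = 0; k < 3 * N; ++k) fr_out[s * 3 * N + k] = frames[s * 3 * N + k];
  }
  fr_out.attr("dim") = IntegerVector::create(3, N, isamp);
  NumericMatrix vel(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) vel(i, c) = v[3 * i + c];
  return List::create(_["times"] = t_out, _["frames"] = fr_out,
                      _["energies"] = e_out, _["kinetic"] = k_out,
                      _["velocities"] = vel,
                      _["diverged_step"] = diverged_step);
}

// [[Rcpp::export]]
List run_langevin_efm_cpp(NumericMatrix pos0, List ref, List ff, List params,
                          List bridges, double dt, double n_steps,
                          int sample_every, double temperature, double gamma,
                          double mass, int seed) {
  lf::EfmModel m = lf::build_efm_model(pos0, ref, ff, params, bridges);
  return run_langevin(m, pos0, dt, (long)n_steps, sample_every, temperature,
                      gamma, mass, seed);
}

// [[Rcpp::export]]
List run_langevin_go_cpp(NumericMatrix pos0, List goff, List params, double dt,
                         double n_steps, int sample_every, double temperature,
                         double gamma, double mass, int seed) {
  lf::GoModel m = lf::build_go_model(pos0.nrow(), goff, params);
  return run_langevin(m, pos0, dt, (long)n_steps, sample_every, temperature,
                      gamma, mass, seed);
}
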