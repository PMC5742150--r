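#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Counter-based uniform RNG: stateless, so noise streams are independent per
// source and invariant under simulation chunking (the draw for a given
// (seed, stream, step) never depends on how many steps were run before).
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t seed, uint64_t stream, uint64_t step) {
  uint64_t h = splitmix64(seed ^ splitmix64(stream ^ splitmix64(step)));
  return (h >> 11) * (1.0 / 9007199254740992.0); // 2^-53
}

// Discrete-time (1 ms) LIF network step loop.
//
// Exponential-Euler membrane update with the synaptic current held
// piecewise-constant over each step:
//   u <- u*exp(-dt/tau_m) + (1 - exp(-dt/tau_m)) * R * (I + c)
// Synaptic current per neuron is an exponentially decaying accumulator
// (decay exp(-dt/tau_syn)); each arriving spike of weight w adds w*q/tau_syn,
// i.e. the peak of the exponential PSC kernel. Noise generators are
// exogenous Bernoulli(rate*dt) event sources gated by their pulse window.
//
// Synapses are in CSR layout by presynaptic global id (principal neurons
// first, then noise generators). Delays are integer steps >= 1, implemented
// with a ring buffer of pending arrival charge.
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n_principal,
              IntegerVector syn_post, NumericVector syn_w,
              IntegerVector syn_delay, IntegerVector row_ptr,
              NumericVector I,
              IntegerVector nz_gid, IntegerVector nz_stream,
              NumericVector nz_p,
              IntegerVector nz_start, IntegerVector nz_end,
              double alpha, double beta, double Rm, double u_th, double u_r,
              double q_over_tau, int t_ref,
              int start_step, int n_steps, int max_delay,
              double seed_d,
              NumericVector u0, NumericVector c0, IntegerVector ref0,
              NumericMatrix buf0, IntegerVector record_ids) {
  const int np = n_principal;
  const int nn = nz_p.size();
  const int nring = max_delay + 1;
  const uint64_t seed = (uint64_t)seed_d;

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> c(c0.begin(), c0.end());
  std::vector<int> ref(ref0.begin(), ref0.end());
  std::vector<double> buf((size_t)nring * np);
  for (int r = 0; r < nring; ++r)
    for (int i = 0; i < np; ++i)
      buf[(size_t)r * np + i] = buf0(r, i);

  std::vector<int> sp_step, sp_id;
  sp_step.reserve(4096); sp_id.reserve(4096);

  const int nrec = record_ids.size();
  NumericMatrix vm(nrec > 0 ? n_steps : 0, nrec);

  for (int s = 0; s < n_steps; ++s) {
    const int t = start_step + s;
    const int row = t % nring;
    double *arr = &buf[(size_t)row * np];

    // noise generator events, delivered through their synapses
    for (int k = 0; k < nn; ++k) {
      if (t < nz_start[k] || t >= nz_end[k] || nz_p[k] <= 0.0) continue;
      if (u01(seed, (uint64_t)nz_stream[k], (uint64_t)t) < nz_p[k]) {
        const int gid = nz_gid[k];
        for (int e = row_ptr[gid]; e < row_ptr[gid + 1]; ++e) {
          const int arow = (t + syn_delay[e]) % nring;
          buf[(size_t)arow * np + syn_post[e]] += syn_w[e];
        }
      }
    }

    // integrate and fire
    for (int i = 0; i < np; ++i) {
      c[i] = c[i] * beta + q_over_tau * arr[i];
      if (ref[i] > 0) { ref[i]--; u[i] = u_r; continue; }
      u[i] = u[i] * alpha + (1.0 - alpha) * Rm * (I[i] + c[i]);
      if (!std::isfinite(u[i]))
        stop("membrane potential of neuron %d became non-finite at step %d",
             i + 1, t);
      // strict crossing: at threshold with zero slope (rheobase) no spike
      if (u[i] > u_th) {
        sp_step.push_back(t);
        sp_id.push_back(i);
        u[i] = u_r;
        ref[i] = t_ref;
        for (int e = row_ptr[i]; e < row_ptr[i + 1]; ++e) {
          const int arow = (t + syn_delay[e]) % nring;
          buf[(size_t)arow * np + syn_post[e]] += syn_w[e];
        }
      }
    }
    // clear consumed ring-buffer row for reuse at step t + nring
    std::fill(arr, arr + np, 0.0);

    for (int r2 = 0; r2 < nrec; ++r2)
      vm(s, r2) = u[record_ids[r2]];
  }

  NumericMatrix buf_out(nring, np);
  for (int r = 0; r < nring; ++r)
    for (int i = 0; i < np; ++i)
      buf_out(r, i) = buf[(size_t)r * np + i];

  return List::create(
    _["spike_step"] = IntegerVector(sp_step.begin(), sp_step.end()),
    _["spike_neuron"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["c"] = NumericVector(c.begin(), c.end()),
    _["ref"] = IntegerVector(ref.begin(), ref.end()),
    _["buf"] = buf_out,
    _["vm"] = vm);
}
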