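#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Explicit Euler (Euler-Maruyama when sigma > 0) integration of the
// Kuramoto network dphi_i/dt = omega_i + G sum_j C_ij sin(phi_j - phi_i)
// (+ sigma * white noise). Row i of C collects the couplings incoming to
// oscillator i. Noise draws come from R's RNG so results follow set.seed().
// Returns unwrapped phases sampled every sample_every steps after the
// transient.
// [[Rcpp::export(name = ".kuramoto_integrate")]]
arma::mat kuramoto_integrate(const arma::mat& C, const arma::vec& omega,
                             double G, double sigma, double dt,
                             double n_steps_d, double transient_steps_d,
                             double sample_every_d, const arma::vec& phi0) {
  const long long n_steps = (long long) n_steps_d;
  const long long transient = (long long) transient_steps_d;
  const long long sample_every = (long long) sample_every_d;
  const arma::uword n = phi0.n_elem;
  const long long n_samples = (n_steps - transient) / sample_every;

  arma::vec phi = phi0;                       // unwrapped state
  arma::mat out(n_samples, n);
  const double sqdt = std::sqrt(dt);
  const bool noisy = sigma > 0.0;
  const arma::mat Gc = G * C;
  long long row = 0;

  for (long long s = 1; s <= n_steps; ++s) {
    const arma::vec sp = arma::sin(phi);
    const arma::vec cp = arma::cos(phi);
    // sum_j C_ij sin(phi_j - phi_i) = cos(phi_i)(C s)_i - sin(phi_i)(C c)_i
    arma::vec drift = omega + cp % (Gc * sp) - sp % (Gc * cp);
    phi += dt * drift;
    if (noisy) {
      for (arma::uword i = 0; i < n; ++i)
        phi[i] += sigma * sqdt * norm_rand();
    }
    if (!phi.is_finite())
      stop("non-finite phase state at step %lld (dt too large?)", s);
    if (s > transient && (s - transient) % sample_every == 0) {
      out.row(row++) = phi.t();
      if (row == n_samples) break;
    }
  }
  return out;
}
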