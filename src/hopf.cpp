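#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Fixed-step integrator for the forced Hopf normal form
//   dz/dt = (eps + i*omega_c) z - (beta_re + i*beta_im) |z|^2 z
//           + sum_k F_k exp(i (omega_k t + phi_k))
// RK4 when `noise` is empty, Euler-Maruyama otherwise (noise holds
// pre-scaled increments sigma*sqrt(dt), interleaved re/im, one pair per
// internal step).  Integration runs on an internal grid dt/oversample and
// the state is recorded every `oversample` internal steps, giving
// n_record+1 recorded states (including z0).
// [[Rcpp::export]]
NumericMatrix hopf_integrate_cpp(double eps, double omega_c,
                                 double beta_re, double beta_im,
                                 NumericVector f_amp, NumericVector f_omega,
                                 NumericVector f_phi,
                                 double dt, int n_record, int oversample,
                                 double z0_re, double z0_im,
                                 NumericVector noise, double bound) {
  const std::complex<double> I(0.0, 1.0);
  const std::complex<double> mu(eps, omega_c);
  const std::complex<double> beta(beta_re, beta_im);
  const int K = f_amp.size();
  const double h = dt / oversample;
  const bool stoch = noise.size() > 0;
  std::complex<double> z(z0_re, z0_im);

  NumericMatrix out(n_record + 1, 2);
  out(0, 0) = z.real();
  out(0, 1) = z.imag();

  auto deriv = [&](double t, std::complex<double> w) {
    std::complex<double> f = mu * w - beta * std::norm(w) * w;
    for (int k = 0; k < K; ++k)
      f += f_amp[k] * std::exp(I * (f_omega[k] * t + f_phi[k]));
    return f;
  };

  long step = 0;
  for (int i = 0; i < n_record; ++i) {
    for (int s = 0; s < oversample; ++s, ++step) {
      double t = step * h;
      if (stoch) {
        std::complex<double> dW(noise[2 * step], noise[2 * step + 1]);
        z += deriv(t, z) * h + dW;
      } else {
        std::complex<double> k1 = deriv(t, z);
        std::complex<double> k2 = deriv(t + 0.5 * h, z + 0.5 * h * k1);
        std::complex<double> k3 = deriv(t + 0.5 * h, z + 0.5 * h * k2);
        std::complex<double> k4 = deriv(t + h, z + h * k3);
        z += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      }
      if (!std::isfinite(z.real()) || !std::isfinite(z.imag()) ||
          std::abs(z) > bound)
        stop("oscillator state diverged (|z| exceeded the configured bound)");
    }
    out(i + 1, 0) = z.real();
    out(i + 1, 1) = z.imag();
  }
  return out;
}
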