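#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: deterministic for a given (seed, stream)
// regardless of R's RNG state or the standard library's distribution details.
namespace {

struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  Xoshiro256(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9e3779b97f4a7c15ULL + stream;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1]; never exactly 0 so log() is safe
  double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
};

// unpolarized Fresnel reflectance, incidence from medium (n_rel = n_in/n_out), ci = cos(theta_i) > 0
inline double fresnel_r(double ci, double n_rel) {
  if (n_rel == 1.0) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = n_rel * n_rel * si2;
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection + uniform azimuth; updates direction in place
inline void spin(double &ux, double &uy, double &uz, double g, Xoshiro256 &rng) {
  double ct;
  if (g == 0.0) {
    ct = 2.0 * rng.unif() - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double psi = 6.283185307179586477 * rng.unif();
  double cp = std::cos(psi), sp = std::sin(psi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -den * st * cp + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
}

}  // namespace

// Photon transport in a semi-infinite homogeneous slab (z >= 0), pencil beam at the
// origin along +z.  Specular reflection at entry is removed before launch.
//
// white = true : transport at mu_a = 0 (mu_t = mu_s), no absorption deposits;
//   per-photon (exit radius, pathlength) records returned for White-Monte-Carlo
//   exp(-mu_a * L) rescaling.  Long-path photons are controlled by Russian
//   roulette on the OPTICAL pathlength tau = mu_s * L (thresholds every
//   tau_block mean free paths, survival 1/roulette_m): tau depends only on the
//   RNG draw sequence, so with a shared seed the roulette decisions are
//   identical across mu_s nodes and the exact 1/mu_s trajectory scaling between
//   nodes is preserved.  A hard cap at tau_max terminates (practically never
//   reached) wanderers; their weight is tallied as capped.
// white = false: albedo weighting at each interaction, Russian roulette below
//   w_threshold with survival 1/roulette_m.
//
// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(double mu_a, double mu_s, double g, double n_rel,
                  int n_photons, bool white,
                  double seed, double stream,
                  double tau_max = 1e5,
                  double w_threshold = 1e-4, double roulette_m = 10.0,
                  double tau_block = 5000.0) {
  if (mu_s <= 0) stop("mu_s must be positive");
  if (n_photons <= 0) stop("n_photons must be positive");
  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);

  const double mu_t = white ? mu_s : (mu_a + mu_s);
  const double albedo_loss = white ? 0.0 : (mu_a / mu_t);
  const double r_sp = (n_rel == 1.0) ? 0.0
      : ((n_rel - 1.0) / (n_rel + 1.0)) * ((n_rel - 1.0) / (n_rel + 1.0));
  const double w0 = 1.0 - r_sp;

  std::vector<double> exit_r, exit_l, exit_w;
  exit_r.reserve(n_photons); exit_l.reserve(n_photons); exit_w.reserve(n_photons);

  double absorbed = 0.0, escaped = 0.0, capped_w = 0.0;
  double roulette_net = 0.0;  // killed weight minus weight added on survival
  long long capped_n = 0;
  double sum_w = 0.0, sum_w2 = 0.0;  // escaped weight per photon, for SE

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1;
    double w = w0, L = 0, tau = 0;
    double next_thresh = tau_block;
    bool alive = true;
    double photon_escaped_w = 0.0;

    while (alive) {
      double step_tau = -std::log(rng.unif());
      double s = step_tau / mu_t;
      if (uz < 0.0 && z + s * uz <= 0.0) {
        // hop to the boundary and attempt escape
        double s1 = -z / uz;
        x += ux * s1; y += uy * s1; z = 0.0;
        L += s1; tau += s1 * mu_t;
        double refl = fresnel_r(-uz, n_rel);
        if (refl == 0.0 || rng.unif() > refl) {
          double r = std::sqrt(x * x + y * y);
          exit_r.push_back(r); exit_l.push_back(L); exit_w.push_back(w);
          escaped += w; photon_escaped_w = w;
          alive = false;
          break;
        }
        uz = -uz;
        double s2 = s - s1;
        x += ux * s2; y += uy * s2; z += uz * s2;
        L += s2; tau += s2 * mu_t;
      } else {
        x += ux * s; y += uy * s; z += uz * s;
        L += s; tau += step_tau;
      }
      // interaction site
      if (albedo_loss > 0.0) {
        double da = w * albedo_loss;
        absorbed += da;
        w -= da;
      }
      spin(ux, uy, uz, g, rng);
      if (white && tau > next_thresh) {
        if (rng.unif() < 1.0 / roulette_m) {
          roulette_net -= w * (roulette_m - 1.0);
          w *= roulette_m;
        } else {
          roulette_net += w;
          alive = false;
        }
        next_thresh += tau_block;
      }
      if (alive && !white && w < w_threshold) {
        if (rng.unif() < 1.0 / roulette_m) {
          roulette_net -= w * (roulette_m - 1.0);
          w *= roulette_m;
        } else {
          roulette_net += w;
          alive = false;
        }
      }
      if (alive && tau > tau_max) {
        capped_w += w;
        ++capped_n;
        alive = false;
      }
    }
    sum_w += photon_escaped_w;
    sum_w2 += photon_escaped_w * photon_escaped_w;
  }

  return List::create(
    _["exit_r"] = NumericVector(exit_r.begin(), exit_r.end()),
    _["exit_l"] = NumericVector(exit_l.begin(), exit_l.end()),
    _["exit_w"] = NumericVector(exit_w.begin(), exit_w.end()),
    _["escaped"] = escaped,
    _["absorbed"] = absorbed,
    _["capped_weight"] = capped_w,
    _["capped_n"] = (double)capped_n,
    _["roulette_net"] = roulette_net,
    _["launch_weight"] = w0,
    _["specular"] = r_sp,
    _["n_photons"] = n_photons,
    _["sum_w"] = sum_w,
    _["sum_w2"] = sum_w2);
}
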