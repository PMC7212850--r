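// Voxel Monte Carlo photon-packet transport for interstitial PDT dosimetry.
// MCML-style dimensionless stepping through a labelled voxel grid:
// step length -ln(xi)/mu_t, absorption-weight deposition w*mu_a/mu_t per
// interaction, Henyey-Greenstein scattering, Russian roulette. The RNG is a
// self-contained counter-seeded xorshift128+ so identical seeds give
// bit-identical fields on any platform, independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift128Plus {
  uint64_t s0, s1;
  explicit XorShift128Plus(uint64_t seed) {
    // splitmix64 expansion of the seed into the two state words
    uint64_t x = seed;
    s0 = splitmix(x);
    s1 = splitmix(x);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  uint64_t next() {
    uint64_t a = s0, b = s1;
    s0 = b;
    a ^= a << 23;
    a ^= a >> 17;
    a ^= b ^ (b >> 26);
    s1 = a;
    return a + b;
  }
  // uniform on the open interval (0, 1)
  double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-9) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// rotate (ux,uy,uz) by polar angle with cosine ct and azimuth phi
inline void scatter_dir(double& ux, double& uy, double& uz,
                        double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= n; uy /= n; uz /= n;
}

} // namespace

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(IntegerVector labels, IntegerVector dims,
                      double voxel, NumericVector source,
                      NumericVector mu_a, NumericVector mu_s,
                      NumericVector g, double packets, double seed,
                      double weight_threshold, double roulette_p) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double lx = nx * voxel, ly = ny * voxel, lz = nz * voxel;
  const long nvox = static_cast<long>(nx) * ny * nz;
  NumericVector dep(nvox);
  double absorbed = 0.0, escaped = 0.0, terminated = 0.0;
  const long npack = static_cast<long>(packets);
  const double eps = 1e-9 * voxel;
  const long max_events = 2000000; // per-packet guard; never binds in practice
  long lost_packets = 0;

  XorShift128Plus rng(static_cast<uint64_t>(seed));

  // Homogeneous media need no voxel-boundary marching: every interaction is
  // a full analytic step, with deposition binned into the containing voxel.
  bool homogeneous = true;
  for (long i = 1; i < static_cast<long>(labels.size()); ++i)
    if (labels[i] != labels[0]) { homogeneous = false; break; }

  if (homogeneous) {
    const int lab = labels[0] - 1;
    const double ma = mu_a[lab], ms = mu_s[lab];
    const double mt = ma + ms, alb = ms / mt, gg = g[lab];
    for (long p = 0; p < npack; ++p) {
      double x = source[0], y = source[1], z = source[2];
      double ct0 = 2.0 * rng.unif() - 1.0;
      double ph0 = 2.0 * M_PI * rng.unif();
      double st0 = std::sqrt(1.0 - ct0 * ct0);
      double ux = st0 * std::cos(ph0), uy = st0 * std::sin(ph0), uz = ct0;
      double w = 1.0;
      long events = 0;
      for (;;) {
        if (++events > max_events) { terminated += w; ++lost_packets; break; }
        double step = -std::log(rng.unif()) / mt;
        x += step * ux; y += step * uy; z += step * uz;
        if (x < 0 || y < 0 || z < 0 || x >= lx || y >= ly || z >= lz) {
          escaped += w;
          break;
        }
        long idx = static_cast<long>(x / voxel) +
                   static_cast<long>(nx) *
                   (static_cast<long>(y / voxel) +
                    static_cast<long>(ny) * static_cast<long>(z / voxel));
        double dw = w * (1.0 - alb);
        dep[idx] += dw;
        absorbed += dw;
        w -= dw;
        if (w < weight_threshold) {
          if (rng.unif() < roulette_p) {
            double wn = w / roulette_p;
            terminated -= (wn - w);
            w = wn;
          } else {
            terminated += w;
            break;
          }
        }
        double ct = hg_cos(gg, rng.unif());
        double phi = 2.0 * M_PI * rng.unif();
        scatter_dir(ux, uy, uz, ct, phi);
      }
    }
    return List::create(_["deposit"] = dep, _["absorbed"] = absorbed,
                        _["escaped"] = escaped, _["terminated"] = terminated,
                        _["lost_packets"] = static_cast<double>(lost_packets),
                        _["packets"] = static_cast<double>(npack));
  }

  for (long p = 0; p < npack; ++p) {
    double x = source[0], y = source[1], z = source[2];
    double ct0 = 2.0 * rng.unif() - 1.0;
    double ph0 = 2.0 * M_PI * rng.unif();
    double st0 = std::sqrt(1.0 - ct0 * ct0);
    double ux = st0 * std::cos(ph0), uy = st0 * std::sin(ph0), uz = ct0;
    double w = 1.0;
    bool alive = true;
    long events = 0;

    double s = -std::log(rng.unif()); // dimensionless optical path

    while (alive) {
      if (++events > max_events) { terminated += w; ++lost_packets; break; }
      // current voxel
      int ix = static_cast<int>(std::floor(x / voxel));
      int iy = static_cast<int>(std::floor(y / voxel));
      int iz = static_cast<int>(std::floor(z / voxel));
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz ||
          x < 0 || y < 0 || z < 0 || x >= lx || y >= ly || z >= lz) {
        escaped += w;
        break;
      }
      long idx = static_cast<long>(ix) +
                 static_cast<long>(nx) * (iy + static_cast<long>(ny) * iz);
      int lab = labels[idx] - 1;
      double ma = mu_a[lab], ms = mu_s[lab];
      double mt = ma + ms;

      // distance to the nearest voxel face along the direction of flight
      double db = 1e30;
      if (ux > 1e-12) db = std::min(db, ((ix + 1) * voxel - x) / ux);
      else if (ux < -1e-12) db = std::min(db, (ix * voxel - x) / ux);
      if (uy > 1e-12) db = std::min(db, ((iy + 1) * voxel - y) / uy);
      else if (uy < -1e-12) db = std::min(db, (iy * voxel - y) / uy);
      if (uz > 1e-12) db = std::min(db, ((iz + 1) * voxel - z) / uz);
      else if (uz < -1e-12) db = std::min(db, (iz * voxel - z) / uz);
      if (db < 0.0) db = 0.0;

      if (db * mt >= s) {
        // interaction inside this voxel
        double step = s / mt;
        x += step * ux; y += step * uy; z += step * uz;
        double dw = w * ma / mt;
        dep[idx] += dw;
        absorbed += dw;
        w -= dw;
        if (w < weight_threshold) {
          if (rng.unif() < roulette_p) {
            double wn = w / roulette_p;
            terminated -= (wn - w);
            w = wn;
          } else {
            terminated += w;
            break;
          }
        }
        double ct = hg_cos(g[lab], rng.unif());
        double phi = 2.0 * M_PI * rng.unif();
        scatter_dir(ux, uy, uz, ct, phi);
        s = -std::log(rng.unif());
      } else {
        // cross into the next voxel, consuming optical path
        s -= db * mt;
        x += (db + eps) * ux; y += (db + eps) * uy; z += (db + eps) * uz;
      }
    }
  }

  return List::create(_["deposit"] = dep, _["absorbed"] = absorbed,
                      _["escaped"] = escaped, _["terminated"] = terminated,
                      _["lost_packets"] = static_cast<double>(lost_packets),
                      _["packets"] = static_cast<double>(npack));
}
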