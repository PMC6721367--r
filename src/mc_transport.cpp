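// Weighted-photon voxel Monte Carlo transport with implicit capture,
// Henyey-Greenstein scattering and Russian roulette. Fluence is estimated
// from the absorbed-energy tally (phi = E_dep / (mu_a * V)). The grid is
// index matched to its surroundings: photons leaving it are tallied as
// reflected (back through z = 0) or transmitted (all other exits).
//
// RNG: xoshiro256++ seeded via splitmix64 so that identical seeds give
// bit-identical results independently of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]: never returns 0, safe for log()
  double runif_pos() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  // uniform in [0, 1)
  double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Henyey-Greenstein cosine of the deflection angle.
inline double hg_cos(Xoshiro &rng, double g) {
  if (std::fabs(g) < 1e-8) return 2.0 * rng.runif() - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif());
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Rotate direction (ux, uy, uz) by deflection ct and azimuth phi.
inline void scatter_dir(double ct, double phi, double &ux, double &uy,
                        double &uz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
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

// [[Rcpp::export(name = ".cpp_mc_transport")]]
List cpp_mc_transport(IntegerVector dims, double h, NumericVector mu_a,
                      NumericVector mu_s, double g, NumericVector src_pos,
                      int src_kind, double n_photons, double seed,
                      double w_threshold, double w_survival,
                      double max_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nph = (long)n_photons;
  if (nph < 1) stop("n_photons must be at least 1");
  if (w_survival <= 0.0 || w_survival >= 1.0)
    stop("roulette survival probability must lie in (0, 1)");
  Xoshiro rng((uint64_t)seed);
  NumericVector absorb(nx * ny * nz);
  double tot_abs = 0.0, tot_refl = 0.0, tot_trans = 0.0;
  const double eps = 1e-9 * h; // pencil-beam entry offset

  for (long p = 0; p < nph; ++p) {
    double x = src_pos[0], y = src_pos[1], z = src_pos[2];
    double ux = 0.0, uy = 0.0, uz = 1.0;
    if (src_kind == 1) { // isotropic point
      double ct = 2.0 * rng.runif() - 1.0;
      double phi = 2.0 * M_PI * rng.runif();
      double st = std::sqrt(1.0 - ct * ct);
      ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
    } else {
      z = std::max(z, eps); // pencil beam enters just inside the surface
    }
    double w = 1.0;
    bool alive = true;
    double steps = 0.0;
    // voxel indices are tracked incrementally (DDA): the walked axis index
    // advances by exactly one per boundary crossing, which guarantees
    // progress even when a position lands on a voxel face to within
    // rounding (recomputing indices from the position can then stall).
    int ix = (int)(x / h), iy2 = (int)(y / h), iz = (int)(z / h);
    if (ix >= nx) ix = nx - 1;
    if (iy2 >= ny) iy2 = ny - 1;
    if (iz >= nz) iz = nz - 1;
    while (alive) {
      double tau = -std::log(rng.runif_pos());
      // propagate through voxels until the optical depth is consumed
      int iv = -1;
      while (true) {
        if (ix < 0 || ix >= nx || iy2 < 0 || iy2 >= ny || iz < 0 ||
            iz >= nz) {
          if (iz < 0) tot_refl += w; else tot_trans += w;
          alive = false; break;
        }
        iv = ix + iy2 * nx + iz * nx * ny;
        double mt = mu_a[iv] + mu_s[iv];
        // distance to each face of the current voxel along the flight
        double tx = (ux > 0) ? ((ix + 1) * h - x) / ux
                  : (ux < 0) ? (ix * h - x) / ux : 1e30;
        double ty = (uy > 0) ? ((iy2 + 1) * h - y) / uy
                  : (uy < 0) ? (iy2 * h - y) / uy : 1e30;
        double tz = (uz > 0) ? ((iz + 1) * h - z) / uz
                  : (uz < 0) ? (iz * h - z) / uz : 1e30;
        if (tx < 0) tx = 0;
        if (ty < 0) ty = 0;
        if (tz < 0) tz = 0;
        double tb = std::min(tx, std::min(ty, tz));
        double dc = (mt > 0.0) ? tau / mt : 1e30;
        if (dc <= tb) { // collision inside this voxel
          x += ux * dc; y += uy * dc; z += uz * dc;
          break;
        }
        x += ux * tb; y += uy * tb; z += uz * tb;
        tau -= tb * mt;
        if (tau < 0.0) tau = 0.0;
        if (tb == tx) ix += (ux > 0) ? 1 : -1;
        else if (tb == ty) iy2 += (uy > 0) ? 1 : -1;
        else iz += (uz > 0) ? 1 : -1;
      }
      if (!alive) break;
      // collision: implicit capture then scatter
      double mt = mu_a[iv] + mu_s[iv];
      double dw = (mt > 0.0) ? w * mu_a[iv] / mt : 0.0;
      absorb[iv] += dw;
      tot_abs += dw;
      w -= dw;
      if (w < w_threshold) {
        if (rng.runif() < w_survival) w /= w_survival;
        else { alive = false; break; }
      }
      double ct = hg_cos(rng, g);
      double phi = 2.0 * M_PI * rng.runif();
      scatter_dir(ct, phi, ux, uy, uz);
      if (++steps > max_steps) { tot_trans += w; alive = false; }
    }
  }
  return List::create(_["absorb"] = absorb,
                      _["absorbed"] = tot_abs / nph,
                      _["reflected"] = tot_refl / nph,
                      _["transmitted"] = tot_trans / nph);
}

// [[Rcpp::export(name = ".cpp_sample_hg")]]
NumericVector cpp_sample_hg(double n, double g, double seed) {
  long nn = (long)n;
  Xoshiro rng((uint64_t)seed);
  NumericVector out(nn);
  for (long i = 0; i < nn; ++i) out[i] = hg_cos(rng, g);
  return out;
}
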