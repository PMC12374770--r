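// Layered time-resolved Monte Carlo photon transport (MCML-style).
//
// Pencil beam, normal incidence at the origin of a stack of plane-parallel
// layers (last layer may be semi-infinite). Henyey-Greenstein scattering,
// implicit-capture absorption (weight multiplied by the single-scattering
// albedo at each interaction), Fresnel reflection/refraction at the surface
// and at internal index mismatches, Russian roulette termination.
//
// Photons escaping through the top surface inside an annulus are binned by
// optical arrival time t = sum_i n_i L_i / c; per-layer geometric pathlengths
// of detected photons are accumulated per arrival bin so that absorption
// perturbations can be re-applied by Beer-Lambert re-weighting.
//
// Reproducibility: a counter-based per-photon substream (splitmix64-seeded
// xoshiro256++) makes results depend only on (seed, photon index).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const double C0 = 29.9792458; // speed of light in vacuum, cm/ns

inline std::uint64_t splitmix64(std::uint64_t &x) {
  std::uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  std::uint64_t s[4];
  void seed(std::uint64_t sd) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sd);
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline std::uint64_t next() {
    std::uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in (0, 1]; never 0 so log() is safe
  inline double unif() {
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
};

// unpolarized Fresnel reflectance, incidence from n1 into n2
inline double fresnel(double n1, double n2, double cosi, double &cost) {
  if (n1 == n2) { cost = cosi; return 0.0; }
  double sini2 = 1.0 - cosi * cosi;
  double sint2 = (n1 / n2) * (n1 / n2) * sini2;
  if (sint2 >= 1.0) { cost = 0.0; return 1.0; } // total internal reflection
  cost = std::sqrt(1.0 - sint2);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericVector mua, NumericVector mus, NumericVector g,
                NumericVector n_layer, NumericVector thickness,
                double n_ambient, double n_photons, double seed,
                double rmin, double rmax, double tmax, int nbins,
                double weight_threshold, double roulette_survival,
                double cos_accept_min) {
  const int nl = mua.size();
  std::vector<double> zlo(nl), zhi(nl), albedo(nl), mut(nl), inv_mut(nl),
      gg_l(nl), nn_l(nl), nc_l(nl);
  double z = 0.0;
  for (int i = 0; i < nl; ++i) {
    zlo[i] = z;
    double th = thickness[i];
    zhi[i] = R_FINITE(th) ? z + th : R_PosInf;
    z = zhi[i];
    mut[i] = mua[i] + mus[i];
    inv_mut[i] = 1.0 / mut[i];
    albedo[i] = mus[i] / mut[i];
    gg_l[i] = g[i];
    nn_l[i] = n_layer[i];
    nc_l[i] = n_layer[i] / C0;
  }
  const double dt = tmax / nbins;

  std::vector<double> dtof(nbins, 0.0), dtof_w2(nbins, 0.0);
  std::vector<double> nphot(nbins, 0.0);
  std::vector<double> path(static_cast<size_t>(nl) * nbins, 0.0);

  double w_detected = 0.0, w_reflected_other = 0.0, w_transmitted = 0.0;
  double w_absorbed = 0.0, w_roulette_killed = 0.0, w_roulette_gain = 0.0;
  double w_timed_out = 0.0;
  double n_detected = 0.0;

  const std::uint64_t seed64 = static_cast<std::uint64_t>(seed);
  const long long np = static_cast<long long>(n_photons);
  std::vector<double> L(nl);

  for (long long pid = 0; pid < np; ++pid) {
    if ((pid & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    Xoshiro256pp rng;
    std::uint64_t mix = seed64 ^ (0xD1342543DE82EF95ULL *
                                  (static_cast<std::uint64_t>(pid) + 1ULL));
    rng.seed(mix);

    double x = 0.0, y = 0.0, zp = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, topt = 0.0;
    int lay = 0;
    std::fill(L.begin(), L.end(), 0.0);
    double step = -std::log(rng.unif()); // dimensionless step (mfp units)
    bool alive = true;

    while (alive) {
      double d = step * inv_mut[lay];
      // distance to the layer boundary along uz
      double db = R_PosInf;
      bool up = false;
      if (uz > 0.0) {
        db = (zhi[lay] - zp) / uz;
      } else if (uz < 0.0) {
        db = (zlo[lay] - zp) / uz;
        up = true;
      }
      if (db <= d) {
        // move to the boundary
        x += ux * db; y += uy * db; zp = up ? zlo[lay] : zhi[lay];
        L[lay] += db;
        topt += nc_l[lay] * db;
        step -= db * mut[lay];
        if (topt > tmax) { w_timed_out += w; break; }

        double next_n = up ? (lay == 0 ? n_ambient : nn_l[lay - 1])
                           : (lay == nl - 1 ? n_ambient : nn_l[lay + 1]);
        double cosi = std::fabs(uz), cost;
        double R = fresnel(nn_l[lay], next_n, cosi, cost);
        if (rng.unif() < R) {
          uz = -uz; // reflected
        } else if (up && lay == 0) {
          // escaped through the top surface
          if (cost >= cos_accept_min) {
            double r = std::sqrt(x * x + y * y);
            if (r >= rmin && r <= rmax) {
              int b = static_cast<int>(topt / dt);
              if (b >= nbins) b = nbins - 1;
              dtof[b] += w; dtof_w2[b] += w * w; nphot[b] += 1.0;
              for (int i = 0; i < nl; ++i)
                path[static_cast<size_t>(i) * nbins + b] += w * L[i];
              w_detected += w; n_detected += 1.0;
            } else {
              w_reflected_other += w;
            }
          } else {
            w_reflected_other += w;
          }
          break;
        } else if (!up && lay == nl - 1) {
          w_transmitted += w; // escaped through the bottom
          break;
        } else {
          // refract into the adjacent layer
          double scale = nn_l[lay] / next_n;
          ux *= scale; uy *= scale;
          uz = (uz > 0.0 ? cost : -cost);
          lay += up ? -1 : 1;
        }
        continue;
      }

      // interaction inside the layer
      x += ux * d; y += uy * d; zp += uz * d;
      L[lay] += d;
      topt += nc_l[lay] * d;
      if (topt > tmax) { w_timed_out += w; break; }

      double w_new = w * albedo[lay];
      w_absorbed += w - w_new;
      w = w_new;
      if (w < weight_threshold) {
        if (rng.unif() < roulette_survival) {
          double gained = w / roulette_survival - w;
          w_roulette_gain += gained;
          w += gained;
        } else {
          w_roulette_killed += w;
          break;
        }
      }

      // Henyey-Greenstein deflection
      double gg = gg_l[lay], ct;
      if (std::fabs(gg) < 1e-6) {
        ct = 2.0 * rng.unif() - 1.0;
      } else {
        double f = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * rng.unif());
        ct = (1.0 + gg * gg - f * f) / (2.0 * gg);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(1.0 - ct * ct);
      // azimuth by rejection sampling on the unit disc (no trig calls)
      double cp, sp;
      for (;;) {
        double aa = 2.0 * rng.unif() - 1.0, bb = 2.0 * rng.unif() - 1.0;
        double rr = aa * aa + bb * bb;
        if (rr <= 1.0 && rr > 1e-12) {
          double inv = 1.0 / std::sqrt(rr);
          cp = aa * inv; sp = bb * inv;
          break;
        }
      }
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = (uz >= 0.0 ? ct : -ct);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double uxn = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double uyn = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double uzn = -den * st * cp + uz * ct;
        ux = uxn; uy = uyn; uz = uzn;
        double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm; uy /= norm; uz /= norm;
      }
      step = -std::log(rng.unif());
    }
  }

  NumericMatrix pmat(nl, nbins);
  for (int i = 0; i < nl; ++i)
    for (int b = 0; b < nbins; ++b)
      pmat(i, b) = path[static_cast<size_t>(i) * nbins + b];

  return List::create(
      _["dtof"] = NumericVector(dtof.begin(), dtof.end()),
      _["dtof_w2"] = NumericVector(dtof_w2.begin(), dtof_w2.end()),
      _["n_detected_bin"] = NumericVector(nphot.begin(), nphot.end()),
      _["pathlen_sums"] = pmat,
      _["totals"] = List::create(
          _["launched"] = static_cast<double>(np),
          _["detected"] = w_detected,
          _["n_detected"] = n_detected,
          _["reflected_other"] = w_reflected_other,
          _["transmitted"] = w_transmitted,
          _["absorbed"] = w_absorbed,
          _["roulette_killed"] = w_roulette_killed,
          _["roulette_gain"] = w_roulette_gain,
          _["timed_out"] = w_timed_out));
}
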