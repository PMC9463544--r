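// Monte Carlo photon transport for a seven-fiber contact probe on layered or
// voxelized turbid media. Weighted packets with continuous absorption
// (survival fraction mu_s/mu_t deposited at each interaction), Henyey-
// Greenstein scattering, Fresnel boundaries at the tissue-air surface and at
// internal index mismatches, Russian roulette, and NA-gated per-fiber
// detection. All randomness comes from counter-derived splitmix64 substreams
// so results are a pure function of (model, probe, n_photons, seed).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 streams keyed by (seed, counter).

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on the open interval (0, 1)
  double u01() {
    for (;;) {
      double u = (next() >> 11) * (1.0 / 9007199254740992.0);
      if (u > 0.0 && u < 1.0) return u;
    }
  }
};

static inline uint64_t mix_seed(uint64_t a, uint64_t b) {
  uint64_t z = a * 0x9E3779B97F4A7C15ULL + (b + 0x632BE59BD9B4E019ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
double derive_stream_seed_cpp(double seed, double index) {
  // reduced to [0, 2^31) so the value round-trips through an R integer
  uint64_t s = mix_seed((uint64_t)seed, (uint64_t)index);
  return (double)(s % 2147483647ULL);
}

// ---------------------------------------------------------------------------
// Transport kernels (also exported for direct testing).

static inline double fresnel_unpol(double ni, double nt, double ci) {
  if (ci > 1.0) ci = 1.0;
  if (ci < 0.0) ci = 0.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = ni / nt * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export]]
NumericVector sample_free_path_cpp(NumericVector mu_t, NumericVector u) {
  R_xlen_t n = mu_t.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = -std::log(u[i]) / mu_t[i];
  return out;
}

// [[Rcpp::export]]
NumericVector sample_hg_cpp(double g, NumericVector u) {
  R_xlen_t n = u.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector fresnel_unpolarized_cpp(double n_i, double n_t, NumericVector cos_theta_i) {
  R_xlen_t n = cos_theta_i.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fresnel_unpol(n_i, n_t, cos_theta_i[i]);
  return out;
}

static void spin(double g, SplitMix& rng, double& ux, double& uy, double& uz) {
  double ct = hg_cos(g, rng.u01());
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.u01();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0 ? ct : -ct);
  } else {
    double d = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / d + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / d + uy * ct;
    double nz = -st * cp * d + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// ---------------------------------------------------------------------------
// Shared tallies and probe description.

struct Probe {
  double src_radius, na, det_radius, spacing;
  int n_det;
  std::vector<double> det_x, det_y;
};

struct Tally {
  std::vector<double> det_w, det_w2;
  double specular = 0, diffuse = 0, transmitted = 0, absorbed = 0, roulette = 0;
  std::vector<double> ring_w;
  Tally(int n_det, int n_ring) : det_w(n_det, 0.0), det_w2(n_det, 0.0),
                                 ring_w(n_ring, 0.0) {}
};

// Photon escapes the top surface: book diffuse reflectance, annular tallies,
// and per-fiber NA-gated detection on the refracted exit direction.
static void book_escape(const Probe& probe, const NumericVector& ring_edges,
                        Tally& tal, double x, double y,
                        double sin_air, double w) {
  tal.diffuse += w;
  int n_ring = (int)tal.ring_w.size();
  if (n_ring > 0) {
    double rho = std::sqrt(x * x + y * y);
    for (int r = 0; r < n_ring; ++r) {
      if (rho >= ring_edges[r] && rho < ring_edges[r + 1]) { tal.ring_w[r] += w; break; }
    }
  }
  if (sin_air <= probe.na) {
    for (int d = 0; d < probe.n_det; ++d) {
      double dx = x - probe.det_x[d], dy = y - probe.det_y[d];
      if (dx * dx + dy * dy <= probe.det_radius * probe.det_radius) {
        tal.det_w[d] += w;
        tal.det_w2[d] += w * w;
        break;
      }
    }
  }
}

// Launch a photon: uniform over the source core, direction uniform in solid
// angle within the NA cone in air, Fresnel specular loss and refraction into
// the top medium (index n_top). Returns the starting weight.
static double launch(const Probe& probe, double n_ext, double n_top, SplitMix& rng,
                     Tally& tal, double& x, double& y, double& z,
                     double& ux, double& uy, double& uz) {
  double r = probe.src_radius * std::sqrt(rng.u01());
  double phi = 2.0 * M_PI * rng.u01();
  x = r * std::cos(phi);
  y = r * std::sin(phi);
  z = 0.0;
  double cos_max = std::sqrt(std::max(0.0, 1.0 - probe.na * probe.na));
  double ci = cos_max + (1.0 - cos_max) * rng.u01();  // uniform in solid angle
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double psi = 2.0 * M_PI * rng.u01();
  double rf = fresnel_unpol(n_ext, n_top, ci);
  tal.specular += rf;
  double w = 1.0 - rf;
  double st = si * n_ext / n_top;  // Snell refraction into the tissue
  double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
  ux = st * std::cos(psi);
  uy = st * std::sin(psi);
  uz = ct;
  return w;
}

static Probe make_probe(List probe) {
  Probe p;
  p.src_radius = as<double>(probe["core_radius_mm"]);
  p.det_radius = p.src_radius;
  p.na = as<double>(probe["na"]);
  p.spacing = as<double>(probe["spacing_mm"]);
  p.n_det = as<int>(probe["n_detectors"]);
  for (int d = 0; d < p.n_det; ++d) {
    double a = 2.0 * M_PI * d / p.n_det;
    p.det_x.push_back(p.spacing * std::cos(a));
    p.det_y.push_back(p.spacing * std::sin(a));
  }
  return p;
}

static List pack_result(const Tally& tal, int n_photons, double seed, bool any_ring) {
  int nd = (int)tal.det_w.size();
  NumericVector det(nd), det_se(nd);
  double N = (double)n_photons;
  for (int d = 0; d < nd; ++d) {
    det[d] = tal.det_w[d] / N;
    double var = (tal.det_w2[d] - tal.det_w[d] * tal.det_w[d] / N) / (N - 1.0);
    det_se[d] = std::sqrt(std::max(0.0, var / N));
  }
  List out = List::create(
    _["detector_fractions"] = det,
    _["detector_se"] = det_se,
    _["specular"] = tal.specular / N,
    _["diffuse_reflectance"] = tal.diffuse / N,
    _["transmittance"] = tal.transmitted / N,
    _["absorbed"] = tal.absorbed / N,
    _["roulette_lost"] = tal.roulette / N,
    _["n_photons"] = n_photons,
    _["seed"] = seed);
  if (any_ring) {
    NumericVector rw(tal.ring_w.size());
    for (size_t r = 0; r < tal.ring_w.size(); ++r) rw[r] = tal.ring_w[r] / N;
    out["ring_weights"] = rw;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Layered transport. Layers are slabs [z_top, z_bot) from the surface down;
// the terminal layer may be semi-infinite (z_bot = Inf). Internal interfaces
// apply Fresnel reflection/refraction only when the refractive index changes.

// [[Rcpp::export]]
List mc_run_layered_cpp(NumericVector z_bot, NumericVector mua, NumericVector mus,
                        NumericVector gg, NumericVector nn,
                        List probe, int n_photons, double seed,
                        NumericVector ring_edges, double w_min, double p_survive,
                        double max_steps, double n_ext) {
  int L = mua.size();
  Probe pr = make_probe(probe);
  int n_ring = std::max(0, (int)ring_edges.size() - 1);
  Tally tal(pr.n_det, n_ring);
  uint64_t run_seed = (uint64_t)seed;

  for (int ip = 0; ip < n_photons; ++ip) {
    SplitMix rng(mix_seed(run_seed, (uint64_t)ip + 1));
    double x, y, z, ux, uy, uz;
    double w = launch(pr, n_ext, nn[0], rng, tal, x, y, z, ux, uy, uz);
    int lay = 0;
    bool alive = true;
    double steps = 0.0;

    while (alive) {
      double s_od = -std::log(rng.u01());  // dimensionless optical depth
      while (s_od > 0.0 && alive) {
        if (++steps > max_steps) {  // safety cap; booked so the ledger stays closed
          tal.roulette += w;
          alive = false;
          break;
        }
        double mu_t = std::max(mua[lay] + mus[lay], 1e-12);
        double z_hi = (lay == 0) ? 0.0 : z_bot[lay - 1];
        double z_lo = z_bot[lay];
        double db;
        if (uz > 0.0)      db = (z_lo - z) / uz;
        else if (uz < 0.0) db = (z_hi - z) / uz;
        else               db = INF;
        if (db < 0.0) db = 0.0;
        double step = s_od / mu_t;

        if (db <= step) {  // reach a boundary first
          x += ux * db; y += uy * db;
          s_od -= db * mu_t;
          bool going_down = uz > 0.0;
          z = going_down ? z_lo : z_hi;
          if (!going_down && lay == 0) {
            // top surface: Fresnel against the external medium
            double ci = -uz;
            double rf = fresnel_unpol(nn[0], n_ext, ci);
            if (rng.u01() < rf) { uz = -uz; }
            else {
              double sin_air = std::sqrt(std::max(0.0, 1.0 - ci * ci)) * nn[0] / n_ext;
              book_escape(pr, ring_edges, tal, x, y, sin_air, w);
              alive = false;
            }
          } else if (going_down && !R_FINITE(z_lo)) {
            // cannot happen (db = Inf), kept for clarity
          } else if (going_down && lay == L - 1) {
            tal.transmitted += w;  // exits the finite bottom
            alive = false;
          } else {
            int nxt = going_down ? lay + 1 : lay - 1;
            if (nn[nxt] != nn[lay]) {
              double ci = std::fabs(uz);
              double rf = fresnel_unpol(nn[lay], nn[nxt], ci);
              if (rng.u01() < rf) { uz = -uz; }
              else {
                double ratio = nn[lay] / nn[nxt];
                double st2 = (1.0 - ci * ci) * ratio * ratio;
                double ct = std::sqrt(std::max(0.0, 1.0 - st2));
                ux *= ratio; uy *= ratio;
                uz = (uz > 0.0 ? ct : -ct);
                double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
                ux /= nrm; uy /= nrm; uz /= nrm;
                lay = nxt;
              }
            } else {
              lay = nxt;
            }
          }
        } else {  // interaction inside the layer
          x += ux * step; y += uy * step; z += uz * step;
          s_od = 0.0;
          double da = w * mua[lay] / mu_t;
          tal.absorbed += da;
          w -= da;
          spin(gg[lay], rng, ux, uy, uz);
          if (w < w_min) {  // Russian roulette, net weight change booked
            if (rng.u01() < p_survive) {
              tal.roulette -= w * (1.0 / p_survive - 1.0);
              w /= p_survive;
            } else {
              tal.roulette += w;
              alive = false;
            }
          }
        }
      }
    }
  }
  return pack_result(tal, n_photons, seed, n_ring > 0);
}

// ---------------------------------------------------------------------------
// Voxelized transport. Material index grid (nx*ny*nz, x fastest), uniform
// refractive index inside the volume (enforced by the R wrapper); lateral
// lookups clamp to the edge material, the bottom face transmits.

// [[Rcpp::export]]
List mc_run_voxel_cpp(IntegerVector grid, IntegerVector dims, double h,
                      NumericVector mua, NumericVector mus,
                      NumericVector gg, double n_in,
                      List probe, int n_photons, double seed,
                      NumericVector ring_edges, double w_min, double p_survive,
                      double max_steps, double n_ext) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double x0 = -0.5 * nx * h, y0 = -0.5 * ny * h;
  double z_max = nz * h;
  Probe pr = make_probe(probe);
  int n_ring = std::max(0, (int)ring_edges.size() - 1);
  Tally tal(pr.n_det, n_ring);
  uint64_t run_seed = (uint64_t)seed;
  const double eps = 1e-9;

  for (int ip = 0; ip < n_photons; ++ip) {
    SplitMix rng(mix_seed(run_seed, (uint64_t)ip + 1));
    double x, y, z, ux, uy, uz;
    double w = launch(pr, n_ext, n_in, rng, tal, x, y, z, ux, uy, uz);
    bool alive = true;
    double steps = 0.0;

    while (alive) {
      double s_od = -std::log(rng.u01());
      while (s_od > 0.0 && alive) {
        if (++steps > max_steps) { tal.roulette += w; alive = false; break; }
        // nudge along the flight direction so on-face positions index the
        // cell ahead
        double zn = z + uz * eps;
        if (zn < 0.0) {  // top surface
          double ci = -uz;
          double rf = fresnel_unpol(n_in, n_ext, ci);
          if (rng.u01() < rf) { uz = -uz; z = 0.0; continue; }
          double sin_air = std::sqrt(std::max(0.0, 1.0 - ci * ci)) * n_in / n_ext;
          book_escape(pr, ring_edges, tal, x, y, sin_air, w);
          alive = false;
          break;
        }
        if (zn >= z_max) { tal.transmitted += w; alive = false; break; }
        int iz = std::min(nz - 1, (int)std::floor(zn / h));
        int ix = (int)std::floor((x + ux * eps - x0) / h);
        int iy = (int)std::floor((y + uy * eps - y0) / h);
        if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
        if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;
        int m = grid[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * (size_t)iz)];
        double mu_t = std::max(mua[m] + mus[m], 1e-12);

        // distance to the nearest voxel face (non-positive -> not limiting)
        double db = INF, t;
        if (ux > 0.0) { t = (x0 + (ix + 1) * h - x) / ux; if (t > 0 && t < db) db = t; }
        else if (ux < 0.0) { t = (x0 + ix * h - x) / ux; if (t > 0 && t < db) db = t; }
        if (uy > 0.0) { t = (y0 + (iy + 1) * h - y) / uy; if (t > 0 && t < db) db = t; }
        else if (uy < 0.0) { t = (y0 + iy * h - y) / uy; if (t > 0 && t < db) db = t; }
        if (uz > 0.0) { t = ((iz + 1) * h - z) / uz; if (t > 0 && t < db) db = t; }
        else if (uz < 0.0) { t = (iz * h - z) / uz; if (t > 0 && t < db) db = t; }
        if (db < eps) db = eps;

        double step = s_od / mu_t;
        if (db <= step) {
          x += ux * db; y += uy * db; z += uz * db;
          s_od -= db * mu_t;
        } else {
          x += ux * step; y += uy * step; z += uz * step;
          s_od = 0.0;
          double da = w * mua[m] / mu_t;
          tal.absorbed += da;
          w -= da;
          spin(gg[m], rng, ux, uy, uz);
          if (w < w_min) {
            if (rng.u01() < p_survive) {
              tal.roulette -= w * (1.0 / p_survive - 1.0);
              w /= p_survive;
            } else {
              tal.roulette += w;
              alive = false;
            }
          }
        }
      }
    }
  }
  return pack_result(tal, n_photons, seed, n_ring > 0);
}
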