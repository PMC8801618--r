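// Voxelised Monte Carlo photon transport with photon-weight random walks:
// exponential step sampling on mu_t, Henyey-Greenstein scattering,
// absorption by weight attenuation, Russian-roulette termination and
// Fresnel partial reflection at the outer refractive boundary.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// xoshiro256** seeded through splitmix64: deterministic and platform
// independent, so a fixed seed gives bit-identical photon paths.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct Grid {
  int nx, ny, nz;
  double ox, oy, oz, h;
  const int* tissue;  // 0 = outside
  inline int idx(int i, int j, int k) const {
    return (k * ny + j) * nx + i;
  }
  inline int tissue_at(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return tissue[idx(i, j, k)];
  }
};

struct Kahan {
  double sum = 0.0, c = 0.0;
  inline void add(double x) {
    double y = x - c;
    double t = sum + y;
    c = (t - sum) - y;
    sum = t;
  }
};

inline double fresnel_unpol(double mu, double n_in, double n_out) {
  if (n_in == n_out) return 0.0;
  double sin_i2 = 1.0 - mu * mu;
  double sin_t2 = (n_in / n_out) * (n_in / n_out) * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;
  double mu_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_in * mu - n_out * mu_t) / (n_in * mu + n_out * mu_t);
  double rp = (n_in * mu_t - n_out * mu) / (n_in * mu_t + n_out * mu);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(IntegerVector tissue, IntegerVector dims, NumericVector origin,
                double voxel, NumericMatrix props, double n_outside,
                int n_photons, double seed, NumericVector src_center,
                double src_radius, double roulette_wmin,
                double roulette_psurv) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.h = voxel;
  g.tissue = INTEGER(tissue);
  const int ntis = props.nrow();  // rows: tissue id 1..ntis
  std::vector<double> mua(ntis), mus(ntis), gg(ntis), nn(ntis), mut(ntis);
  for (int i = 0; i < ntis; ++i) {
    mua[i] = props(i, 0); mus[i] = props(i, 1);
    gg[i] = props(i, 2); nn[i] = props(i, 3);
    mut[i] = mua[i] + mus[i];
  }
  Rng rng(static_cast<uint64_t>(seed));

  std::vector<double> absorbed(static_cast<size_t>(g.nx) * g.ny * g.nz, 0.0);
  std::vector<double> exit_x, exit_y, exit_z, exit_w, exit_ux, exit_uy,
      exit_uz;
  Kahan tot_absorbed, tot_exited, roulette_delta;
  const double eps = 1e-9 * voxel;

  for (int ph = 0; ph < n_photons; ++ph) {
    // launch: isotropic from a point uniform in the source sphere
    double px, py, pz;
    if (src_radius <= 0.0) {
      px = src_center[0]; py = src_center[1]; pz = src_center[2];
    } else {
      do {
        px = 2.0 * rng.unif() - 1.0;
        py = 2.0 * rng.unif() - 1.0;
        pz = 2.0 * rng.unif() - 1.0;
      } while (px * px + py * py + pz * pz > 1.0);
      px = src_center[0] + src_radius * px;
      py = src_center[1] + src_radius * py;
      pz = src_center[2] + src_radius * pz;
    }
    double cz = 2.0 * rng.unif() - 1.0;
    double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    double phi = 2.0 * M_PI * rng.unif();
    double ux = sz * std::cos(phi), uy = sz * std::sin(phi), uz = cz;
    double w = 1.0;

    int ci = static_cast<int>(std::floor((px - g.ox) / g.h));
    int cj = static_cast<int>(std::floor((py - g.oy) / g.h));
    int ck = static_cast<int>(std::floor((pz - g.oz) / g.h));
    int tis = g.tissue_at(ci, cj, ck);
    if (tis == 0) {  // source outside the medium: counts as exited
      tot_exited.add(w);
      exit_x.push_back(px); exit_y.push_back(py); exit_z.push_back(pz);
      exit_w.push_back(w);
      exit_ux.push_back(ux); exit_uy.push_back(uy); exit_uz.push_back(uz);
      continue;
    }

    bool alive = true;
    while (alive) {
      double tau = -std::log(rng.unif());  // dimensionless optical depth
      while (tau > 0.0) {
        double mt = mut[tis - 1];
        // distances to the voxel's three exit planes along u
        double vx0 = g.ox + ci * g.h, vy0 = g.oy + cj * g.h,
               vz0 = g.oz + ck * g.h;
        double dx = (ux > 0) ? (vx0 + g.h - px) / ux
                             : (ux < 0 ? (vx0 - px) / ux : 1e30);
        double dy = (uy > 0) ? (vy0 + g.h - py) / uy
                             : (uy < 0 ? (vy0 - py) / uy : 1e30);
        double dz = (uz > 0) ? (vz0 + g.h - pz) / uz
                             : (uz < 0 ? (vz0 - pz) / uz : 1e30);
        double dbound = std::min(dx, std::min(dy, dz));
        // identify the exit face before clamping: a slightly negative
        // distance (photon marginally past a face) must still cross that
        // same face, or the voxel index desynchronises from the position
        int face = (dbound == dx) ? 0 : (dbound == dy ? 1 : 2);
        if (dbound < 0) dbound = 0;
        double dstep = (mt > 0) ? tau / mt : 1e30;
        if (dstep < dbound) {
          // interaction inside this voxel
          px += ux * dstep; py += uy * dstep; pz += uz * dstep;
          tau = 0.0;
          if (mt <= 0.0) break;
          double dw = w * mua[tis - 1] / mt;
          absorbed[g.idx(ci, cj, ck)] += dw;
          tot_absorbed.add(dw);
          w -= dw;
          // Henyey-Greenstein scatter
          double ganis = gg[tis - 1];
          double ct;
          if (std::fabs(ganis) < 1e-8) {
            ct = 2.0 * rng.unif() - 1.0;
          } else {
            double f = (1.0 - ganis * ganis) /
                       (1.0 - ganis + 2.0 * ganis * rng.unif());
            ct = (1.0 + ganis * ganis - f * f) / (2.0 * ganis);
            if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
          }
          double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
          double ph2 = 2.0 * M_PI * rng.unif();
          double cp = std::cos(ph2), sp = std::sin(ph2);
          double nux, nuy, nuz;
          if (std::fabs(uz) > 0.99999) {
            nux = st * cp; nuy = st * sp; nuz = (uz > 0 ? ct : -ct);
          } else {
            double den = std::sqrt(1.0 - uz * uz);
            nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
            nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
            nuz = -st * cp * den + uz * ct;
          }
          double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
          ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
          // roulette
          if (w < roulette_wmin) {
            if (rng.unif() <= roulette_psurv) {
              roulette_delta.add(-w * (1.0 / roulette_psurv - 1.0));
              w /= roulette_psurv;
            } else {
              roulette_delta.add(w);
              alive = false;
              tau = 0.0;
            }
          }
        } else {
          // advance to the voxel face
          tau -= mt * dbound;
          px += ux * dbound; py += uy * dbound; pz += uz * dbound;
          int ni = ci, nj = cj, nk = ck;
          if (face == 0) ni += (ux > 0 ? 1 : -1);
          else if (face == 1) nj += (uy > 0 ? 1 : -1);
          else nk += (uz > 0 ? 1 : -1);
          int ntis2 = g.tissue_at(ni, nj, nk);
          if (ntis2 == 0) {
            // outer boundary: Fresnel partial reflection
            double n_in = nn[tis - 1];
            double mu = (face == 0) ? std::fabs(ux)
                       : (face == 1 ? std::fabs(uy) : std::fabs(uz));
            double R = fresnel_unpol(mu, n_in, n_outside);
            if (rng.unif() < R) {
              // specular reflection on the face
              if (face == 0) ux = -ux;
              else if (face == 1) uy = -uy;
              else uz = -uz;
              // nudge back inside the current voxel
              px += ux * eps; py += uy * eps; pz += uz * eps;
            } else {
              tot_exited.add(w);
              exit_x.push_back(px); exit_y.push_back(py); exit_z.push_back(pz);
              exit_w.push_back(w);
              exit_ux.push_back(ux); exit_uy.push_back(uy); exit_uz.push_back(uz);
              alive = false;
              tau = 0.0;
            }
          } else {
            ci = ni; cj = nj; ck = nk;
            tis = ntis2;
            // nudge across the face to avoid re-testing it
            px += ux * eps; py += uy * eps; pz += uz * eps;
          }
        }
        if (!alive) break;
      }
    }
    if ((ph & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
      _["exit"] = DataFrame::create(
          _["x"] = exit_x, _["y"] = exit_y, _["z"] = exit_z,
          _["w"] = exit_w, _["ux"] = exit_ux, _["uy"] = exit_uy,
          _["uz"] = exit_uz),
      _["total_absorbed"] = tot_absorbed.sum,
      _["total_exited"] = tot_exited.sum,
      _["roulette_delta"] = roulette_delta.sum,
      _["launched"] = static_cast<double>(n_photons));
}
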