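// Voxel-based Monte Carlo photon transport for layered head models.
//
// Geometry: labels on a regular voxel grid (edge `voxel` cm); the outer
// medium (index n_outer) occupies z < 0 above the grid's top face, and may
// also appear as embedded label-0 voxels (curved surfaces). Refraction occurs
// only where the refractive index changes (tissue<->outer, tissue<->sinus);
// index-matched tissue interfaces are crossed freely. Normals are voxel-face
// normals, so flat-slab physics is exact and curved surfaces are stair-step
// approximated.
//
// White mode records per-compartment pathlengths of detected photons so that
// reflectance at any absorption can be recovered afterwards through the
// microscopic Beer-Lambert law; absorbing mode carries a continuous
// exp(-mua*s) weight and scores reflectance directly.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// counter-based per-photon RNG: splitmix64-seeded xoroshiro128+, so photon i
// gets the same stream regardless of scheduling or batching
struct Rng {
  uint64_t s0, s1;
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0xD2B74407B1CE6E93ULL);
    s0 = splitmix(x);
    s1 = splitmix(x);
    if (!(s0 | s1)) s1 = 0x9E3779B97f4A7C15ULL;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = rotl(a, 55) ^ b ^ (b << 14);
    s1 = rotl(b, 36);
    return r;
  }
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double u01p() {
    double u;
    do { u = u01(); } while (u <= 0.0);
    return u;
  }
};

double fresnel_unpolarized(double n1, double n2, double cosi, double &cost) {
  double eta = n1 / n2;
  double sin2t = eta * eta * (1.0 - cosi * cosi);
  if (sin2t >= 1.0) { cost = 0.0; return 1.0; }  // total internal reflection
  cost = std::sqrt(1.0 - sin2t);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

void hg_scatter(Rng &rng, double g, double *d) {
  double ct;
  double u = rng.u01();
  if (std::fabs(g) < 1e-6) {
    ct = 2.0 * u - 1.0;
  } else {
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    ct = (1.0 + g * g - t * t) / (2.0 * g);
  }
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * rng.u01();
  double cp = std::cos(phi), sp = std::sin(phi);
  double dx = d[0], dy = d[1], dz = d[2];
  if (std::fabs(dz) > 0.99999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = (dz > 0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - dz * dz);
    d[0] = st * (dx * dz * cp - dy * sp) / den + dx * ct;
    d[1] = st * (dy * dz * cp + dx * sp) / den + dy * ct;
    d[2] = -st * cp * den + dz * ct;
  }
  double nn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= nn; d[1] /= nn; d[2] /= nn;
}

// direction uniform in solid angle within a cone of half-angle asin(sin_max)
// about `axis`
void cone_direction(Rng &rng, const double *axis, double sin_max, double *d) {
  double cos_min = std::sqrt(std::max(0.0, 1.0 - sin_max * sin_max));
  double ct = cos_min + (1.0 - cos_min) * rng.u01();
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.u01();
  double cp = std::cos(phi), sp = std::sin(phi);
  double az = axis[2];
  if (std::fabs(az) > 0.99999) {
    d[0] = st * cp; d[1] = st * sp; d[2] = (az > 0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - az * az);
    d[0] = st * (axis[0] * az * cp - axis[1] * sp) / den + axis[0] * ct;
    d[1] = st * (axis[1] * az * cp + axis[0] * sp) / den + axis[1] * ct;
    d[2] = -st * cp * den + az * ct;
  }
}

enum Fate { DETECTED = 0, ESCAPED_TOP = 1, ESCAPED_OTHER = 2,
            TERMINATED = 3, SPECULAR = 4 };

}  // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(IntegerVector labels, IntegerVector dims, double voxel,
                NumericVector mus_l, NumericVector g_l, NumericVector n_l,
                NumericVector mua_l, bool absorbing,
                NumericVector src_pos, NumericVector src_normal_in,
                double src_radius, double src_na, double n_outer,
                NumericMatrix det_info,  // cols: x,y,z,nx,ny,nz,radius,sds (cm)
                double det_na, int detect_mode,  // 0 discrete, 1 radial
                NumericVector annulus_hw,  // per detector, cm
                double n_photons, double seed,
                double path_cap, double att_max, bool terminate_on_exit,
                bool record_paths, double roulette_start,
                double roulette_step, double roulette_survival) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ndet = det_info.nrow();
  // compact uint8 copy of the label volume: cache-friendlier traversal
  std::vector<uint8_t> lab_u8(labels.size());
  for (R_xlen_t i = 0; i < labels.size(); i++)
    lab_u8[i] = (uint8_t)labels[i];
  const uint8_t *lab = lab_u8.data();
  const double v = voxel;
  const long long ntot = (long long)n_photons;
  const uint64_t sd = (uint64_t)seed;
  const double sin_acc2 = (det_na >= 1.0) ? 2.0 :
    (det_na / n_outer) * (det_na / n_outer);
  const double ln10 = std::log(10.0);

  std::vector<double> recs;  // det, pl1..pl5, angle, w0, wdet
  const int RCOL = 9;
  std::vector<long long> det_raw(ndet, 0);
  std::vector<double> det_sw(ndet, 0.0), det_sw2(ndet, 0.0);
  long long n_spec = 0, n_esc_top = 0, n_esc_other = 0, n_term = 0, n_det = 0;

  for (long long ip = 0; ip < ntot; ip++) {
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    Rng rng(sd, (uint64_t)ip);

    // launch on the source disc, direction within the launch NA cone
    double pos[3], d[3];
    {
      double r = src_radius * std::sqrt(rng.u01());
      double th = 2.0 * M_PI * rng.u01();
      // disc in the plane perpendicular to the inward normal
      double a[3] = {src_normal_in[0], src_normal_in[1], src_normal_in[2]};
      double t1[3], t2[3];
      if (std::fabs(a[2]) > 0.9) { t1[0] = 1; t1[1] = 0; t1[2] = 0; }
      else { t1[0] = 0; t1[1] = 0; t1[2] = 1; }
      double dot = t1[0] * a[0] + t1[1] * a[1] + t1[2] * a[2];
      for (int k = 0; k < 3; k++) t1[k] -= dot * a[k];
      double nn = std::sqrt(t1[0] * t1[0] + t1[1] * t1[1] + t1[2] * t1[2]);
      for (int k = 0; k < 3; k++) t1[k] /= nn;
      t2[0] = a[1] * t1[2] - a[2] * t1[1];
      t2[1] = a[2] * t1[0] - a[0] * t1[2];
      t2[2] = a[0] * t1[1] - a[1] * t1[0];
      for (int k = 0; k < 3; k++)
        pos[k] = src_pos[k] + r * (std::cos(th) * t1[k] + std::sin(th) * t2[k]);
      double sin_launch = (src_na >= 1.0) ? 1.0 : src_na / n_outer;
      cone_direction(rng, a, sin_launch, d);
    }
    const double launch_x = pos[0], launch_y = pos[1];

    int ix = (int)std::floor(pos[0] / v);
    int iy = (int)std::floor(pos[1] / v);
    int iz = (int)std::floor(pos[2] / v);
    if (iz < 0) iz = 0;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz >= nz) { n_esc_other++; continue; }

    int lbl = lab[ix + nx * (iy + (long long)ny * iz)];
    if (lbl != 0) {
      // launching straight into tissue: specular reflection at the fiber-
      // tissue interface (n_outer -> n_tissue) against the source normal
      double cosi = d[0] * src_normal_in[0] + d[1] * src_normal_in[1] +
                    d[2] * src_normal_in[2];
      if (cosi < 0) { n_esc_other++; continue; }
      double cost;
      double R = fresnel_unpolarized(n_outer, n_l[lbl], cosi, cost);
      if (rng.u01() < R) { n_spec++; continue; }
      // refract across the source normal
      double eta = n_outer / n_l[lbl];
      for (int k = 0; k < 3; k++)
        d[k] = eta * d[k] - (eta * cosi - cost) * src_normal_in[k];
    }

    double PL[7] = {0, 0, 0, 0, 0, 0, 0};
    double att = 0.0, total = 0.0, w0_mult = 1.0;
    double next_cp = roulette_start;
    double tau = -std::log(rng.u01p());
    bool alive = true;
    int fate = ESCAPED_OTHER;
    bool recorded = false;

    while (alive) {
      lbl = lab[ix + nx * (iy + (long long)ny * iz)];
      double mus = mus_l[lbl];
      double ss = (mus > 0) ? tau / mus : 1e30;

      // cheap no-crossing test: L-infinity distance to the voxel faces
      double lo0 = pos[0] - ix * v, lo1 = pos[1] - iy * v, lo2 = pos[2] - iz * v;
      double dmin = std::min(std::min(std::min(lo0, v - lo0),
                                      std::min(lo1, v - lo1)),
                             std::min(lo2, v - lo2));
      double tb = 1e30;
      int ax = -1, stp = 0;
      if (ss > dmin) {
        // exact distance to the nearest voxel face along d
        for (int a2 = 0; a2 < 3; a2++) {
          int idx = (a2 == 0 ? ix : (a2 == 1 ? iy : iz));
          double t;
          int s;
          if (d[a2] > 1e-12) { t = ((idx + 1) * v - pos[a2]) / d[a2]; s = 1; }
          else if (d[a2] < -1e-12) { t = (idx * v - pos[a2]) / d[a2]; s = -1; }
          else continue;
          if (t < tb) { tb = t; ax = a2; stp = s; }
        }
        if (tb < 0) tb = 0;
      }

      if (ss <= tb) {
        for (int k = 0; k < 3; k++) pos[k] += ss * d[k];
        PL[lbl] += ss; total += ss; att += mua_l[lbl] * ss;
        hg_scatter(rng, g_l[lbl], d);
        tau = -std::log(rng.u01p());
      } else {
        for (int k = 0; k < 3; k++) pos[k] += tb * d[k];
        PL[lbl] += tb; total += tb; att += mua_l[lbl] * tb;
        if (mus > 0) tau -= mus * tb;

        int jx = ix, jy = iy, jz = iz;
        if (ax == 0) jx += stp; else if (ax == 1) jy += stp; else jz += stp;
        bool outside = (jx < 0 || jx >= nx || jy < 0 || jy >= ny ||
                        jz < 0 || jz >= nz);
        double n2 = outside ? ((ax == 2 && stp < 0) ? n_outer : n_l[lbl])
                            : n_l[lab[jx + nx * (jy + (long long)ny * jz)]];
        bool exit_top = outside && ax == 2 && stp < 0;
        bool into_embedded_outer =
            !outside && lbl != 0 &&
            lab[jx + nx * (jy + (long long)ny * jz)] == 0;

        if (n2 != n_l[lbl]) {
          double cosi = std::fabs(d[ax]);
          double cost;
          double R = fresnel_unpolarized(n_l[lbl], n2, cosi, cost);
          if (rng.u01() < R) {
            d[ax] = -d[ax];  // stay in the current voxel
          } else {
            double eta = n_l[lbl] / n2;
            for (int k = 0; k < 3; k++) if (k != ax) d[k] *= eta;
            d[ax] = (stp > 0 ? cost : -cost);
            if (exit_top || into_embedded_outer) {
              // transmitted into the outer medium: detection test
              for (int dd = 0; dd < ndet; dd++) {
                double w0 = -1.0, cosq = 0.0;
                if (detect_mode == 1) {
                  double rx = pos[0] - launch_x, ry = pos[1] - launch_y;
                  double rho = std::sqrt(rx * rx + ry * ry);
                  double rdet = det_info(dd, 6), sds = det_info(dd, 7);
                  double hw = std::max(rdet, annulus_hw[dd]);
                  if (std::fabs(rho - sds) <= hw && sds > 0) {
                    w0 = rdet * rdet / (4.0 * sds * hw);
                    cosq = -d[2];
                  } else if (sds <= 0 && rho <= hw) {
                    w0 = 1.0; cosq = -d[2];
                  }
                } else {
                  double dx0 = pos[0] - det_info(dd, 0);
                  double dy0 = pos[1] - det_info(dd, 1);
                  double dz0 = pos[2] - det_info(dd, 2);
                  double rdet = det_info(dd, 6);
                  if (dx0 * dx0 + dy0 * dy0 + dz0 * dz0 <= rdet * rdet) {
                    w0 = 1.0;
                    cosq = d[0] * det_info(dd, 3) + d[1] * det_info(dd, 4) +
                           d[2] * det_info(dd, 5);
                  }
                }
                if (w0 > 0 && cosq > 0) {
                  double sin2 = 1.0 - cosq * cosq;
                  if (sin2 <= sin_acc2) {
                    w0 *= w0_mult;
                    double wdet = absorbing ? std::exp(-att) : 1.0;
                    det_raw[dd]++;
                    double w = w0 * wdet;
                    det_sw[dd] += w;
                    det_sw2[dd] += w * w;
                    if (record_paths) {
                      recs.push_back(dd + 1);
                      for (int l = 1; l <= 5; l++) recs.push_back(PL[l]);
                      double cq = cosq > 1.0 ? 1.0 : cosq;
                      recs.push_back(std::acos(cq));
                      recs.push_back(w0);
                      recs.push_back(wdet);
                    }
                    recorded = true;
                  }
                }
              }
              if (recorded) { fate = DETECTED; alive = false; }
              else if (exit_top || terminate_on_exit) {
                fate = ESCAPED_TOP; alive = false;
              } else {
                ix = jx; iy = jy; iz = jz;  // keep flying in embedded outer
              }
            } else {
              ix = jx; iy = jy; iz = jz;  // e.g. tissue <-> sinus
            }
          }
        } else if (outside) {
          fate = exit_top ? ESCAPED_TOP : ESCAPED_OTHER;
          alive = false;
        } else {
          ix = jx; iy = jy; iz = jz;
        }
      }

      if (alive && absorbing && att > att_max) {
        if (rng.u01() < 0.9) { fate = TERMINATED; alive = false; }
        else att -= ln10;
      }
      if (alive && total > next_cp) {
        // pathlength roulette: unbiased geometric termination of long
        // wanderers, compensated through the statistical weight
        if (rng.u01() < roulette_survival) {
          w0_mult /= roulette_survival;
          next_cp += roulette_step;
        } else { fate = TERMINATED; alive = false; }
      }
      if (alive && total > path_cap) { fate = TERMINATED; alive = false; }
    }

    switch (fate) {
      case DETECTED: n_det++; break;
      case ESCAPED_TOP: n_esc_top++; break;
      case ESCAPED_OTHER: n_esc_other++; break;
      case TERMINATED: n_term++; break;
      default: break;
    }
  }

  NumericMatrix rec_mat(recs.size() / RCOL, RCOL);
  for (size_t i = 0; i < recs.size(); i++) rec_mat[i % RCOL * rec_mat.nrow() + i / RCOL] = recs[i];
  colnames(rec_mat) = CharacterVector::create(
      "det", "pl_scalp", "pl_skull", "pl_csf", "pl_gm", "pl_wm",
      "exit_angle", "w0", "wdet");

  return List::create(
      _["records"] = rec_mat,
      _["n_total"] = (double)ntot,
      _["det_raw"] = NumericVector(det_raw.begin(), det_raw.end()),
      _["det_sum_w"] = NumericVector(det_sw.begin(), det_sw.end()),
      _["det_sum_w2"] = NumericVector(det_sw2.begin(), det_sw2.end()),
      _["n_specular"] = (double)n_spec,
      _["n_escaped_top"] = (double)n_esc_top,
      _["n_escaped_other"] = (double)n_esc_other,
      _["n_terminated"] = (double)n_term,
      _["n_detected"] = (double)n_det);
}
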