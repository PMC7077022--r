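#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simplified divergent pencil-beam kernel.
//
// For one field, casts one ray per beamlet (from the source through the
// beamlet centre on the isocenter plane; in parallel test mode, along the
// central axis through the beamlet centre) and deposits, at every body voxel
// within the lateral Gaussian cutoff of the ray,
//   d = (sad / dist_source_voxel)^2 * exp(-mu * radiological_depth) * G(r)
// where radiological depth is the in-body path length from grid entry to the
// voxel's axial position (uniform ray stepping at half the minimum voxel
// spacing, linear interpolation between step edges) and G is a Gaussian of
// the perpendicular distance r to the ray with unit peak. In parallel mode
// the inverse-square factor is dropped.
//
// Returns triplets (body-voxel row, beamlet column, dose per unit weight).

// [[Rcpp::export]]
List beamlet_influence_cpp(NumericVector origin, NumericVector spacing,
                           IntegerVector shape, LogicalVector body,
                           NumericMatrix body_xyz, NumericVector source,
                           NumericVector axis_dir, NumericMatrix beamlet_xyz,
                           double sad, double mu, double sigma,
                           bool parallel, double rel_cutoff,
                           NumericVector density) {
  // density: optional relative-density volume (same layout as body);
  // length 0 means water-equivalent body (density 1 inside, 0 outside)
  const bool has_density = density.size() > 0;
  const int n1 = shape[0], n2 = shape[1], n3 = shape[2];
  const int nvox = body_xyz.nrow();
  const int nb = beamlet_xyz.nrow();
  const double dt = 0.5 * std::min(spacing[0], std::min(spacing[1], spacing[2]));
  const double r2cut = -2.0 * sigma * sigma * std::log(rel_cutoff);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  // grid bounding box (outer voxel faces)
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (shape[a] - 0.5) * spacing[a];
  }

  std::vector<int> ti, tj;
  std::vector<double> tx;
  std::vector<double> cum; // cumulative radiological depth at step edges

  for (int b = 0; b < nb; ++b) {
    double o[3], d[3];
    if (parallel) {
      double far = 2.0 * sad;
      for (int a = 0; a < 3; ++a) {
        d[a] = axis_dir[a];
        o[a] = beamlet_xyz(b, a) - far * d[a];
      }
    } else {
      double nrm = 0.0;
      for (int a = 0; a < 3; ++a) {
        o[a] = source[a];
        d[a] = beamlet_xyz(b, a) - source[a];
        nrm += d[a] * d[a];
      }
      nrm = std::sqrt(nrm);
      for (int a = 0; a < 3; ++a) d[a] /= nrm;
    }

    // slab intersection with the grid bbox
    double tmin = 0.0, tmax = 1e300;
    bool miss = false;
    for (int a = 0; a < 3 && !miss; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (o[a] < lo[a] || o[a] > hi[a]) miss = true;
      } else {
        double t0 = (lo[a] - o[a]) / d[a], t1 = (hi[a] - o[a]) / d[a];
        if (t0 > t1) std::swap(t0, t1);
        if (t0 > tmin) tmin = t0;
        if (t1 < tmax) tmax = t1;
        if (tmin > tmax) miss = true;
      }
    }
    if (miss) continue;

    const int ns = (int)std::ceil((tmax - tmin) / dt);
    cum.assign(ns + 1, 0.0);
    for (int k = 0; k < ns; ++k) {
      double t = tmin + (k + 0.5) * dt;
      double p0 = o[0] + t * d[0], p1 = o[1] + t * d[1], p2 = o[2] + t * d[2];
      int i0 = (int)std::lround((p0 - origin[0]) / spacing[0]);
      int i1 = (int)std::lround((p1 - origin[1]) / spacing[1]);
      int i2 = (int)std::lround((p2 - origin[2]) / spacing[2]);
      double rho = 0.0;
      if (i0 >= 0 && i0 < n1 && i1 >= 0 && i1 < n2 && i2 >= 0 && i2 < n3) {
        R_xlen_t lin = i0 + (R_xlen_t)n1 * (i1 + (R_xlen_t)n2 * i2);
        if (body[lin]) rho = has_density ? density[lin] : 1.0;
      }
      cum[k + 1] = cum[k] + rho * dt;
    }

    for (int v = 0; v < nvox; ++v) {
      double vx = body_xyz(v, 0) - o[0];
      double vy = body_xyz(v, 1) - o[1];
      double vz = body_xyz(v, 2) - o[2];
      double t = vx * d[0] + vy * d[1] + vz * d[2];
      if (t <= 0.0) continue;
      double vv = vx * vx + vy * vy + vz * vz;
      double r2 = vv - t * t;
      if (r2 < 0.0) r2 = 0.0;
      if (r2 > r2cut) continue;
      // radiological depth at axial position t
      double depth;
      if (t <= tmin) depth = 0.0;
      else if (t >= tmax) depth = cum[ns];
      else {
        double u = (t - tmin) / dt;
        int k = (int)u;
        if (k >= ns) k = ns - 1;
        depth = cum[k] + (u - k) * (cum[k + 1] - cum[k]);
      }
      double dose = std::exp(-mu * depth - r2 * inv2s2);
      if (!parallel) dose *= (sad * sad) / vv;
      if (dose <= 0.0 || !std::isfinite(dose)) continue;
      ti.push_back(v + 1);
      tj.push_back(b + 1);
      tx.push_back(dose);
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}
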