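#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Sequential rejection packing of non-overlapping spheres in a cylinder lumen.
//
// Cylinder axis along x, lumen radius Ri, segment x in [0, L].  Centres are
// proposed uniformly in the lumen bounding box using R's RNG (so results are
// reproducible under set.seed()); proposals protruding through the wall or
// overlapping an accepted sphere are rejected.  A linked cell list keeps the
// overlap test O(1) per proposal at dilute volume fractions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List pack_spheres_cpp(NumericVector r, double Ri, double L, int max_try) {
  const int n = r.size();
  NumericVector x(n), y(n), z(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  if (rmax >= Ri)
    stop("a sphere radius (%.4g mm) exceeds the lumen radius", rmax);

  const double h = std::max(2.0 * rmax, 1e-6);
  const int nx = std::max(1, (int)std::ceil(L / h));
  const int ny = std::max(1, (int)std::ceil(2.0 * Ri / h));
  const int nz = ny;
  std::vector<int> head((size_t)nx * ny * nz, -1);
  std::vector<int> nxt(n, -1);

  auto cell_of = [&](double px, double py, double pz) {
    int cx = std::min(nx - 1, std::max(0, (int)(px / h)));
    int cy = std::min(ny - 1, std::max(0, (int)((py + Ri) / h)));
    int cz = std::min(nz - 1, std::max(0, (int)((pz + Ri) / h)));
    return (size_t)(cx * ny + cy) * nz + cz;
  };

  for (int i = 0; i < n; ++i) {
    const double ri = r[i];
    const double rad = Ri - ri;  // centre must stay this far from the axis
    bool placed = false;
    for (int t = 0; t < max_try; ++t) {
      const double px = R::runif(0.0, L);
      const double py = R::runif(-Ri, Ri);
      const double pz = R::runif(-Ri, Ri);
      if (py * py + pz * pz > rad * rad) continue;  // wall protrusion
      // neighbour search
      int cx = std::min(nx - 1, std::max(0, (int)(px / h)));
      int cy = std::min(ny - 1, std::max(0, (int)((py + Ri) / h)));
      int cz = std::min(nz - 1, std::max(0, (int)((pz + Ri) / h)));
      bool overlap = false;
      for (int ax = std::max(0, cx - 1); ax <= std::min(nx - 1, cx + 1) && !overlap; ++ax)
        for (int ay = std::max(0, cy - 1); ay <= std::min(ny - 1, cy + 1) && !overlap; ++ay)
          for (int az = std::max(0, cz - 1); az <= std::min(nz - 1, cz + 1) && !overlap; ++az) {
            for (int j = head[(size_t)(ax * ny + ay) * nz + az]; j >= 0; j = nxt[j]) {
              const double dx = px - x[j], dy = py - y[j], dz = pz - z[j];
              const double s = ri + r[j];
              if (dx * dx + dy * dy + dz * dz < s * s) { overlap = true; break; }
            }
          }
      if (overlap) continue;
      x[i] = px; y[i] = py; z[i] = pz;
      size_t c = cell_of(px, py, pz);
      nxt[i] = head[c];
      head[c] = i;
      placed = true;
      break;
    }
    if (!placed)
      stop("failed to place sphere %d of %d after %d attempts; "
           "concentration too high for rejection packing", i + 1, n, max_try);
  }
  return List::create(_["x"] = x, _["y"] = y, _["z"] = z);
}

// ---------------------------------------------------------------------------
// Ray-optics trace of parallel rays (along +z) through the vessel phantom.
//
// For each ray at entrance position (x, y):
//   * attenuation: analytic chord lengths through the nylon wall, the water
//     lumen and any gas spheres hit, multiplied as exp(-sum mu_i * l_i);
//   * refraction: at every interface crossing the ray picks up a small-angle
//     deviation (delta_next - delta_prev) * tan(theta_inc); only the
//     component in the analyser diffraction plane (y-z) is accumulated,
//     since the crystal is insensitive to deviations out of that plane.
//     For a full sphere traversal at impact parameter b this sums to the
//     closed form 2*(delta_in - delta_out)*b/sqrt(r^2-b^2), directed toward
//     the sphere axis for a gas bubble in water (a converging x-ray lens).
//
// Straight-line geometry is used for intersection finding: microradian
// deviations displace the ray by far less than a pixel over the phantom
// depth, so deflections are accumulated without re-steering.
// ---------------------------------------------------------------------------

// [[Rcpp::export(rng = false)]]
List trace_rays_cpp(NumericVector ray_x, NumericVector ray_y,
                    NumericVector sx, NumericVector sy, NumericVector sr,
                    double Ri, double Ro, double L,
                    double mu_wall, double mu_lumen, double mu_gas,
                    double delta_wall, double delta_lumen, double delta_gas,
                    double delta_ambient) {
  const int nray = ray_x.size();
  const int nsph = sx.size();
  NumericVector weight(nray), defl(nray);

  // 2D cell list over (x, y): a ray at (x, y) can only hit spheres whose
  // centre lies within rmax of it in the x-y plane
  double rmax = 0.0;
  for (int i = 0; i < nsph; ++i) rmax = std::max(rmax, sr[i]);
  const double h = std::max(rmax, 0.01);  // empty pack: trivial grid
  const int nx = std::max(1, (int)std::ceil(L / h));
  const int ny = std::max(1, (int)std::ceil(2.0 * Ri / h));
  std::vector<int> head((size_t)nx * ny, -1);
  std::vector<int> nxt(nsph, -1);
  for (int i = 0; i < nsph; ++i) {
    int cx = std::min(nx - 1, std::max(0, (int)(sx[i] / h)));
    int cy = std::min(ny - 1, std::max(0, (int)((sy[i] + Ri) / h)));
    size_t c = (size_t)cx * ny + cy;
    nxt[i] = head[c];
    head[c] = i;
  }

  const double eps = 1e-9;
  for (int k = 0; k < nray; ++k) {
    const double px = ray_x[k], py = ray_y[k];
    double w = 1.0, dth = 0.0;  // dth in radians, y-component
    const double y2 = py * py;

    if (std::fabs(py) < Ro) {
      const double co = std::sqrt(std::max(Ro * Ro - y2, eps * eps));
      if (std::fabs(py) < Ri) {
        const double ci = std::sqrt(std::max(Ri * Ri - y2, eps * eps));
        double wall = 2.0 * (co - ci);
        double lumen = 2.0 * ci;
        double gas = 0.0;
        // sphere hits via the cell list (3x3 neighbourhood)
        int cx = std::min(nx - 1, std::max(0, (int)(px / h)));
        int cy = std::min(ny - 1, std::max(0, (int)((py + Ri) / h)));
        for (int ax = std::max(0, cx - 1); ax <= std::min(nx - 1, cx + 1); ++ax)
          for (int ay = std::max(0, cy - 1); ay <= std::min(ny - 1, cy + 1); ++ay)
            for (int j = head[(size_t)ax * ny + ay]; j >= 0; j = nxt[j]) {
              const double dx = px - sx[j], dy = py - sy[j];
              const double b2 = dx * dx + dy * dy;
              const double r2 = sr[j] * sr[j];
              if (b2 >= r2) continue;
              const double half = std::sqrt(r2 - b2);
              gas += 2.0 * half;
              // entry + exit refraction, diffraction-plane component;
              // guard the grazing limit
              if (half > 1e-7)
                dth += 2.0 * (delta_gas - delta_lumen) * dy / half;
            }
        if (gas > lumen) gas = lumen;  // cannot exceed the water chord
        w = std::exp(-(mu_wall * wall + mu_lumen * (lumen - gas) +
                       mu_gas * gas));
        // cylinder-wall refraction (outer and inner interfaces, both sides)
        dth += 2.0 * (delta_wall - delta_ambient) * py / co;
        dth += 2.0 * (delta_lumen - delta_wall) * py / ci;
      } else {
        // ray crosses the wall annulus only
        w = std::exp(-mu_wall * 2.0 * co);
        dth += 2.0 * (delta_wall - delta_ambient) * py / co;
      }
    }
    weight[k] = w;
    defl[k] = dth * 1e6;  // radians -> microradian
  }
  return List::create(_["weight"] = weight, _["defl_urad"] = defl);
}
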