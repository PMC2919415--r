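#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Monte-Carlo projection areas of a union of spheres.
//
// For each of n_rot uniformly random orientations (quaternion method, R's
// RNG so set.seed() controls the draw) the spheres are projected onto the
// viewing plane and the area of the union of disks is estimated by uniform
// point sampling over the tight bounding box of the projection.  Returns the
// per-orientation areas; mean and between-orientation spread are taken in R.
//
// Hit testing is pruned by sorting projected centres on x and only checking
// disks whose x-interval can contain the sample point.
// [[Rcpp::export]]
NumericVector pa_projection_areas(NumericMatrix centers, NumericVector radii,
                                  int n_rot, int n_points) {
  const int n = centers.nrow();
  if (n < 1) stop("no spheres");
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!(radii[i] > 0.0)) stop("all radii must be positive");
    if (radii[i] > rmax) rmax = radii[i];
  }

  NumericVector areas(n_rot);
  std::vector<double> px(n), py(n), pr(n), sx(n);
  std::vector<int> ord(n);

  for (int rot = 0; rot < n_rot; ++rot) {
    // uniform random rotation from a normalized 4-normal quaternion
    double q0 = norm_rand(), q1 = norm_rand(), q2 = norm_rand(), q3 = norm_rand();
    double qn = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
    q0 /= qn; q1 /= qn; q2 /= qn; q3 /= qn;
    // first two rows of the rotation matrix give the projection
    const double r00 = 1.0 - 2.0 * (q2 * q2 + q3 * q3);
    const double r01 = 2.0 * (q1 * q2 - q0 * q3);
    const double r02 = 2.0 * (q1 * q3 + q0 * q2);
    const double r10 = 2.0 * (q1 * q2 + q0 * q3);
    const double r11 = 1.0 - 2.0 * (q1 * q1 + q3 * q3);
    const double r12 = 2.0 * (q2 * q3 - q0 * q1);

    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
      px[i] = r00 * cx + r01 * cy + r02 * cz;
      py[i] = r10 * cx + r11 * cy + r12 * cz;
      pr[i] = radii[i];
      xmin = std::min(xmin, px[i] - pr[i]);
      xmax = std::max(xmax, px[i] + pr[i]);
      ymin = std::min(ymin, py[i] - pr[i]);
      ymax = std::max(ymax, py[i] + pr[i]);
    }

    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return px[a] < px[b]; });
    for (int i = 0; i < n; ++i) sx[i] = px[ord[i]];

    const double wx = xmax - xmin, wy = ymax - ymin;
    int hits = 0;
    for (int p = 0; p < n_points; ++p) {
      const double x = xmin + unif_rand() * wx;
      const double y = ymin + unif_rand() * wy;
      // disks with |px - x| > rmax cannot contain (x, y)
      int lo = std::lower_bound(sx.begin(), sx.end(), x - rmax) - sx.begin();
      int hi = std::upper_bound(sx.begin(), sx.end(), x + rmax) - sx.begin();
      for (int k = lo; k < hi; ++k) {
        const int i = ord[k];
        const double dx = px[i] - x, dy = py[i] - y;
        if (dx * dx + dy * dy <= pr[i] * pr[i]) { ++hits; break; }
      }
    }
    areas[rot] = (static_cast<double>(hits) / n_points) * wx * wy;
  }
  return areas;
}
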