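// Exact planar geometry kernels for circular-buffer predictor extraction.
// All coordinates are projected meters; disks are closed (distance <= radius).

#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// length of the part of segment (x0,y0)-(x1,y1) inside the closed disk
// centered at (cx,cy) with radius r, via the quadratic |P + tD - C|^2 = r^2
inline double seg_len_in_disk(double x0, double y0, double x1, double y1,
                              double cx, double cy, double r) {
  const double dx = x1 - x0, dy = y1 - y0;
  const double fx = x0 - cx, fy = y0 - cy;
  const double a = dx * dx + dy * dy;
  const double seglen = std::sqrt(a);
  if (a == 0.0) return 0.0;  // degenerate segment carries no length
  const double b = 2.0 * (fx * dx + fy * dy);
  const double c = fx * fx + fy * fy - r * r;
  const double disc = b * b - 4.0 * a * c;
  if (disc <= 0.0) return 0.0;  // line misses (or grazes) the disk
  const double sq = std::sqrt(disc);
  double t1 = (-b - sq) / (2.0 * a);
  double t2 = (-b + sq) / (2.0 * a);
  t1 = std::max(t1, 0.0);
  t2 = std::min(t2, 1.0);
  if (t2 <= t1) return 0.0;
  return (t2 - t1) * seglen;
}

inline double pt_seg_dist(double px, double py, double x0, double y0,
                          double x1, double y1) {
  const double dx = x1 - x0, dy = y1 - y0;
  const double a = dx * dx + dy * dy;
  double t = 0.0;
  if (a > 0.0) {
    t = ((px - x0) * dx + (py - y0) * dy) / a;
    t = std::min(1.0, std::max(0.0, t));
  }
  const double ex = x0 + t * dx - px, ey = y0 + t * dy - py;
  return std::sqrt(ex * ex + ey * ey);
}

// Liang-Barsky: does the segment intersect the axis-aligned rectangle?
inline bool seg_intersects_rect(double x0, double y0, double x1, double y1,
                                double xmin, double ymin, double xmax,
                                double ymax) {
  double t0 = 0.0, t1 = 1.0;
  const double dx = x1 - x0, dy = y1 - y0;
  const double p[4] = {-dx, dx, -dy, dy};
  const double q[4] = {x0 - xmin, xmax - x0, y0 - ymin, ymax - y0};
  for (int i = 0; i < 4; ++i) {
    if (p[i] == 0.0) {
      if (q[i] < 0.0) return false;  // parallel and outside
    } else {
      const double t = q[i] / p[i];
      if (p[i] < 0.0) {
        if (t > t1) return false;
        if (t > t0) t0 = t;
      } else {
        if (t < t0) return false;
        if (t < t1) t1 = t;
      }
    }
  }
  return true;
}

}  // namespace

// segs: n x 4 matrix (x0, y0, x1, y1); returns centers x radii length sums
// [[Rcpp::export]]
NumericMatrix cpp_line_lengths(NumericMatrix segs, NumericMatrix centers,
                               NumericVector radii) {
  const int ns = segs.nrow(), nc = centers.nrow(), nr = radii.size();
  NumericMatrix out(nc, nr);
  const double rmax = nr ? *std::max_element(radii.begin(), radii.end()) : 0.0;
  for (int i = 0; i < nc; ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1);
    for (int s = 0; s < ns; ++s) {
      // cheap reject on the largest radius
      if (pt_seg_dist(cx, cy, segs(s, 0), segs(s, 1), segs(s, 2), segs(s, 3)) >
          rmax)
        continue;
      for (int k = 0; k < nr; ++k)
        out(i, k) += seg_len_in_disk(segs(s, 0), segs(s, 1), segs(s, 2),
                                     segs(s, 3), cx, cy, radii[k]);
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_point_counts(NumericMatrix points, NumericMatrix centers,
                               NumericVector radii) {
  const int np = points.nrow(), nc = centers.nrow(), nr = radii.size();
  IntegerMatrix out(nc, nr);
  for (int i = 0; i < nc; ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1);
    for (int p = 0; p < np; ++p) {
      const double dx = points(p, 0) - cx, dy = points(p, 1) - cy;
      const double d2 = dx * dx + dy * dy;
      for (int k = 0; k < nr; ++k)
        if (d2 <= radii[k] * radii[k]) out(i, k) += 1;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_min_dist_to_segments(NumericMatrix centers,
                                       NumericMatrix segs) {
  const int nc = centers.nrow(), ns = segs.nrow();
  NumericVector out(nc);
  for (int i = 0; i < nc; ++i) {
    double best = R_PosInf;
    for (int s = 0; s < ns; ++s) {
      const double d = pt_seg_dist(centers(i, 0), centers(i, 1), segs(s, 0),
                                   segs(s, 1), segs(s, 2), segs(s, 3));
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Mean of raster cells whose centers fall in the disk. values is the grid
// matrix (row 1 = southernmost row); cell centers at xmin + (col-0.5)*cell.
// Returns means (NaN where the disk holds no cell center) and cell counts.
// [[Rcpp::export]]
List cpp_raster_mean_in_disk(NumericMatrix values, double xmin, double ymin,
                             double cell, NumericMatrix centers, double radius) {
  const int nrow = values.nrow(), ncol = values.ncol(), nc = centers.nrow();
  NumericVector means(nc);
  IntegerVector counts(nc);
  const double r2 = radius * radius;
  for (int i = 0; i < nc; ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1);
    int jlo = std::max(0, (int)std::floor((cx - radius - xmin) / cell));
    int jhi = std::min(ncol - 1, (int)std::floor((cx + radius - xmin) / cell));
    int ilo = std::max(0, (int)std::floor((cy - radius - ymin) / cell));
    int ihi = std::min(nrow - 1, (int)std::floor((cy + radius - ymin) / cell));
    double sum = 0.0;
    int k = 0;
    for (int ii = ilo; ii <= ihi; ++ii) {
      const double yy = ymin + (ii + 0.5) * cell - cy;
      for (int jj = jlo; jj <= jhi; ++jj) {
        const double xx = xmin + (jj + 0.5) * cell - cx;
        if (xx * xx + yy * yy <= r2) {
          sum += values(ii, jj);
          ++k;
        }
      }
    }
    means[i] = k ? sum / k : R_NaReal;
    counts[i] = k;
  }
  return List::create(_["mean"] = means, _["n_cells"] = counts);
}

// Per-class cell-center counts in the disk for a categorical grid with
// integer codes 1..n_classes.
// [[Rcpp::export]]
IntegerMatrix cpp_class_counts_in_disk(IntegerMatrix codes, int n_classes,
                                       double xmin, double ymin, double cell,
                                       NumericMatrix centers, double radius) {
  const int nrow = codes.nrow(), ncol = codes.ncol(), nc = centers.nrow();
  IntegerMatrix out(nc, n_classes);
  const double r2 = radius * radius;
  for (int i = 0; i < nc; ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1);
    int jlo = std::max(0, (int)std::floor((cx - radius - xmin) / cell));
    int jhi = std::min(ncol - 1, (int)std::floor((cx + radius - xmin) / cell));
    int ilo = std::max(0, (int)std::floor((cy - radius - ymin) / cell));
    int ihi = std::min(nrow - 1, (int)std::floor((cy + radius - ymin) / cell));
    for (int ii = ilo; ii <= ihi; ++ii) {
      const double yy = ymin + (ii + 0.5) * cell - cy;
      for (int jj = jlo; jj <= jhi; ++jj) {
        const double xx = xmin + (jj + 0.5) * cell - cx;
        if (xx * xx + yy * yy <= r2) {
          const int cls = codes(ii, jj);
          if (cls >= 1 && cls <= n_classes) out(i, cls - 1) += 1;
        }
      }
    }
  }
  return out;
}

// For each square cell (center, half-width), TRUE if any segment intersects it.
// [[Rcpp::export]]
LogicalVector cpp_any_segment_in_cell(NumericMatrix segs, NumericMatrix centers,
                                      double half) {
  const int nc = centers.nrow(), ns = segs.nrow();
  LogicalVector out(nc);
  for (int i = 0; i < nc; ++i) {
    const double xmin = centers(i, 0) - half, xmax = centers(i, 0) + half;
    const double ymin = centers(i, 1) - half, ymax = centers(i, 1) + half;
    bool hit = false;
    for (int s = 0; s < ns && !hit; ++s)
      hit = seg_intersects_rect(segs(s, 0), segs(s, 1), segs(s, 2), segs(s, 3),
                                xmin, ymin, xmax, ymax);
    out[i] = hit;
  }
  return out;
}
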