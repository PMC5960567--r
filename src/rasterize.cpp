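#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Silhouette rasterization over a pixel window.
//
// Pixel centers sit at integer coordinates (0-based, x right / y down); the
// window covers centers x in [x0, x0+w-1], y in [y0, y0+h-1]. A pixel is lit
// iff its center lies inside (or exactly on an edge of) the projection of at
// least one triangle: the silhouette is a union, so no depth buffer and no
// back-face culling. Edge rule is inclusive (e >= 0 after orienting each
// triangle counter-clockwise), which is deterministic and seam-free under OR.
//
// vx, vy: projected vertex coordinates in continuous pixel units (full-image
// frame); faces: 3 x M matrix of 0-based vertex indices.
template <typename OUT>
static void rasterize_into(OUT& out, const NumericVector& vx,
                           const NumericVector& vy,
                           const IntegerMatrix& faces,
                           int x0, int y0, int w, int h);

// [[Rcpp::export(name = ".rasterize_cpp")]]
IntegerMatrix rasterize_cpp(NumericVector vx, NumericVector vy,
                            IntegerMatrix faces,
                            int x0, int y0, int w, int h) {
  if (w < 0 || h < 0) stop("window dimensions must be non-negative");
  IntegerMatrix out(h, w);
  struct Sink {
    IntegerMatrix& m; int h;
    void set(int i, int j) { m(i, j) = 1; }
  } sink{out, h};
  rasterize_into(sink, vx, vy, faces, x0, y0, w, h);
  return out;
}

// fast path for the registration inner loop: the window raster flattened
// column-major (equivalently: as.numeric of the matrix version), as doubles
// ready for residual arithmetic
// [[Rcpp::export(name = ".rasterize_vec_cpp")]]
NumericVector rasterize_vec_cpp(NumericVector vx, NumericVector vy,
                                IntegerMatrix faces,
                                int x0, int y0, int w, int h) {
  if (w < 0 || h < 0) stop("window dimensions must be non-negative");
  NumericVector out((R_xlen_t)w * h);
  struct Sink {
    double* p; int h;
    void set(int i, int j) { p[(R_xlen_t)j * h + i] = 1.0; }
  } sink{REAL(out), h};
  rasterize_into(sink, vx, vy, faces, x0, y0, w, h);
  return out;
}

template <typename OUT>
static void rasterize_into(OUT& out, const NumericVector& vx,
                           const NumericVector& vy,
                           const IntegerMatrix& faces,
                           int x0, int y0, int w, int h) {
  const int m = faces.ncol();
  const R_xlen_t nv = vx.size();

  for (int t = 0; t < m; ++t) {
    int i0 = faces(0, t), i1 = faces(1, t), i2 = faces(2, t);
    if (i0 < 0 || i1 < 0 || i2 < 0 || i0 >= nv || i1 >= nv || i2 >= nv)
      stop("face index out of range");
    double ax = vx[i0], ay = vy[i0];
    double bx = vx[i1], by = vy[i1];
    double cx = vx[i2], cy = vy[i2];

    // orient CCW (in x-right / y-down coordinates a positive signed area
    // after this swap means the inclusive test is e >= 0 on all edges)
    double area2 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (area2 == 0.0) continue;  // degenerate: contributes no pixels
    if (area2 < 0.0) { std::swap(bx, cx); std::swap(by, cy); }

    // bounding box in window-local pixel indices
    double minx = std::min(ax, std::min(bx, cx));
    double maxx = std::max(ax, std::max(bx, cx));
    double miny = std::min(ay, std::min(by, cy));
    double maxy = std::max(ay, std::max(by, cy));
    int jlo = std::max(0, (int)std::ceil(minx - x0));
    int jhi = std::min(w - 1, (int)std::floor(maxx - x0));
    int ilo = std::max(0, (int)std::ceil(miny - y0));
    int ihi = std::min(h - 1, (int)std::floor(maxy - y0));
    if (jlo > jhi || ilo > ihi) continue;

    for (int i = ilo; i <= ihi; ++i) {
      double py = (double)(y0 + i);
      for (int j = jlo; j <= jhi; ++j) {
        // direct (non-incremental) edge evaluation keeps the inclusive
        // edge rule exact for pixel centers lying on an edge
        double px = (double)(x0 + j);
        double e0 = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
        if (e0 < 0.0) continue;
        double e1 = (cx - bx) * (py - by) - (cy - by) * (px - bx);
        if (e1 < 0.0) continue;
        double e2 = (ax - cx) * (py - cy) - (ay - cy) * (px - cx);
        if (e2 >= 0.0) out.set(i, j);
      }
    }
  }
}
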