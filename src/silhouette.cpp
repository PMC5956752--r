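#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pixel convention: image stored as an ny x nx integer matrix, mask(i, j)
// with 1-based row i (y) and column j (x); the centre of pixel (i, j) sits
// at continuous coordinates (x, y) = (j - 0.5, i - 0.5), so the image
// occupies [0, nx] x [0, ny].

// [[Rcpp::export]]
IntegerMatrix cppRasterizeTriangles(NumericMatrix px, IntegerMatrix faces,
                                    int nx, int ny) {
  IntegerMatrix mask(ny, nx);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    const double x1 = px(a, 0), y1 = px(a, 1);
    const double x2 = px(b, 0), y2 = px(b, 1);
    const double x3 = px(c, 0), y3 = px(c, 1);
    const double area2 = (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1);
    if (std::fabs(area2) < 1e-12) continue;
    double xmin = std::min(x1, std::min(x2, x3));
    double xmax = std::max(x1, std::max(x2, x3));
    double ymin = std::min(y1, std::min(y2, y3));
    double ymax = std::max(y1, std::max(y2, y3));
    int j0 = std::max(1, (int)std::ceil(xmin + 0.5 - 1e-9));
    int j1 = std::min(nx, (int)std::floor(xmax + 0.5 + 1e-9));
    int i0 = std::max(1, (int)std::ceil(ymin + 0.5 - 1e-9));
    int i1 = std::min(ny, (int)std::floor(ymax + 0.5 + 1e-9));
    if (j0 > j1 || i0 > i1) continue;
    const double eps = 1e-9 * (std::fabs(area2) + 1.0);
    for (int i = i0; i <= i1; ++i) {
      const double y = i - 0.5;
      for (int j = j0; j <= j1; ++j) {
        const double x = j - 0.5;
        const double e1 = (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1);
        const double e2 = (x3 - x2) * (y - y2) - (y3 - y2) * (x - x2);
        const double e3 = (x1 - x3) * (y - y3) - (y1 - y3) * (x - x3);
        const bool pos = e1 >= -eps && e2 >= -eps && e3 >= -eps;
        const bool neg = e1 <= eps && e2 <= eps && e3 <= eps;
        if (pos || neg) mask(i - 1, j - 1) = 1;
      }
    }
  }
  return mask;
}

// [[Rcpp::export]]
NumericMatrix cppRasterizePolygon(NumericMatrix poly, int nx, int ny) {
  // even-odd fill of a single closed polygon (used to re-rasterize noisy
  // contours); vertices in pixel coordinates, implicit closure
  IntegerMatrix mask(ny, nx);
  const int n = poly.nrow();
  for (int i = 1; i <= ny; ++i) {
    const double y = i - 0.5;
    std::vector<double> xs;
    for (int k = 0; k < n; ++k) {
      const int k2 = (k + 1) % n;
      const double y1 = poly(k, 1), y2 = poly(k2, 1);
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        const double t = (y - y1) / (y2 - y1);
        xs.push_back(poly(k, 0) + t * (poly(k2, 0) - poly(k, 0)));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int j0 = std::max(1, (int)std::ceil(xs[k] + 0.5 - 1e-9));
      int j1 = std::min(nx, (int)std::floor(xs[k + 1] + 0.5 + 1e-9));
      for (int j = j0; j <= j1; ++j) mask(i - 1, j - 1) = 1;
    }
  }
  NumericMatrix out(ny, nx);
  for (int i = 0; i < ny * nx; ++i) out[i] = mask[i];
  return out;
}

static inline long long hEdgeId(int i, int j, int w) {
  return ((long long)i * w + j) * 2LL;
}
static inline long long vEdgeId(int i, int j, int w) {
  return ((long long)i * w + j) * 2LL + 1LL;
}

// [[Rcpp::export]]
List cppMarchingSquares(IntegerMatrix mask) {
  // iso-0.5 contours of a binary image sampled at pixel centres; returns a
  // list of closed loops (matrices of x, y edge-midpoint coordinates)
  const int ny = mask.nrow(), nx = mask.ncol();
  const int w = nx + 2;  // padded sample-grid width for edge ids
  // sample value at padded index (i, j), i in 0..ny+1, j in 0..nx+1
  auto val = [&](int i, int j) -> int {
    if (i < 1 || i > ny || j < 1 || j > nx) return 0;
    return mask(i - 1, j - 1) != 0 ? 1 : 0;
  };
  std::vector<long long> segA, segB;
  for (int i = 0; i <= ny; ++i) {
    for (int j = 0; j <= nx; ++j) {
      const int tl = val(i, j), tr = val(i, j + 1);
      const int br = val(i + 1, j + 1), bl = val(i + 1, j);
      const int idx = tl | (tr << 1) | (br << 2) | (bl << 3);
      if (idx == 0 || idx == 15) continue;
      const long long top = hEdgeId(i, j, w);
      const long long bottom = hEdgeId(i + 1, j, w);
      const long long left = vEdgeId(i, j, w);
      const long long right = vEdgeId(i, j + 1, w);
      auto add = [&](long long a, long long b) {
        segA.push_back(a);
        segB.push_back(b);
      };
      switch (idx) {
        case 1:  add(top, left); break;
        case 2:  add(top, right); break;
        case 3:  add(left, right); break;
        case 4:  add(right, bottom); break;
        case 5:  add(top, left); add(right, bottom); break;
        case 6:  add(top, bottom); break;
        case 7:  add(left, bottom); break;
        case 8:  add(bottom, left); break;
        case 9:  add(top, bottom); break;
        case 10: add(top, right); add(bottom, left); break;
        case 11: add(right, bottom); break;
        case 12: add(right, left); break;
        case 13: add(top, right); break;
        case 14: add(top, left); break;
        default: break;
      }
    }
  }
  const int nseg = (int)segA.size();
  std::unordered_map<long long, std::vector<int> > byEdge;
  byEdge.reserve(nseg * 2);
  for (int s = 0; s < nseg; ++s) {
    byEdge[segA[s]].push_back(s);
    byEdge[segB[s]].push_back(s);
  }
  auto edgeXY = [&](long long id, double *x, double *y) {
    const bool vert = (id & 1LL) != 0;
    const long long cell = id >> 1;
    const int i = (int)(cell / w), j = (int)(cell % w);
    if (vert) { *x = j - 0.5; *y = i; }
    else      { *x = j;       *y = i - 0.5; }
  };
  std::vector<char> used(nseg, 0);
  List loops;
  for (int s0 = 0; s0 < nseg; ++s0) {
    if (used[s0]) continue;
    std::vector<long long> path;
    long long start = segA[s0];
    long long cur = segB[s0];
    path.push_back(start);
    used[s0] = 1;
    int guard = 0;
    while (cur != start && guard++ <= nseg) {
      path.push_back(cur);
      const std::vector<int> &segs = byEdge[cur];
      int nxt = -1;
      for (size_t k = 0; k < segs.size(); ++k)
        if (!used[segs[k]]) { nxt = segs[k]; break; }
      if (nxt < 0) break;  // open chain (should not happen on padded mask)
      used[nxt] = 1;
      cur = (segA[nxt] == cur) ? segB[nxt] : segA[nxt];
    }
    NumericMatrix loop(path.size(), 2);
    for (size_t k = 0; k < path.size(); ++k) {
      double x, y;
      edgeXY(path[k], &x, &y);
      loop(k, 0) = x;
      loop(k, 1) = y;
    }
    loops.push_back(loop);
  }
  return loops;
}

// [[Rcpp::export]]
double cppMeanMinDist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1);
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    acc += std::sqrt(best);
  }
  return acc / n;
}

// [[Rcpp::export]]
double cppSymmetricContourDist(NumericMatrix A, NumericMatrix B) {
  return 0.5 * (cppMeanMinDist(A, B) + cppMeanMinDist(B, A));
}

// [[Rcpp::export]]
double cppMaskMismatch(IntegerMatrix A, IntegerMatrix B) {
  const int n = A.nrow() * A.ncol();
  int acc = 0;
  for (int i = 0; i < n; ++i) acc += (A[i] != 0) != (B[i] != 0);
  return (double)acc;
}

// [[Rcpp::export]]
NumericVector cppMaskMoments(IntegerMatrix A) {
  // returns (centroid x, centroid y, pixel count) in pixel coordinates
  const int ny = A.nrow(), nx = A.ncol();
  double sx = 0, sy = 0, n = 0;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      if (A(i, j) != 0) { sx += j + 0.5; sy += i + 0.5; n += 1; }
  if (n > 0) { sx /= n; sy /= n; }
  return NumericVector::create(sx, sy, n);
}
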