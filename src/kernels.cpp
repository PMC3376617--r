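#include <Rcpp.h>
#include <queue>
#include <limits>
using namespace Rcpp;

// Connected-component labeling of a binary mask by queue-based flood fill
// (iterative, so no stack-depth hazard on large regions). Labels are assigned
// in row-major discovery order starting at 1, which gives the deterministic
// tie rule downstream: among equal-sized regions the smallest label is the
// one whose first pixel comes earliest in row-major order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc); // zero-initialized
  // neighbour offsets (row, col)
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        lab(r, c) = next;
        q.push(std::make_pair(r, c));
        while (!q.empty()) {
          std::pair<int, int> p = q.front();
          q.pop();
          for (int k = 0; k < nn; ++k) {
            int rr = p.first + dr[k], cc = p.second + dc[k];
            if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
                mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// --- Minimum enclosing circle (Welzl, move-to-front, deterministic) -------

struct Circ { double x, y, r2; };

static Circ circ2(double ax, double ay, double bx, double by) {
  Circ c;
  c.x = (ax + bx) / 2.0;
  c.y = (ay + by) / 2.0;
  double dx = ax - c.x, dy = ay - c.y;
  c.r2 = dx * dx + dy * dy;
  return c;
}

static bool circ3(double ax, double ay, double bx, double by,
                  double cx, double cy, Circ& out) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (d == 0.0) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  out.x = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  out.y = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - out.x, dy = ay - out.y;
  out.r2 = dx * dx + dy * dy;
  return true;
}

static bool inside(const Circ& c, double px, double py, double eps) {
  double dx = px - c.x, dy = py - c.y;
  return dx * dx + dy * dy <= c.r2 + eps;
}

// Exact minimum enclosing circle radius of a 2-d point set. Deterministic:
// points are pre-shuffled with a fixed linear congruential sequence (Welzl's
// expected-linear behaviour needs a data-independent order, not true
// randomness).
// [[Rcpp::export(name = ".mec_radius")]]
double mec_radius(const NumericMatrix& pts) {
  int n = pts.nrow();
  if (n == 0) stop("empty point set");
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pts(i, 0); y[i] = pts(i, 1); }
  unsigned long long s = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) { // Fisher-Yates with xorshift64
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    int j = (int)(s % (unsigned long long)(i + 1));
    std::swap(x[i], x[j]);
    std::swap(y[i], y[j]);
  }
  const double eps = 1e-7;
  Circ c; c.x = x[0]; c.y = y[0]; c.r2 = 0.0;
  for (int i = 1; i < n; ++i) {
    if (inside(c, x[i], y[i], eps)) continue;
    c.x = x[i]; c.y = y[i]; c.r2 = 0.0;
    for (int j = 0; j < i; ++j) {
      if (inside(c, x[j], y[j], eps)) continue;
      c = circ2(x[i], y[i], x[j], y[j]);
      for (int k = 0; k < j; ++k) {
        if (inside(c, x[k], y[k], eps)) continue;
        Circ t;
        if (circ3(x[i], y[i], x[j], y[j], x[k], y[k], t)) c = t;
      }
    }
  }
  return std::sqrt(c.r2);
}

// 1-d squared-distance transform (lower envelope of parabolas).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform: for each pixel, squared distance to the
// nearest zero pixel (center-to-center). Pixels outside the image border are
// treated as background at distance (row/col index + 1), so a region touching
// the border still has a finite inscribed radius.
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e30;
  NumericMatrix d(nr, nc);
  // columns pass: distance within each column to nearest 0 (or border)
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  std::vector<int> v(std::max(nr, nc));
  std::vector<double> z(std::max(nr, nc) + 1);
  for (int c = 0; c < nc; ++c) {
    f.assign(nr, INF);
    for (int r = 0; r < nr; ++r) f[r] = (mask(r, c) == 0) ? 0.0 : INF;
    dt1d(std::vector<double>(f.begin(), f.begin() + nr), out, v, z);
    for (int r = 0; r < nr; ++r) {
      double border = std::min(r + 1, nr - r); // off-image background
      double b2 = border * border;
      d(r, c) = std::min(out[r], b2);
    }
  }
  // rows pass
  for (int r = 0; r < nr; ++r) {
    std::vector<double> fr(nc);
    for (int c = 0; c < nc; ++c) fr[c] = d(r, c);
    dt1d(fr, out, v, z);
    for (int c = 0; c < nc; ++c) {
      double border = std::min(c + 1, nc - c);
      double b2 = border * border;
      d(r, c) = std::min(out[c], b2);
    }
  }
  return d;
}
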