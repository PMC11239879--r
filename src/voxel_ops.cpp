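// Low-level voxel kernels for 3D fluorescence stack processing.
// Volumes are numeric arrays with dim = c(nz, ny, nx) (z fastest, R
// column-major). All coordinates crossing the R boundary are 1-based;
// linear indices are 0-based C offsets computed on the R side.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>
#include <cstring>
#include <utility>

using namespace Rcpp;

static inline int reflect101(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = i % period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// Separable Gaussian blur; sigma is in voxels per axis (z, y, x).
// Kernel truncated at 3 sigma, reflect-101 boundary.
// [[Rcpp::export]]
NumericVector cpp_sep_gauss_blur(NumericVector vol, IntegerVector dims,
                                 NumericVector sigma) {
  int n[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t total = (R_xlen_t)n[0] * n[1] * n[2];
  std::vector<double> a(vol.begin(), vol.end()), b(total);
  long str[3] = {1, (long)n[0], (long)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int h = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * h + 1);
    double ksum = 0;
    for (int i = -h; i <= h; ++i) {
      k[i + h] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + h];
    }
    for (double &v : k) v /= ksum;
    int na = n[ax];
    long sa = str[ax];
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    int n1 = n[o1], n2 = n[o2];
    long s1 = str[o1], s2 = str[o2];
    std::vector<double> line(na);
    for (int i2 = 0; i2 < n2; ++i2) {
      for (int i1 = 0; i1 < n1; ++i1) {
        long base = (long)i1 * s1 + (long)i2 * s2;
        for (int i = 0; i < na; ++i) line[i] = a[base + (long)i * sa];
        int lo = h < na ? h : na;
        for (int i = 0; i < lo; ++i) {  // left boundary (reflect-101)
          double acc = 0;
          for (int j = -h; j <= h; ++j)
            acc += k[j + h] * line[reflect101(i + j, na)];
          b[base + (long)i * sa] = acc;
        }
        for (int i = lo; i < na - h; ++i) {  // interior, no reflection
          double acc = 0;
          const double *lp = &line[i - h];
          for (int j = 0; j <= 2 * h; ++j) acc += k[j] * lp[j];
          b[base + (long)i * sa] = acc;
        }
        for (int i = na - h > lo ? na - h : lo; i < na; ++i) {
          double acc = 0;
          for (int j = -h; j <= h; ++j)
            acc += k[j + h] * line[reflect101(i + j, na)];
          b[base + (long)i * sa] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

// Box mean with per-axis half-widths (voxels); window truncated at the
// volume border and renormalised by the actual voxel count.
// [[Rcpp::export]]
NumericVector cpp_box_mean(NumericVector vol, IntegerVector dims,
                           IntegerVector half) {
  int n[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t total = (R_xlen_t)n[0] * n[1] * n[2];
  std::vector<double> a(vol.begin(), vol.end()), b(total);
  long str[3] = {1, (long)n[0], (long)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    int h = half[ax];
    if (h <= 0) continue;
    int na = n[ax];
    long sa = str[ax];
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    int n1 = n[o1], n2 = n[o2];
    long s1 = str[o1], s2 = str[o2];
    std::vector<double> pref(na + 1);
    for (int i2 = 0; i2 < n2; ++i2) {
      for (int i1 = 0; i1 < n1; ++i1) {
        long base = (long)i1 * s1 + (long)i2 * s2;
        pref[0] = 0;
        for (int i = 0; i < na; ++i)
          pref[i + 1] = pref[i] + a[base + (long)i * sa];
        for (int i = 0; i < na; ++i) {
          int lo = i - h < 0 ? 0 : i - h;
          int hi = i + h >= na ? na - 1 : i + h;
          b[base + (long)i * sa] = (pref[hi + 1] - pref[lo]) / (hi - lo + 1);
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

static void slide_extremum(const std::vector<double> &in,
                           std::vector<double> &out, int h, bool do_max,
                           std::vector<int> &ring) {
  // monotonic queue on a ring buffer (indices head..tail-1)
  int na = (int)in.size();
  if ((int)ring.size() < na) ring.resize(na);
  int head = 0, tail = 0, r = 0;
  for (int i = 0; i < na; ++i) {
    int hi = i + h >= na ? na - 1 : i + h;
    for (; r <= hi; ++r) {
      double v = in[r];
      while (tail > head &&
             (do_max ? in[ring[tail - 1]] <= v : in[ring[tail - 1]] >= v))
        --tail;
      ring[tail++] = r;
    }
    int lo = i - h < 0 ? 0 : i - h;
    while (ring[head] < lo) ++head;
    out[i] = in[ring[head]];
  }
}

// Separable box erosion (do_max = FALSE) / dilation (do_max = TRUE).
// [[Rcpp::export]]
NumericVector cpp_box_extremum(NumericVector vol, IntegerVector dims,
                               IntegerVector half, bool do_max) {
  int n[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t total = (R_xlen_t)n[0] * n[1] * n[2];
  std::vector<double> a(vol.begin(), vol.end()), b(total);
  long str[3] = {1, (long)n[0], (long)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    int h = half[ax];
    if (h <= 0) continue;
    int na = n[ax];
    long sa = str[ax];
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    int n1 = n[o1], n2 = n[o2];
    long s1 = str[o1], s2 = str[o2];
    std::vector<double> line(na), res(na);
    std::vector<int> ring;
    for (int i2 = 0; i2 < n2; ++i2) {
      for (int i1 = 0; i1 < n1; ++i1) {
        long base = (long)i1 * s1 + (long)i2 * s2;
        for (int i = 0; i < na; ++i) line[i] = a[base + (long)i * sa];
        slide_extremum(line, res, h, do_max, ring);
        for (int i = 0; i < na; ++i) b[base + (long)i * sa] = res[i];
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

// 3D running median over a box window (half-widths per axis), computed on
// a quantised histogram (Huang's sliding-histogram algorithm along x with a
// tracked running median). Values are binned into nbins equal-width bins
// between the volume min and max; the reported median is the centre value
// of the median bin, so the quantisation error is at most range/nbins.
// [[Rcpp::export]]
NumericVector cpp_median_box(NumericVector vol, IntegerVector dims,
                             IntegerVector half, int nbins) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t total = (R_xlen_t)nz * ny * nx;
  NumericVector out(total);
  double mn = R_PosInf, mx = R_NegInf;
  for (R_xlen_t i = 0; i < total; ++i) {
    double v = vol[i];
    if (v < mn) mn = v;
    if (v > mx) mx = v;
  }
  if (!(mx > mn)) {  // constant volume: median is the volume itself
    for (R_xlen_t i = 0; i < total; ++i) out[i] = vol[i];
    return out;
  }
  double scale = (nbins - 1) / (mx - mn);
  std::vector<int> q(total);
  for (R_xlen_t i = 0; i < total; ++i)
    q[i] = (int)((vol[i] - mn) * scale + 0.5);
  int hz = half[0], hy = half[1], hx = half[2];
  std::vector<int> cnt(nbins);
  long sy = nz, sx = (long)nz * ny;
  for (int y0 = 0; y0 < ny; ++y0) {
    int ylo = y0 - hy < 0 ? 0 : y0 - hy;
    int yhi = y0 + hy >= ny ? ny - 1 : y0 + hy;
    for (int z0 = 0; z0 < nz; ++z0) {
      int zlo = z0 - hz < 0 ? 0 : z0 - hz;
      int zhi = z0 + hz >= nz ? nz - 1 : z0 + hz;
      std::memset(cnt.data(), 0, sizeof(int) * nbins);
      int totalw = 0, below = 0, m = 0;
      int xhi0 = hx >= nx ? nx - 1 : hx;
      for (int x = 0; x <= xhi0; ++x)
        for (int y = ylo; y <= yhi; ++y)
          for (int z = zlo; z <= zhi; ++z) {
            ++cnt[q[z + y * sy + (long)x * sx]];
            ++totalw;
          }
      for (int x0 = 0; x0 < nx; ++x0) {
        if (x0 > 0) {
          int xout = x0 - 1 - hx, xin = x0 + hx;
          if (xout >= 0)
            for (int y = ylo; y <= yhi; ++y)
              for (int z = zlo; z <= zhi; ++z) {
                int b = q[z + y * sy + (long)xout * sx];
                --cnt[b];
                --totalw;
                if (b < m) --below;
              }
          if (xin < nx)
            for (int y = ylo; y <= yhi; ++y)
              for (int z = zlo; z <= zhi; ++z) {
                int b = q[z + y * sy + (long)xin * sx];
                ++cnt[b];
                ++totalw;
                if (b < m) ++below;
              }
        }
        int k = (totalw + 1) / 2;  // lower median for even counts
        while (below >= k) {
          --m;
          below -= cnt[m];
        }
        while (below + cnt[m] < k) {
          below += cnt[m];
          ++m;
        }
        out[z0 + y0 * sy + (long)x0 * sx] = mn + m / scale;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

static void neighbor_offsets26(int nz, int ny, std::vector<long> &off,
                               std::vector<int> &dzs, std::vector<int> &dys,
                               std::vector<int> &dxs) {
  long sy = nz, sx = (long)nz * ny;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        off.push_back(dz + dy * sy + dx * sx);
        dzs.push_back(dz);
        dys.push_back(dy);
        dxs.push_back(dx);
      }
}

// 26-connected component labelling of a 0/1 mask. Labels are assigned in
// raster-scan order of the first voxel encountered, so they are
// deterministic and contiguous from 1.
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t total = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(total);
  std::vector<long> off;
  std::vector<int> dzs, dys, dxs;
  neighbor_offsets26(nz, ny, off, dzs, dys, dxs);
  int nb = (int)off.size();
  std::vector<long> stack;
  int next = 0;
  long sy = nz, sx = (long)nz * ny;
  for (R_xlen_t i = 0; i < total; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      long cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz), y = (int)((cur / sy) % ny), x = (int)(cur / sx);
      for (int j = 0; j < nb; ++j) {
        int z2 = z + dzs[j], y2 = y + dys[j], x2 = x + dxs[j];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        long idx = cur + off[j];
        if (mask[idx] && !lab[idx]) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Dijkstra geodesic distance inside a mask, 26-connected, edges weighted by
// their physical length under the voxel spacing (z, y, x in micrometres).
// seeds are 0-based linear indices. Returns +Inf for mask voxels not
// reachable from any seed and NA outside the mask.
// [[Rcpp::export]]
NumericVector cpp_geodesic26(IntegerVector mask, IntegerVector dims,
                             IntegerVector seeds, NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t total = (R_xlen_t)nz * ny * nx;
  NumericVector dist(total);
  for (R_xlen_t i = 0; i < total; ++i)
    dist[i] = mask[i] ? R_PosInf : NA_REAL;
  std::vector<long> off;
  std::vector<int> dzs, dys, dxs;
  neighbor_offsets26(nz, ny, off, dzs, dys, dxs);
  int nb = (int)off.size();
  std::vector<double> w(nb);
  for (int j = 0; j < nb; ++j)
    w[j] = std::sqrt(std::pow(dzs[j] * spacing[0], 2) +
                     std::pow(dys[j] * spacing[1], 2) +
                     std::pow(dxs[j] * spacing[2], 2));
  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int s = 0; s < seeds.size(); ++s) {
    long i = (long)seeds[s];
    if (i < 0 || i >= total || !mask[i]) stop("seed outside mask");
    dist[i] = 0.0;
    pq.push(Node(0.0, i));
  }
  long sy = nz, sx = (long)nz * ny;
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    double d = nd.first;
    long cur = nd.second;
    if (d > dist[cur]) continue;
    int z = (int)(cur % nz), y = (int)((cur / sy) % ny), x = (int)(cur / sx);
    for (int j = 0; j < nb; ++j) {
      int z2 = z + dzs[j], y2 = y + dys[j], x2 = x + dxs[j];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      long idx = cur + off[j];
      if (!mask[idx]) continue;
      double nd2 = d + w[j];
      if (nd2 < dist[idx]) {
        dist[idx] = nd2;
        pq.push(Node(nd2, idx));
      }
    }
  }
  dist.attr("dim") = dims;
  return dist;
}

// Multi-source Dijkstra on a 2D label image (8-connected, physical pixel
// pitch dy/dx): for every pixel within maxdist of some nonzero label,
// report the distance and the label of the nearest seed region.
// [[Rcpp::export]]
List cpp_nearest_label2d(IntegerMatrix lab, double dy, double dx,
                         double maxdist) {
  int ny = lab.nrow(), nx = lab.ncol();
  NumericMatrix dist(ny, nx);
  IntegerMatrix nearest(ny, nx);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if (lab(y, x) > 0) {
        dist(y, x) = 0.0;
        nearest(y, x) = lab(y, x);
        pq.push(Node(0.0, (long)y + (long)x * ny));
      }
  int dys[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dxs[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  double w[8];
  for (int j = 0; j < 8; ++j)
    w[j] = std::sqrt(std::pow(dys[j] * dy, 2) + std::pow(dxs[j] * dx, 2));
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    double d = nd.first;
    long cur = nd.second;
    int y = (int)(cur % ny), x = (int)(cur / ny);
    if (d > dist(y, x)) continue;
    for (int j = 0; j < 8; ++j) {
      int y2 = y + dys[j], x2 = x + dxs[j];
      if (y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
      double nd2 = d + w[j];
      if (nd2 <= maxdist && nd2 < dist(y2, x2)) {
        dist(y2, x2) = nd2;
        nearest(y2, x2) = nearest(y, x);
        pq.push(Node(nd2, (long)y2 + (long)x2 * ny));
      }
    }
  }
  return List::create(_["dist"] = dist, _["label"] = nearest);
}
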