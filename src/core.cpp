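// Low-level 3D image primitives: exact Euclidean distance transform,
// grayscale morphology, slicewise rotation, separable Gaussian smoothing,
// patch matching scan, morphological reconstruction, marker watershed,
// connected components and fibre rasterization.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, squared
// distances propagated separably along each axis).

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = -1; // top of the lower envelope; only finite parabolas enter
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      if (k < 0) break;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * (q - v[k]));
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      k++; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int t = 0;
  for (int q = 0; q < n; q++) {
    while (z[t + 1] < q) t++;
    d[q] = (double)(q - v[t]) * (q - v[t]) + f[v[t]];
  }
}

// Squared distance from every voxel with mask != 0 to the nearest voxel with
// mask == 0 (zero on the mask == 0 voxels themselves).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)k * n2 * n1 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; i++) f[i] = g[base + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; i++) g[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = (R_xlen_t)k * n2 * n1 + i;
      for (int j = 0; j < n2; j++) f[j] = g[base + (R_xlen_t)j * n1];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; j++) g[base + (R_xlen_t)j * n1] = d[j];
    }
  // axis 3
  R_xlen_t sl = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; k++) f[k] = g[base + (R_xlen_t)k * sl];
      dt1d(f, d, v, z, n3);
      for (int k = 0; k < n3; k++) g[base + (R_xlen_t)k * sl] = d[k];
    }
  return g;
}

// ---------------------------------------------------------------------------
// Grayscale erosion / dilation with a spherical structuring element of
// diameter 3 voxels (19 offsets: the 3x3x3 neighbourhood minus corners).
// Out-of-bounds neighbours are ignored (border values replicate their own
// in-bounds support).

// [[Rcpp::export]]
NumericVector cpp_morph_gray(NumericVector x, IntegerVector dim, int op) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3, sl = (R_xlen_t)n1 * n2;
  NumericVector out(n);
  static const int off[19][3] = {
      {0, 0, 0},  {1, 0, 0},  {-1, 0, 0}, {0, 1, 0},  {0, -1, 0},
      {0, 0, 1},  {0, 0, -1}, {1, 1, 0},  {1, -1, 0}, {-1, 1, 0},
      {-1, -1, 0},{1, 0, 1},  {1, 0, -1}, {-1, 0, 1}, {-1, 0, -1},
      {0, 1, 1},  {0, 1, -1}, {0, -1, 1}, {0, -1, -1}};
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double acc = (op == 0) ? INF : -INF;
        for (int t = 0; t < 19; t++) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
            continue;
          double val = x[(R_xlen_t)kk * sl + (R_xlen_t)jj * n1 + ii];
          if (op == 0) { if (val < acc) acc = val; }
          else { if (val > acc) acc = val; }
        }
        out[(R_xlen_t)k * sl + (R_xlen_t)j * n1 + i] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Rotation about one array axis by `angle` degrees, bilinear interpolation in
// the perpendicular plane, NA outside the source footprint.

// [[Rcpp::export]]
NumericVector cpp_rotate_axis(NumericVector x, IntegerVector dim, int axis,
                              double angle) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t sl = (R_xlen_t)n1 * n2;
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  double th = angle * M_PI / 180.0, c = std::cos(th), s = std::sin(th);
  // plane axes (0-based array axes) perpendicular to `axis` (1-based)
  int a = axis - 1;
  int u = (a == 0) ? 1 : 0;
  int v = (a == 2) ? 1 : 2;
  int nd[3] = {n1, n2, n3};
  double cu = (nd[u] - 1) / 2.0, cv = (nd[v] - 1) / 2.0;
  R_xlen_t stride[3] = {1, (R_xlen_t)n1, sl};
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        int idx3[3] = {i, j, k};
        double du = idx3[u] - cu, dv = idx3[v] - cv;
        // inverse rotation of the destination coordinate
        double su = c * du + s * dv + cu;
        double sv = -s * du + c * dv + cv;
        R_xlen_t o = (R_xlen_t)k * sl + (R_xlen_t)j * n1 + i;
        int u0 = (int)std::floor(su), v0 = (int)std::floor(sv);
        if (u0 < 0 || v0 < 0 || u0 + 1 > nd[u] - 1 || v0 + 1 > nd[v] - 1) {
          // allow exact hits on the last row/column
          if (u0 >= 0 && v0 >= 0 && su <= nd[u] - 1 && sv <= nd[v] - 1) {
            int uu = (int)std::round(su), vv = (int)std::round(sv);
            if (std::fabs(su - uu) < 1e-9 && std::fabs(sv - vv) < 1e-9) {
              R_xlen_t src = (R_xlen_t)idx3[a] * stride[a] +
                             (R_xlen_t)uu * stride[u] + (R_xlen_t)vv * stride[v];
              out[o] = x[src];
              continue;
            }
          }
          out[o] = NA_REAL;
          continue;
        }
        double fu = su - u0, fv = sv - v0;
        R_xlen_t b = (R_xlen_t)idx3[a] * stride[a];
        double x00 = x[b + (R_xlen_t)u0 * stride[u] + (R_xlen_t)v0 * stride[v]];
        double x10 = x[b + (R_xlen_t)(u0 + 1) * stride[u] + (R_xlen_t)v0 * stride[v]];
        double x01 = x[b + (R_xlen_t)u0 * stride[u] + (R_xlen_t)(v0 + 1) * stride[v]];
        double x11 = x[b + (R_xlen_t)(u0 + 1) * stride[u] + (R_xlen_t)(v0 + 1) * stride[v]];
        out[o] = x00 * (1 - fu) * (1 - fv) + x10 * fu * (1 - fv) +
                 x01 * (1 - fu) * fv + x11 * fu * fv;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing; truncated at 3 sigma, kernel renormalized at
// the borders so constants are preserved.

static void blur_axis(std::vector<double> &buf, NumericVector &g, int n1,
                      int n2, int n3, int axis, const std::vector<double> &ker) {
  int r = ((int)ker.size() - 1) / 2;
  R_xlen_t sl = (R_xlen_t)n1 * n2;
  int nd[3] = {n1, n2, n3};
  R_xlen_t stride[3] = {1, (R_xlen_t)n1, sl};
  int na = nd[axis];
  int ob = (axis == 0) ? 1 : 0, oc = (axis == 2) ? 1 : 2;
  for (int b = 0; b < nd[ob]; b++)
    for (int cidx = 0; cidx < nd[oc]; cidx++) {
      R_xlen_t base = (R_xlen_t)b * stride[ob] + (R_xlen_t)cidx * stride[oc];
      for (int q = 0; q < na; q++) buf[q] = g[base + (R_xlen_t)q * stride[axis]];
      for (int q = 0; q < na; q++) {
        double acc = 0, wsum = 0;
        int lo = std::max(0, q - r), hi = std::min(na - 1, q + r);
        for (int t = lo; t <= hi; t++) {
          double w = ker[t - q + r];
          acc += w * buf[t];
          wsum += w;
        }
        g[base + (R_xlen_t)q * stride[axis]] = acc / wsum;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector x, IntegerVector dim, double sigma) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector g = clone(x);
  if (sigma <= 0) return g;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  for (int t = -r; t <= r; t++) ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  std::vector<double> buf(std::max(n1, std::max(n2, n3)));
  blur_axis(buf, g, n1, n2, n3, 0, ker);
  blur_axis(buf, g, n1, n2, n3, 1, ker);
  blur_axis(buf, g, n1, n2, n3, 2, ker);
  return g;
}

// ---------------------------------------------------------------------------
// Exhaustive patch matching: mean absolute difference against the canvas
// window over occupied voxels, lowest index wins ties.

// [[Rcpp::export]]
List cpp_match_scan(NumericVector patches, NumericVector window,
                    LogicalVector occ) {
  R_xlen_t L = window.size();
  R_xlen_t P = patches.size() / L;
  std::vector<R_xlen_t> idx;
  idx.reserve(L);
  for (R_xlen_t t = 0; t < L; t++)
    if (occ[t]) idx.push_back(t);
  R_xlen_t nm = idx.size();
  if (nm == 0)
    return List::create(_["best"] = NA_INTEGER, _["error"] = NA_REAL);
  double bestTotal = INF;
  R_xlen_t besti = -1;
  for (R_xlen_t p = 0; p < P; p++) {
    const double *pat = &patches[p * L];
    double sum = 0;
    bool aborted = false;
    for (R_xlen_t t = 0; t < nm; t++) {
      sum += std::fabs(window[idx[t]] - pat[idx[t]]);
      if (sum >= bestTotal) { aborted = true; break; }
    }
    if (!aborted && sum < bestTotal) {
      bestTotal = sum;
      besti = p;
    }
  }
  return List::create(_["best"] = (int)(besti + 1),
                      _["error"] = bestTotal / nm);
}

// ---------------------------------------------------------------------------
// Morphological reconstruction by dilation (6-connectivity), hybrid
// raster-scan + FIFO queue algorithm.

// [[Rcpp::export]]
NumericVector cpp_grayrec_dilate(NumericVector marker, NumericVector mask,
                                 IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t sl = (R_xlen_t)n1 * n2, n = sl * n3;
  NumericVector J(n);
  for (R_xlen_t i = 0; i < n; i++) J[i] = std::min(marker[i], mask[i]);
  // forward scan
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t p = (R_xlen_t)k * sl + (R_xlen_t)j * n1 + i;
        double m = J[p];
        if (i > 0 && J[p - 1] > m) m = J[p - 1];
        if (j > 0 && J[p - n1] > m) m = J[p - n1];
        if (k > 0 && J[p - sl] > m) m = J[p - sl];
        J[p] = std::min(m, mask[p]);
      }
  // backward scan + seed queue
  std::queue<R_xlen_t> q;
  for (int k = n3 - 1; k >= 0; k--)
    for (int j = n2 - 1; j >= 0; j--)
      for (int i = n1 - 1; i >= 0; i--) {
        R_xlen_t p = (R_xlen_t)k * sl + (R_xlen_t)j * n1 + i;
        double m = J[p];
        if (i < n1 - 1 && J[p + 1] > m) m = J[p + 1];
        if (j < n2 - 1 && J[p + n1] > m) m = J[p + n1];
        if (k < n3 - 1 && J[p + sl] > m) m = J[p + sl];
        J[p] = std::min(m, mask[p]);
        bool enq = false;
        if (i < n1 - 1 && J[p + 1] < J[p] && J[p + 1] < mask[p + 1]) enq = true;
        if (!enq && j < n2 - 1 && J[p + n1] < J[p] && J[p + n1] < mask[p + n1]) enq = true;
        if (!enq && k < n3 - 1 && J[p + sl] < J[p] && J[p + sl] < mask[p + sl]) enq = true;
        if (enq) q.push(p);
      }
  const R_xlen_t offs[6] = {1, -1, (R_xlen_t)n1, -(R_xlen_t)n1, sl, -sl};
  while (!q.empty()) {
    R_xlen_t p = q.front();
    q.pop();
    int i = (int)(p % n1), j = (int)((p / n1) % n2), k = (int)(p / sl);
    int ii[6] = {i + 1, i - 1, i, i, i, i};
    int jj[6] = {j, j, j + 1, j - 1, j, j};
    int kk[6] = {k, k, k, k, k + 1, k - 1};
    for (int t = 0; t < 6; t++) {
      if (ii[t] < 0 || jj[t] < 0 || kk[t] < 0 || ii[t] >= n1 || jj[t] >= n2 ||
          kk[t] >= n3)
        continue;
      R_xlen_t pq = p + offs[t];
      if (J[pq] < J[p] && J[pq] < mask[pq]) {
        J[pq] = std::min(J[p], mask[pq]);
        q.push(pq);
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Regional maxima (6-connectivity) restricted to a domain; returns a label
// image with one positive label per maximal plateau, 0 elsewhere.

// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector f, LogicalVector domain,
                                  IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t sl = (R_xlen_t)n1 * n2, n = sl * n3;
  IntegerVector lab(n); // 0 = unlabelled
  std::vector<char> visited(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack, plateau;
  for (R_xlen_t p0 = 0; p0 < n; p0++) {
    if (!domain[p0] || visited[p0]) continue;
    double v = f[p0];
    bool ismax = true;
    stack.clear();
    plateau.clear();
    stack.push_back(p0);
    visited[p0] = 1;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      plateau.push_back(p);
      int i = (int)(p % n1), j = (int)((p / n1) % n2), k = (int)(p / sl);
      int ii[6] = {i + 1, i - 1, i, i, i, i};
      int jj[6] = {j, j, j + 1, j - 1, j, j};
      int kk[6] = {k, k, k, k, k + 1, k - 1};
      for (int t = 0; t < 6; t++) {
        if (ii[t] < 0 || jj[t] < 0 || kk[t] < 0 || ii[t] >= n1 ||
            jj[t] >= n2 || kk[t] >= n3)
          continue;
        R_xlen_t pq = (R_xlen_t)kk[t] * sl + (R_xlen_t)jj[t] * n1 + ii[t];
        if (!domain[pq]) continue;
        if (f[pq] > v) ismax = false;
        else if (f[pq] == v && !visited[pq]) {
          visited[pq] = 1;
          stack.push_back(pq);
        }
      }
    }
    if (ismax) {
      next++;
      for (size_t t = 0; t < plateau.size(); t++) lab[plateau[t]] = next;
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-based watershed by priority flooding (Meyer), 6-connectivity,
// restricted to a domain. `priority` is flooded from low to high.

struct PQItem {
  double v;
  R_xlen_t order;
  R_xlen_t idx;
};
struct PQCmp {
  bool operator()(const PQItem &a, const PQItem &b) const {
    if (a.v != b.v) return a.v > b.v;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            LogicalVector domain, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t sl = (R_xlen_t)n1 * n2, n = sl * n3;
  IntegerVector lab = clone(markers);
  std::priority_queue<PQItem, std::vector<PQItem>, PQCmp> pq;
  R_xlen_t counter = 0;
  for (R_xlen_t p = 0; p < n; p++)
    if (domain[p] && lab[p] > 0) pq.push({priority[p], counter++, p});
  while (!pq.empty()) {
    PQItem it = pq.top();
    pq.pop();
    R_xlen_t p = it.idx;
    int i = (int)(p % n1), j = (int)((p / n1) % n2), k = (int)(p / sl);
    int ii[6] = {i + 1, i - 1, i, i, i, i};
    int jj[6] = {j, j, j + 1, j - 1, j, j};
    int kk[6] = {k, k, k, k, k + 1, k - 1};
    for (int t = 0; t < 6; t++) {
      if (ii[t] < 0 || jj[t] < 0 || kk[t] < 0 || ii[t] >= n1 || jj[t] >= n2 ||
          kk[t] >= n3)
        continue;
      R_xlen_t pq2 = (R_xlen_t)kk[t] * sl + (R_xlen_t)jj[t] * n1 + ii[t];
      if (!domain[pq2] || lab[pq2] != 0) continue;
      lab[pq2] = lab[p];
      pq.push({priority[pq2], counter++, pq2});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Connected component labelling (6- or 26-connectivity) of a logical mask.

// [[Rcpp::export]]
IntegerVector cpp_label_cc(LogicalVector mask, IntegerVector dim, int conn) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t sl = (R_xlen_t)n1 * n2, n = sl * n3;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t p0 = 0; p0 < n; p0++) {
    if (!mask[p0] || lab[p0]) continue;
    next++;
    stack.clear();
    stack.push_back(p0);
    lab[p0] = next;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i = (int)(p % n1), j = (int)((p / n1) % n2), k = (int)(p / sl);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            int ad = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (ad == 0) continue;
            if (conn == 6 && ad > 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
              continue;
            R_xlen_t pq = (R_xlen_t)kk * sl + (R_xlen_t)jj * n1 + ii;
            if (mask[pq] && !lab[pq]) {
              lab[pq] = next;
              stack.push_back(pq);
            }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Rasterize cylindrical fibre segments into a solid mask. Each fibre is a
// centre point p0 = (x, y, z), a unit direction u, a radius and an axial
// extent [t0, t1] about p0 (all in voxel units, 1-based voxel-centre
// coordinates; flat end caps). The dominant axis of u must be the third
// component (fibres are walked slice by slice along axis 3); exact
// point-to-line distance is used so tilted fibres keep circular sections.

// [[Rcpp::export]]
LogicalVector cpp_rasterize_fibres(IntegerVector dim, NumericMatrix fibres) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t sl = (R_xlen_t)n1 * n2;
  LogicalVector solid((R_xlen_t)n1 * n2 * n3);
  for (int fi = 0; fi < fibres.nrow(); fi++) {
    double px = fibres(fi, 0), py = fibres(fi, 1), pz = fibres(fi, 2);
    double ux = fibres(fi, 3), uy = fibres(fi, 4), uz = fibres(fi, 5);
    double r = fibres(fi, 6);
    double t0 = fibres(fi, 7), t1 = fibres(fi, 8);
    double margin = r / std::fabs(uz) + 1.0;
    for (int k = 0; k < n3; k++) {
      double z = k + 1.0;
      double t = (z - pz) / uz;
      if (t < t0 - margin || t > t1 + margin) continue;
      double cx = px + t * ux, cy = py + t * uy;
      int ilo = std::max(0, (int)std::floor(cx - margin) - 1);
      int ihi = std::min(n1 - 1, (int)std::ceil(cx + margin));
      int jlo = std::max(0, (int)std::floor(cy - margin) - 1);
      int jhi = std::min(n2 - 1, (int)std::ceil(cy + margin));
      for (int j = jlo; j <= jhi; j++)
        for (int i = ilo; i <= ihi; i++) {
          double vx = (i + 1.0) - px, vy = (j + 1.0) - py, vz = z - pz;
          double dot = vx * ux + vy * uy + vz * uz;
          if (dot < t0 || dot > t1) continue;
          double dx = vx - dot * ux, dy = vy - dot * uy, dz = vz - dot * uz;
          if (dx * dx + dy * dy + dz * dz <= r * r)
            solid[(R_xlen_t)k * sl + (R_xlen_t)j * n1 + i] = true;
        }
    }
  }
  return solid;
}
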