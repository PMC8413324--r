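#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3D connected-component labelling (6- or 26-connectivity), two-pass
// union-find.  Labels are contiguous positive integers in scan order.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerVector label3dCpp(IntegerVector mask, IntegerVector dims,
                         int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector out(mask.size());
  // backward half-neighbourhood offsets
  std::vector<std::array<int,3> > off;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({{dx, dy, dz}});
      }
  std::vector<int> parent;
  parent.push_back(0); // dummy for label 0
  std::vector<int> lab(n, 0);
  const int *M = mask.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        if (!M[idx]) continue;
        int cur = 0;
        for (size_t o = 0; o < off.size(); ++o) {
          int ii = i + off[o][0], jj = j + off[o][1], kk = k + off[o][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          size_t nidx = ii + (size_t)nx * (jj + (size_t)ny * kk);
          int nl = lab[nidx];
          if (nl) {
            if (!cur) cur = nl;
            else uf_union(parent, cur, nl);
          }
        }
        if (!cur) {
          cur = (int)parent.size();
          parent.push_back(cur);
        }
        lab[idx] = cur;
      }
  // resolve and relabel contiguously in scan order
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (size_t idx = 0; idx < n; ++idx) {
    if (!lab[idx]) continue;
    int r = uf_find(parent, lab[idx]);
    if (!remap[r]) remap[r] = ++next;
    out[idx] = remap[r];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra on a (smoothed) scalar field.
// Each grid cell is split into 6 tetrahedra sharing the main diagonal;
// iso-vertices are linearly interpolated, coordinates in physical units.
// ---------------------------------------------------------------------------

static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};
static const int CO[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};

static inline double triArea(const double a[3], const double b[3],
                             const double c[3]) {
  double u0 = b[0]-a[0], u1 = b[1]-a[1], u2 = b[2]-a[2];
  double v0 = c[0]-a[0], v1 = c[1]-a[1], v2 = c[2]-a[2];
  double w0 = u1*v2 - u2*v1, w1 = u2*v0 - u0*v2, w2 = u0*v1 - u1*v0;
  return 0.5 * std::sqrt(w0*w0 + w1*w1 + w2*w2);
}

static inline void isoVertex(double level, const double *pa, double va,
                             const double *pb, double vb, double out[3]) {
  double t = (level - va) / (vb - va);
  out[0] = pa[0] + t * (pb[0] - pa[0]);
  out[1] = pa[1] + t * (pb[1] - pa[1]);
  out[2] = pa[2] + t * (pb[2] - pa[2]);
}

// [[Rcpp::export]]
double mtAreaCpp(NumericVector field, IntegerVector dims, double level,
                 NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double *F = field.begin();
  double area = 0.0;
  double P[8][3], V[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CO[c][0], jj = j + CO[c][1], kk = k + CO[c][2];
          double v = F[ii + (size_t)nx * (jj + (size_t)ny * kk)];
          V[c] = v;
          P[c][0] = ii * dx; P[c][1] = jj * dy; P[c][2] = kk * dz;
          if (v > level) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          int above[4], below[4]; int na = 0, nb = 0;
          for (int m = 0; m < 4; ++m) {
            int c = TETS[t][m];
            if (V[c] > level) above[na++] = c; else below[nb++] = c;
          }
          if (na == 0 || nb == 0) continue;
          double q[4][3];
          if (na == 1 || nb == 1) {
            int apex = (na == 1) ? above[0] : below[0];
            int *base = (na == 1) ? below : above;
            for (int m = 0; m < 3; ++m)
              isoVertex(level, P[apex], V[apex], P[base[m]], V[base[m]], q[m]);
            area += triArea(q[0], q[1], q[2]);
          } else {
            isoVertex(level, P[above[0]], V[above[0]], P[below[0]], V[below[0]], q[0]);
            isoVertex(level, P[above[0]], V[above[0]], P[below[1]], V[below[1]], q[1]);
            isoVertex(level, P[above[1]], V[above[1]], P[below[1]], V[below[1]], q[2]);
            isoVertex(level, P[above[1]], V[above[1]], P[below[0]], V[below[0]], q[3]);
            area += triArea(q[0], q[1], q[2]);
            area += triArea(q[0], q[2], q[3]);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Cylindrical K-function on a rectangular (r, t) grid with translation
// edge correction for a box window.  Pair (i, j) contributes
// 1 / |W ∩ W_h| at the smallest grid cell containing (perp, |axial|);
// the cumulative sum over both grid axes then yields the estimate at
// every (r, t) simultaneously.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cylKCpp(NumericMatrix pts, NumericVector u,
                      NumericVector rvals, NumericVector tvals,
                      NumericVector lo, NumericVector hi) {
  const int n = pts.nrow();
  const int nr = rvals.size(), nt = tvals.size();
  NumericMatrix K(nr, nt);
  if (n < 2) return K;
  const double Lx = hi[0] - lo[0], Ly = hi[1] - lo[1], Lz = hi[2] - lo[2];
  const double volW = Lx * Ly * Lz;
  const double rmax = rvals[nr - 1], tmax = tvals[nt - 1];
  std::vector<double> bin(nr * (size_t)nt, 0.0);
  const double *X = &pts(0, 0), *Y = &pts(0, 1), *Z = &pts(0, 2);
  const double ux = u[0], uy = u[1], uz = u[2];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double hx = X[j] - X[i], hy = Y[j] - Y[i], hz = Z[j] - Z[i];
      double axial = std::fabs(hx * ux + hy * uy + hz * uz);
      if (axial > tmax) continue;
      double h2 = hx * hx + hy * hy + hz * hz;
      double perp2 = h2 - axial * axial;
      if (perp2 < 0) perp2 = 0;
      double perp = std::sqrt(perp2);
      if (perp > rmax) continue;
      double w = (Lx - std::fabs(hx)) * (Ly - std::fabs(hy)) *
                 (Lz - std::fabs(hz));
      if (w <= 0) continue;
      int ri = (int)(std::lower_bound(rvals.begin(), rvals.end(), perp) -
                     rvals.begin());
      int ti = (int)(std::lower_bound(tvals.begin(), tvals.end(), axial) -
                     tvals.begin());
      if (ri >= nr || ti >= nt) continue;
      bin[ri + (size_t)nr * ti] += 2.0 / w; // both ordered pairs
    }
  }
  // 2D cumulative sum
  for (int ti = 0; ti < nt; ++ti)
    for (int ri = 1; ri < nr; ++ri)
      bin[ri + (size_t)nr * ti] += bin[ri - 1 + (size_t)nr * ti];
  for (int ti = 1; ti < nt; ++ti)
    for (int ri = 0; ri < nr; ++ri)
      bin[ri + (size_t)nr * ti] += bin[ri + (size_t)nr * (ti - 1)];
  const double scale = volW * volW / ((double)n * (n - 1));
  for (int ti = 0; ti < nt; ++ti)
    for (int ri = 0; ri < nr; ++ri)
      K(ri, ti) = scale * bin[ri + (size_t)nr * ti];
  return K;
}

// ---------------------------------------------------------------------------
// Diameter (maximum pairwise distance) of a point cloud, brute force.
// Returns (dmax, i, j) with 1-based indices.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector maxPairDistCpp(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0; int bi = 1, bj = 1;
  const double *X = &pts(0, 0), *Y = &pts(0, 1), *Z = &pts(0, 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; bi = i + 1; bj = j + 1; }
    }
  return NumericVector::create(std::sqrt(best), bi, bj);
}
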