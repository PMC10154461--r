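// Low-level image kernels: spacing-aware Euclidean distance transform,
// separable Gaussian filtering, grey-level matrix accumulation and
// isosurface meshing. All arrays are R column-major (nx, ny, nz),
// linear index i + nx*(j + ny*k).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e30;

// 1D squared distance transform (lower envelope of parabolas),
// sample step s in mm.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double sq = q * s;
    double fs;
    for (;;) {
      double sv = v[k] * s;
      fs = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * (sq - sv));
      if (k > 0 && fs <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = fs;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double sq = q * s;
    while (z[k + 1] < sq) k++;
    double sv = v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest
// zero voxel centre. in_plane = true restricts to within-slice (x,y).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing, bool in_plane) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t t = 0; t < n; t++) d[t] = mask[t] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = d[base + i];
      dt1d(f, dd, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) d[base + i] = dd[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = d[base + (R_xlen_t)nx * j];
      dt1d(f, dd, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) d[base + (R_xlen_t)nx * j] = dd[j];
    }
  if (!in_plane) {
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t base = i + (R_xlen_t)nx * j;
        R_xlen_t step = (R_xlen_t)nx * ny;
        for (int k = 0; k < nz; k++) f[k] = d[base + step * k];
        dt1d(f, dd, v, z, nz, spacing[2]);
        for (int k = 0; k < nz; k++) d[base + step * k] = dd[k];
      }
  }
  return d;
}

static void conv1d_reflect(std::vector<double>& line, int n,
                           const std::vector<double>& w, int r,
                           std::vector<double>& out) {
  for (int i = 0; i < n; i++) {
    double acc = 0.0;
    for (int t = -r; t <= r; t++) {
      int p = i + t;
      if (p < 0) p = -p - 1;          // reflect about -0.5
      if (p >= n) p = 2 * n - 1 - p;  // reflect about n-0.5
      acc += w[t + r] * line[p];
    }
    out[i] = acc;
  }
}

// Separable Gaussian blur with per-axis sigma in voxel units,
// reflecting boundary. sigma <= 0 skips the axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d = clone(vol);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), out(nmax);

  for (int ax = 0; ax < 3; ax++) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    if (r < 1) r = 1;
    std::vector<double> w(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; t++) {
      w[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += w[t + r];
    }
    for (int t = 0; t <= 2 * r; t++) w[t] /= sum;

    if (ax == 0) {
      for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++) {
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int i = 0; i < nx; i++) line[i] = d[base + i];
          conv1d_reflect(line, nx, w, r, out);
          for (int i = 0; i < nx; i++) d[base + i] = out[i];
        }
    } else if (ax == 1) {
      for (int k = 0; k < nz; k++)
        for (int i = 0; i < nx; i++) {
          R_xlen_t base = i + (R_xlen_t)nx * ny * k;
          for (int j = 0; j < ny; j++) line[j] = d[base + (R_xlen_t)nx * j];
          conv1d_reflect(line, ny, w, r, out);
          for (int j = 0; j < ny; j++) d[base + (R_xlen_t)nx * j] = out[j];
        }
    } else {
      R_xlen_t step = (R_xlen_t)nx * ny;
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          R_xlen_t base = i + (R_xlen_t)nx * j;
          for (int k = 0; k < nz; k++) line[k] = d[base + step * k];
          conv1d_reflect(line, nz, w, r, out);
          for (int k = 0; k < nz; k++) d[base + step * k] = out[k];
        }
    }
  }
  (void)n;
  return d;
}

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// Symmetric co-occurrence counts for the 13 unique distance-1 3D
// directions: returns ng x ng x 13 (levels 0 = outside ROI are skipped).
// [[Rcpp::export]]
NumericVector cpp_glcm13(IntegerVector lev, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector P((R_xlen_t)ng * ng * 13);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int a = lev[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (a == 0) continue;
        for (int d = 0; d < 13; d++) {
          int ii = i + DIR13[d][0], jj = j + DIR13[d][1], kk = k + DIR13[d][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          int b = lev[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          if (b == 0) continue;
          P[(a - 1) + (R_xlen_t)ng * (b - 1) + (R_xlen_t)ng * ng * d] += 1.0;
          P[(b - 1) + (R_xlen_t)ng * (a - 1) + (R_xlen_t)ng * ng * d] += 1.0;
        }
      }
  return P;
}

// Run-length counts per direction: ng x maxlen x 13.
// [[Rcpp::export]]
NumericVector cpp_glrlm13(IntegerVector lev, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector P((R_xlen_t)ng * maxlen * 13);
  for (int d = 0; d < 13; d++) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (pi >= 0 && pi < nx && pj >= 0 && pj < ny && pk >= 0 && pk < nz)
            continue;  // not a line start
          int cur = 0, len = 0;
          int ii = i, jj = j, kk = k;
          while (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz) {
            int a = lev[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
            if (a == cur && a != 0) {
              len++;
            } else {
              if (cur != 0)
                P[(cur - 1) + (R_xlen_t)ng * (len - 1) + (R_xlen_t)ng * maxlen * d] += 1.0;
              cur = a;
              len = (a != 0) ? 1 : 0;
            }
            ii += dx; jj += dy; kk += dz;
          }
          if (cur != 0)
            P[(cur - 1) + (R_xlen_t)ng * (len - 1) + (R_xlen_t)ng * maxlen * d] += 1.0;
        }
  }
  return P;
}

// Connected zones of equal grey level (26-connectivity).
// Returns a 2-column matrix: level, zone size.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector lev, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (seen[s] || lev[s] == 0) continue;
    int g = lev[s];
    int size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      size++;
      int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (!seen[q] && lev[q] == g) {
              seen[q] = 1;
              stack.push_back(q);
            }
          }
    }
    zl.push_back(g);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t t = 0; t < zl.size(); t++) {
    out(t, 0) = zl[t];
    out(t, 1) = zs[t];
  }
  return out;
}

// Dependence counts: ng x 27 matrix; column (d+1) counts voxels of a
// given level having d 26-neighbours within +/- alpha grey levels.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lev, IntegerVector dims, int ng, int alpha) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix P(ng, 27);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int a = lev[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (a == 0) continue;
        int dep = 0;
        for (int dk = -1; dk <= 1; dk++)
          for (int dj = -1; dj <= 1; dj++)
            for (int di = -1; di <= 1; di++) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              int b = lev[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
              if (b != 0 && std::abs(a - b) <= alpha) dep++;
            }
        P(a - 1, dep) += 1.0;
      }
  return P;
}

// Neighbourhood grey-tone difference accumulators: per level the count
// n_i of contributing voxels and s_i = sum |i - mean(26-neighbourhood)|.
// Voxels with no in-ROI neighbour do not contribute.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector lev, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector ncnt(ng), svec(ng);
  double nvp = 0.0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int a = lev[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; dk++)
          for (int dj = -1; dj <= 1; dj++)
            for (int di = -1; di <= 1; di++) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              int b = lev[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
              if (b != 0) { sum += b; cnt++; }
            }
        if (cnt > 0) {
          ncnt[a - 1] += 1.0;
          svec[a - 1] += std::fabs(a - sum / cnt);
          nvp += 1.0;
        }
      }
  return List::create(_["n"] = ncnt, _["s"] = svec, _["nvp"] = nvp);
}

// Marching tetrahedra on a scalar field: isosurface area (mm^2) and
// enclosed volume (mm^3) at the given iso level. Cube split into six
// tetrahedra around the main diagonal; edge vertices linearly
// interpolated; triangles oriented outward (high side inside).
static const int CUBE_OFF[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};
static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};

// [[Rcpp::export]]
NumericVector cpp_march_tets(NumericVector field, IntegerVector dims,
                             NumericVector spacing, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol = 0.0;
  double P[8][3], V[8];

  for (int k = 0; k + 1 < nz; k++)
    for (int j = 0; j + 1 < ny; j++)
      for (int i = 0; i + 1 < nx; i++) {
        int nin8 = 0;
        for (int c = 0; c < 8; c++) {
          int ci = i + CUBE_OFF[c][0], cj = j + CUBE_OFF[c][1], ck = k + CUBE_OFF[c][2];
          V[c] = field[ci + (R_xlen_t)nx * (cj + (R_xlen_t)ny * ck)];
          P[c][0] = ci * sx; P[c][1] = cj * sy; P[c][2] = ck * sz;
          if (V[c] >= iso) nin8++;
        }
        if (nin8 == 0 || nin8 == 8) continue;

        for (int t = 0; t < 6; t++) {
          int vin[4], vout[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; c++) {
            int idx = TETS[t][c];
            if (V[idx] >= iso) vin[nin++] = idx; else vout[nout++] = idx;
          }
          if (nin == 0 || nin == 4) continue;

          // reference direction: inside -> outside
          double ref[3] = {0, 0, 0};
          for (int c = 0; c < nout; c++)
            for (int a = 0; a < 3; a++) ref[a] += P[vout[c]][a] / nout;
          for (int c = 0; c < nin; c++)
            for (int a = 0; a < 3; a++) ref[a] -= P[vin[c]][a] / nin;

          double tri[2][3][3];
          int ntri = 0;
          auto ipt = [&](int a, int b, double* out) {
            double tt = (iso - V[a]) / (V[b] - V[a]);
            for (int x = 0; x < 3; x++) out[x] = P[a][x] + tt * (P[b][x] - P[a][x]);
          };
          if (nin == 1) {
            ipt(vin[0], vout[0], tri[0][0]);
            ipt(vin[0], vout[1], tri[0][1]);
            ipt(vin[0], vout[2], tri[0][2]);
            ntri = 1;
          } else if (nin == 3) {
            ipt(vout[0], vin[0], tri[0][0]);
            ipt(vout[0], vin[1], tri[0][1]);
            ipt(vout[0], vin[2], tri[0][2]);
            ntri = 1;
          } else {  // nin == 2
            double m[4][3];
            ipt(vin[0], vout[0], m[0]);
            ipt(vin[0], vout[1], m[1]);
            ipt(vin[1], vout[1], m[2]);
            ipt(vin[1], vout[0], m[3]);
            for (int x = 0; x < 3; x++) {
              tri[0][0][x] = m[0][x]; tri[0][1][x] = m[1][x]; tri[0][2][x] = m[2][x];
              tri[1][0][x] = m[0][x]; tri[1][1][x] = m[2][x]; tri[1][2][x] = m[3][x];
            }
            ntri = 2;
          }
          for (int q = 0; q < ntri; q++) {
            double e1[3], e2[3], nvec[3];
            for (int x = 0; x < 3; x++) {
              e1[x] = tri[q][1][x] - tri[q][0][x];
              e2[x] = tri[q][2][x] - tri[q][0][x];
            }
            nvec[0] = e1[1] * e2[2] - e1[2] * e2[1];
            nvec[1] = e1[2] * e2[0] - e1[0] * e2[2];
            nvec[2] = e1[0] * e2[1] - e1[1] * e2[0];
            double dot = nvec[0] * ref[0] + nvec[1] * ref[1] + nvec[2] * ref[2];
            if (dot < 0)
              for (int x = 0; x < 3; x++) {
                double tmp = tri[q][1][x]; tri[q][1][x] = tri[q][2][x]; tri[q][2][x] = tmp;
                nvec[x] = -nvec[x];
              }
            double nn = std::sqrt(nvec[0] * nvec[0] + nvec[1] * nvec[1] + nvec[2] * nvec[2]);
            area += 0.5 * nn;
            // signed volume of tetra (origin, p0, p1, p2); outward normals sum
            // to the enclosed volume by the divergence theorem
            double* p0 = tri[q][0];
            double c1[3], c2[3];
            for (int x = 0; x < 3; x++) { c1[x] = tri[q][1][x]; c2[x] = tri[q][2][x]; }
            double cx = c1[1] * c2[2] - c1[2] * c2[1];
            double cy = c1[2] * c2[0] - c1[0] * c2[2];
            double cz = c1[0] * c2[1] - c1[1] * c2[0];
            vol += (p0[0] * cx + p0[1] * cy + p0[2] * cz) / 6.0;
          }
        }
      }
  return NumericVector::create(area, vol);
}

// Largest pairwise Euclidean distance between rows of a point matrix.
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
  int n = pts.nrow(), m = pts.ncol();
  double best = 0.0;
  for (int a = 0; a < n; a++)
    for (int b = a + 1; b < n; b++) {
      double s = 0.0;
      for (int c = 0; c < m; c++) {
        double d = pts(a, c) - pts(b, c);
        s += d * d;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
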