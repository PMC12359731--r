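// Low-level voxel kernels: texture-matrix accumulation, exact Euclidean
// distance transform, connected components, and marching-tetrahedra surface
// area. Feature formulas live in R; only the O(n_voxels) scans are compiled.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// 13 unique 3D offsets (one of each +/- pair); the reverse directions are
// recovered by transposition (GLCM) or are redundant (GLRLM).
static const int DIRS[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline int at(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// levels: integer array, 0 outside the ROI, 1..ng inside.

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dim, int ng,
                       int distance) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector out(static_cast<R_xlen_t>(ng) * ng * 13);
    for (int d = 0; d < 13; ++d) {
        int dx = DIRS[d][0] * distance, dy = DIRS[d][1] * distance,
            dz = DIRS[d][2] * distance;
        double *slab = out.begin() + static_cast<R_xlen_t>(d) * ng * ng;
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int li = levels[at(x, y, z, nx, ny)];
                    if (li == 0) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                    int lj = levels[at(x2, y2, z2, nx, ny)];
                    if (lj == 0) continue;
                    slab[(li - 1) + ng * (lj - 1)] += 1.0;
                }
    }
    out.attr("dim") = IntegerVector::create(ng, ng, 13);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int maxlen = std::max(nx, std::max(ny, nz));
    NumericVector out(static_cast<R_xlen_t>(ng) * maxlen * 13);
    for (int d = 0; d < 13; ++d) {
        int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        double *slab = out.begin() + static_cast<R_xlen_t>(d) * ng * maxlen;
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int li = levels[at(x, y, z, nx, ny)];
                    if (li == 0) continue;
                    // run starts where the backward neighbour breaks the run
                    int xb = x - dx, yb = y - dy, zb = z - dz;
                    if (inside(xb, yb, zb, nx, ny, nz) &&
                        levels[at(xb, yb, zb, nx, ny)] == li)
                        continue;
                    int len = 1;
                    int xf = x + dx, yf = y + dy, zf = z + dz;
                    while (inside(xf, yf, zf, nx, ny, nz) &&
                           levels[at(xf, yf, zf, nx, ny)] == li) {
                        ++len; xf += dx; yf += dy; zf += dz;
                    }
                    slab[(li - 1) + ng * (len - 1)] += 1.0;
                }
    }
    out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
    return out;
}

// Zones of identical gray level, 26-connected. Returns a 2-column matrix
// (level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int n = nx * ny * nz;
    std::vector<char> seen(n, 0);
    std::vector<int> zl, zs, stack;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int i0 = at(x, y, z, nx, ny);
                int lv = levels[i0];
                if (lv == 0 || seen[i0]) continue;
                int size = 0;
                stack.clear();
                stack.push_back(i0);
                seen[i0] = 1;
                while (!stack.empty()) {
                    int i = stack.back(); stack.pop_back();
                    ++size;
                    int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
                    for (int ddz = -1; ddz <= 1; ++ddz)
                        for (int ddy = -1; ddy <= 1; ++ddy)
                            for (int ddx = -1; ddx <= 1; ++ddx) {
                                if (!ddx && !ddy && !ddz) continue;
                                int x2 = cx + ddx, y2 = cy + ddy, z2 = cz + ddz;
                                if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                                int j = at(x2, y2, z2, nx, ny);
                                if (!seen[j] && levels[j] == lv) {
                                    seen[j] = 1;
                                    stack.push_back(j);
                                }
                            }
                }
                zl.push_back(lv);
                zs.push_back(size);
            }
    IntegerMatrix out(zl.size(), 2);
    for (size_t k = 0; k < zl.size(); ++k) {
        out(k, 0) = zl[k];
        out(k, 1) = zs[k];
    }
    return out;
}

// Dependence counts: for each ROI voxel, the number of 26-neighbours inside
// the ROI whose level differs by at most alpha. Returns ng x 27 counts
// (dependence 0..26).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int alpha) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int ng = 0;
    for (int i = 0; i < levels.size(); ++i) ng = std::max(ng, levels[i]);
    NumericMatrix out(std::max(ng, 1), 27);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int li = levels[at(x, y, z, nx, ny)];
                if (li == 0) continue;
                int dep = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                            int lj = levels[at(x2, y2, z2, nx, ny)];
                            if (lj != 0 && std::abs(lj - li) <= alpha) ++dep;
                        }
                out(li - 1, dep) += 1.0;
            }
    return out;
}

// NGTDM: per-level voxel counts n_i and summed absolute deviation s_i from
// the mean level of the available in-ROI 26-neighbours.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericMatrix out(ng, 2);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int li = levels[at(x, y, z, nx, ny)];
                if (li == 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                            int lj = levels[at(x2, y2, z2, nx, ny)];
                            if (lj != 0) { sum += lj; ++cnt; }
                        }
                out(li - 1, 0) += 1.0;
                if (cnt > 0) out(li - 1, 1) += std::fabs(li - sum / cnt);
            }
    return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with sampling
// interval w; f is the squared distance so far.
static void dt1d(std::vector<double> &f, double w) {
    int n = f.size();
    std::vector<int> v(n);
    std::vector<double> zb(n + 1), d(n);
    int k = 0;
    v[0] = 0;
    zb[0] = -std::numeric_limits<double>::infinity();
    zb[1] = std::numeric_limits<double>::infinity();
    double w2 = w * w;
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            int p = v[k];
            s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
                (2.0 * w2 * (q - p));
            if (k > 0 && s <= zb[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        zb[k] = s;
        zb[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (zb[k + 1] < q) ++k;
        int p = v[k];
        d[q] = w2 * (q - p) * (q - p) + f[p];
    }
    f.swap(d);
}

// Exact squared Euclidean distance (physical units) from every voxel centre
// to the nearest foreground voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector out(mask.size());
    // large finite sentinel keeps the envelope arithmetic exact
    const double BIG = 1e20;
    for (int i = 0; i < mask.size(); ++i) out[i] = mask[i] ? 0.0 : BIG;
    // x pass
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            std::vector<double> f(nx);
            for (int x = 0; x < nx; ++x) f[x] = out[at(x, y, z, nx, ny)];
            dt1d(f, spacing[0]);
            for (int x = 0; x < nx; ++x) out[at(x, y, z, nx, ny)] = f[x];
        }
    // y pass
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            std::vector<double> f(ny);
            for (int y = 0; y < ny; ++y) f[y] = out[at(x, y, z, nx, ny)];
            dt1d(f, spacing[1]);
            for (int y = 0; y < ny; ++y) out[at(x, y, z, nx, ny)] = f[y];
        }
    // z pass
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            std::vector<double> f(nz);
            for (int z = 0; z < nz; ++z) f[z] = out[at(x, y, z, nx, ny)];
            dt1d(f, spacing[2]);
            for (int z = 0; z < nz; ++z) out[at(x, y, z, nx, ny)] = f[z];
        }
    out.attr("dim") = dim;
    return out;
}

// 6-connected component labelling of a binary mask (labels 1..k, 0 outside).
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    IntegerVector lab(mask.size());
    int next = 0;
    std::vector<int> stack;
    const int N6[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
    for (int i = 0; i < mask.size(); ++i) {
        if (!mask[i] || lab[i]) continue;
        ++next;
        stack.clear();
        stack.push_back(i);
        lab[i] = next;
        while (!stack.empty()) {
            int j = stack.back(); stack.pop_back();
            int cx = j % nx, cy = (j / nx) % ny, cz = j / (nx * ny);
            for (int d = 0; d < 6; ++d) {
                int x2 = cx + N6[d][0], y2 = cy + N6[d][1], z2 = cz + N6[d][2];
                if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                int k = at(x2, y2, z2, nx, ny);
                if (mask[k] && !lab[k]) { lab[k] = next; stack.push_back(k); }
            }
        }
    }
    lab.attr("dim") = dim;
    return lab;
}

static inline void lerp(const double *p0, const double *p1, double f0,
                        double f1, double iso, double *out) {
    double t = (f1 - f0) == 0.0 ? 0.5 : (iso - f0) / (f1 - f0);
    for (int k = 0; k < 3; ++k) out[k] = p0[k] + t * (p1[k] - p0[k]);
}

static inline double tri_area(const double *a, const double *b,
                              const double *c) {
    double u[3], v[3], w[3];
    for (int k = 0; k < 3; ++k) { u[k] = b[k] - a[k]; v[k] = c[k] - a[k]; }
    w[0] = u[1] * v[2] - u[2] * v[1];
    w[1] = u[2] * v[0] - u[0] * v[2];
    w[2] = u[0] * v[1] - u[1] * v[0];
    return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

static double tet_surface(const double p[4][3], const double f[4],
                          double iso) {
    int above[4], nab = 0;
    for (int c = 0; c < 4; ++c)
        if (f[c] > iso) above[nab++] = c;
    if (nab == 0 || nab == 4) return 0.0;
    double e[4][3];
    if (nab == 1 || nab == 3) {
        int apex = -1;
        for (int c = 0; c < 4; ++c) {
            bool isAb = f[c] > iso;
            if ((nab == 1 && isAb) || (nab == 3 && !isAb)) apex = c;
        }
        int m = 0;
        for (int c = 0; c < 4; ++c) {
            if (c == apex) continue;
            lerp(p[apex], p[c], f[apex], f[c], iso, e[m]);
            ++m;
        }
        return tri_area(e[0], e[1], e[2]);
    }
    int lo[2], hi[2], nl = 0, nh = 0;
    for (int c = 0; c < 4; ++c) {
        if (f[c] > iso) hi[nh++] = c; else lo[nl++] = c;
    }
    lerp(p[hi[0]], p[lo[0]], f[hi[0]], f[lo[0]], iso, e[0]);
    lerp(p[hi[0]], p[lo[1]], f[hi[0]], f[lo[1]], iso, e[1]);
    lerp(p[hi[1]], p[lo[1]], f[hi[1]], f[lo[1]], iso, e[2]);
    lerp(p[hi[1]], p[lo[0]], f[hi[1]], f[lo[0]], iso, e[3]);
    return tri_area(e[0], e[1], e[2]) + tri_area(e[0], e[2], e[3]);
}

// Iso-surface area by marching tetrahedra on a symmetric 24-tetrahedra
// decomposition of each cell (body centre + 6 face centres, interpolated as
// vertex averages), which avoids the diagonal bias of the classic 6-tet
// split. Coordinates in physical units.
// [[Rcpp::export]]
double cpp_mt_area(NumericVector field, IntegerVector dim,
                   NumericVector spacing, double iso) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    static const int CO[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                 {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
    // faces as corner quads in cyclic order
    static const int FACES[6][4] = {{0, 1, 2, 3}, {4, 5, 6, 7}, {0, 1, 5, 4},
                                    {3, 2, 6, 7}, {0, 3, 7, 4}, {1, 2, 6, 5}};
    double area = 0.0;
    for (int z = 0; z + 1 < nz; ++z)
        for (int y = 0; y + 1 < ny; ++y)
            for (int x = 0; x + 1 < nx; ++x) {
                double fv[8];
                double pv[8][3];
                double fmin = 1e300, fmax = -1e300;
                for (int c = 0; c < 8; ++c) {
                    int xx = x + CO[c][0], yy = y + CO[c][1], zz = z + CO[c][2];
                    fv[c] = field[at(xx, yy, zz, nx, ny)];
                    if (fv[c] < fmin) fmin = fv[c];
                    if (fv[c] > fmax) fmax = fv[c];
                    pv[c][0] = xx * spacing[0];
                    pv[c][1] = yy * spacing[1];
                    pv[c][2] = zz * spacing[2];
                }
                if (fmin > iso || fmax <= iso) continue; // cell off-surface
                double fc = 0.0, pc[3] = {0, 0, 0};
                for (int c = 0; c < 8; ++c) {
                    fc += fv[c] / 8.0;
                    for (int k = 0; k < 3; ++k) pc[k] += pv[c][k] / 8.0;
                }
                for (int fi = 0; fi < 6; ++fi) {
                    const int *F = FACES[fi];
                    double ff = 0.0, pf[3] = {0, 0, 0};
                    for (int c = 0; c < 4; ++c) {
                        ff += fv[F[c]] / 4.0;
                        for (int k = 0; k < 3; ++k) pf[k] += pv[F[c]][k] / 4.0;
                    }
                    for (int e = 0; e < 4; ++e) {
                        int a = F[e], b = F[(e + 1) % 4];
                        double tp[4][3], tf[4];
                        for (int k = 0; k < 3; ++k) {
                            tp[0][k] = pc[k];
                            tp[1][k] = pf[k];
                            tp[2][k] = pv[a][k];
                            tp[3][k] = pv[b][k];
                        }
                        tf[0] = fc; tf[1] = ff; tf[2] = fv[a]; tf[3] = fv[b];
                        area += tet_surface(tp, tf, iso);
                    }
                }
            }
    return area;
}
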