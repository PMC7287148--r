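#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Continuous voxel index of a world coordinate for an axis-aligned grid:
// world = origin + index * spacing  (indices 0-based, voxel centers).
static inline void worldToIndex(const double *w, const double *origin,
                                const double *spacing, double *idx) {
    for (int a = 0; a < 3; ++a) idx[a] = (w[a] - origin[a]) / spacing[a];
}

// Trilinear interpolation of `vol` (dims d0,d1,d2, column-major) at a
// continuous voxel index (ix,iy,iz). Out-of-grid samples return `fill`.
// Optionally also returns the gradient with respect to the *index* coords.
static inline double sampleTrilinear(const double *vol, const int *d,
                                     double ix, double iy, double iz,
                                     double fill, double *gradIdx) {
    if (ix < 0 || iy < 0 || iz < 0 ||
        ix > d[0] - 1 || iy > d[1] - 1 || iz > d[2] - 1) {
        if (gradIdx) gradIdx[0] = gradIdx[1] = gradIdx[2] = 0.0;
        return fill;
    }
    int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy), z0 = (int)std::floor(iz);
    if (x0 == d[0] - 1) --x0;
    if (y0 == d[1] - 1) --y0;
    if (z0 == d[2] - 1) --z0;
    if (d[0] == 1) x0 = 0;
    if (d[1] == 1) y0 = 0;
    if (d[2] == 1) z0 = 0;
    double fx = ix - x0, fy = iy - y0, fz = iz - z0;
    int x1 = std::min(x0 + 1, d[0] - 1);
    int y1 = std::min(y0 + 1, d[1] - 1);
    int z1 = std::min(z0 + 1, d[2] - 1);
    const R_xlen_t sx = 1, sy = d[0], sz = (R_xlen_t)d[0] * d[1];
    double c000 = vol[x0 * sx + y0 * sy + z0 * sz];
    double c100 = vol[x1 * sx + y0 * sy + z0 * sz];
    double c010 = vol[x0 * sx + y1 * sy + z0 * sz];
    double c110 = vol[x1 * sx + y1 * sy + z0 * sz];
    double c001 = vol[x0 * sx + y0 * sy + z1 * sz];
    double c101 = vol[x1 * sx + y0 * sy + z1 * sz];
    double c011 = vol[x0 * sx + y1 * sy + z1 * sz];
    double c111 = vol[x1 * sx + y1 * sy + z1 * sz];
    double c00 = c000 + (c100 - c000) * fx;
    double c10 = c010 + (c110 - c010) * fx;
    double c01 = c001 + (c101 - c001) * fx;
    double c11 = c011 + (c111 - c011) * fx;
    double c0 = c00 + (c10 - c00) * fy;
    double c1 = c01 + (c11 - c01) * fy;
    if (gradIdx) {
        double d00 = c100 - c000, d10 = c110 - c010;
        double d01 = c101 - c001, d11 = c111 - c011;
        gradIdx[0] = (d00 + (d10 - d00) * fy) * (1 - fz) + (d01 + (d11 - d01) * fy) * fz;
        double e0 = c10 - c00, e1 = c11 - c01;
        gradIdx[1] = e0 + (e1 - e0) * fz;
        gradIdx[2] = c1 - c0;
    }
    return c0 + (c1 - c0) * fz;
}

// [[Rcpp::export(name = ".cppInterpTrilinear")]]
NumericVector cppInterpTrilinear(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix coords, double fill) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    const double sp[3] = {spacing[0], spacing[1], spacing[2]};
    const double org[3] = {origin[0], origin[1], origin[2]};
    const R_xlen_t n = coords.nrow();
    NumericVector out(n);
    const double *v = vol.begin();
    for (R_xlen_t i = 0; i < n; ++i) {
        double w[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
        double idx[3];
        worldToIndex(w, org, sp, idx);
        out[i] = sampleTrilinear(v, d, idx[0], idx[1], idx[2], fill, nullptr);
    }
    return out;
}

// Mean-squared-difference metric between fixed values and the moving volume
// sampled at given world coordinates (one coord row per fixed value).
// [[Rcpp::export(name = ".cppMseAt")]]
double cppMseAt(NumericVector fixedVals, NumericVector mov, IntegerVector dim,
                NumericVector spacing, NumericVector origin,
                NumericMatrix coords, double fill) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    const double sp[3] = {spacing[0], spacing[1], spacing[2]};
    const double org[3] = {origin[0], origin[1], origin[2]};
    const R_xlen_t n = coords.nrow();
    const double *v = mov.begin();
    double acc = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        double w[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
        double idx[3];
        worldToIndex(w, org, sp, idx);
        double r = sampleTrilinear(v, d, idx[0], idx[1], idx[2], fill, nullptr) - fixedVals[i];
        acc += r * r;
    }
    return acc / (double)n;
}

// Cubic B-spline basis weights of the fractional position t in [0,1].
static inline void bspline4(double t, double *w) {
    double t2 = t * t, t3 = t2 * t;
    w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
    w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
    w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
    w[3] = t3 / 6.0;
}

static inline int clampi(int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
}

// Cubic B-spline interpolation of the control-point displacements at one
// world coordinate; fills idx64/w64 (support indices and weights) and u.
static inline void ctrlSupport(const double *p, const int *cd,
                               const double *csp, const double *corg,
                               R_xlen_t *idx64, double *w64) {
    double c[3];
    int i0[3];
    double wx[4], wy[4], wz[4];
    for (int a = 0; a < 3; ++a) {
        c[a] = (p[a] - corg[a]) / csp[a];
        int fl = (int)std::floor(c[a]);
        double t = c[a] - fl;
        if (a == 0) bspline4(t, wx);
        else if (a == 1) bspline4(t, wy);
        else bspline4(t, wz);
        i0[a] = fl - 1;
    }
    int k = 0;
    for (int dz = 0; dz < 4; ++dz)
        for (int dy = 0; dy < 4; ++dy)
            for (int dx = 0; dx < 4; ++dx) {
                int xi = clampi(i0[0] + dx, 0, cd[0] - 1);
                int yi = clampi(i0[1] + dy, 0, cd[1] - 1);
                int zi = clampi(i0[2] + dz, 0, cd[2] - 1);
                idx64[k] = (R_xlen_t)xi + (R_xlen_t)cd[0] * yi +
                           (R_xlen_t)cd[0] * cd[1] * zi;
                w64[k] = wx[dx] * wy[dy] * wz[dz];
                ++k;
            }
}

// MSE + analytic gradient for a free-form deformation parameterized by
// displacements on a coarse control lattice with cubic B-spline basis.
//
//   y_i = base_i + u(x_i),   u(x) = sum_j B_j(x) c_j
//   cost = mean_i (M(y_i) - F_i)^2
//
// base_i is the rigid-initialized moving-space coordinate of fixed voxel i,
// x_i its fixed-space world coordinate (where the control lattice lives).
// Returns list(cost, grad) with grad a (#ctrl x 3) matrix.
// [[Rcpp::export(name = ".cppFfdMseGrad")]]
List cppFfdMseGrad(NumericVector fixedVals, NumericMatrix base,
                   NumericMatrix fixedWorld, NumericVector mov,
                   IntegerVector dim, NumericVector spacing,
                   NumericVector origin, IntegerVector ctrlDim,
                   NumericVector ctrlSpacing, NumericVector ctrlOrigin,
                   NumericMatrix ctrlDisp, double fill) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    const double sp[3] = {spacing[0], spacing[1], spacing[2]};
    const double org[3] = {origin[0], origin[1], origin[2]};
    const int cd[3] = {ctrlDim[0], ctrlDim[1], ctrlDim[2]};
    const double csp[3] = {ctrlSpacing[0], ctrlSpacing[1], ctrlSpacing[2]};
    const double corg[3] = {ctrlOrigin[0], ctrlOrigin[1], ctrlOrigin[2]};
    const R_xlen_t n = fixedVals.size();
    const R_xlen_t nc = ctrlDisp.nrow();
    const double *v = mov.begin();
    NumericMatrix grad(nc, 3);
    double acc = 0.0;
    R_xlen_t idx64[64];
    double w64[64];

    for (R_xlen_t i = 0; i < n; ++i) {
        double p[3] = {fixedWorld(i, 0), fixedWorld(i, 1), fixedWorld(i, 2)};
        ctrlSupport(p, cd, csp, corg, idx64, w64);
        double u[3] = {0, 0, 0};
        for (int k = 0; k < 64; ++k) {
            u[0] += w64[k] * ctrlDisp(idx64[k], 0);
            u[1] += w64[k] * ctrlDisp(idx64[k], 1);
            u[2] += w64[k] * ctrlDisp(idx64[k], 2);
        }
        double y[3] = {base(i, 0) + u[0], base(i, 1) + u[1], base(i, 2) + u[2]};
        double idx[3], gIdx[3];
        worldToIndex(y, org, sp, idx);
        double val = sampleTrilinear(v, d, idx[0], idx[1], idx[2], fill, gIdx);
        double r = val - fixedVals[i];
        acc += r * r;
        double gy[3] = {gIdx[0] / sp[0], gIdx[1] / sp[1], gIdx[2] / sp[2]};
        for (int k = 0; k < 64; ++k) {
            double f = 2.0 * r * w64[k] / (double)n;
            grad(idx64[k], 0) += f * gy[0];
            grad(idx64[k], 1) += f * gy[1];
            grad(idx64[k], 2) += f * gy[2];
        }
    }
    return List::create(Named("cost") = acc / (double)n, Named("grad") = grad);
}

// Displacement (mm) of the cubic B-spline control lattice at arbitrary
// world coordinates, matching .cppFfdMseGrad.
// [[Rcpp::export(name = ".cppCtrlDispAt")]]
NumericMatrix cppCtrlDispAt(NumericMatrix coords, IntegerVector ctrlDim,
                            NumericVector ctrlSpacing, NumericVector ctrlOrigin,
                            NumericMatrix ctrlDisp) {
    const int cd[3] = {ctrlDim[0], ctrlDim[1], ctrlDim[2]};
    const double csp[3] = {ctrlSpacing[0], ctrlSpacing[1], ctrlSpacing[2]};
    const double corg[3] = {ctrlOrigin[0], ctrlOrigin[1], ctrlOrigin[2]};
    const R_xlen_t n = coords.nrow();
    NumericMatrix out(n, 3);
    R_xlen_t idx64[64];
    double w64[64];
    for (R_xlen_t i = 0; i < n; ++i) {
        double p[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
        ctrlSupport(p, cd, csp, corg, idx64, w64);
        double u[3] = {0, 0, 0};
        for (int k = 0; k < 64; ++k) {
            u[0] += w64[k] * ctrlDisp(idx64[k], 0);
            u[1] += w64[k] * ctrlDisp(idx64[k], 1);
            u[2] += w64[k] * ctrlDisp(idx64[k], 2);
        }
        out(i, 0) = u[0];
        out(i, 1) = u[1];
        out(i, 2) = u[2];
    }
    return out;
}

// 26-connected component of a binary mask containing the seed voxel
// (0-based linear index). Returns a logical vector over the full grid.
// [[Rcpp::export(name = ".cppConnComp26")]]
LogicalVector cppConnComp26(LogicalVector mask, IntegerVector dim, int seed) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
    LogicalVector out(n, false);
    if (seed < 0 || seed >= n || !mask[seed]) return out;
    std::vector<R_xlen_t> stack;
    stack.push_back(seed);
    out[seed] = true;
    while (!stack.empty()) {
        R_xlen_t cur = stack.back();
        stack.pop_back();
        int z = (int)(cur / ((R_xlen_t)d0 * d1));
        int rem = (int)(cur % ((R_xlen_t)d0 * d1));
        int y = rem / d0, x = rem % d0;
        for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                    if (!dx && !dy && !dz) continue;
                    int nx = x + dx, ny = y + dy, nz = z + dz;
                    if (nx < 0 || ny < 0 || nz < 0 || nx >= d0 || ny >= d1 || nz >= d2)
                        continue;
                    R_xlen_t ni = (R_xlen_t)nx + (R_xlen_t)d0 * ny + (R_xlen_t)d0 * d1 * nz;
                    if (mask[ni] && !out[ni]) {
                        out[ni] = true;
                        stack.push_back(ni);
                    }
                }
    }
    return out;
}

// Separable Gaussian smoothing of a 3D volume (sigma per axis, in voxels;
// truncated at 3 sigma, kernel renormalized, edges use reflection).
// [[Rcpp::export(name = ".cppSmoothGaussian")]]
NumericVector cppSmoothGaussian(NumericVector vol, IntegerVector dim,
                                NumericVector sigmaVox) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
    std::vector<double> buf(vol.begin(), vol.end());
    std::vector<double> out(n);
    const R_xlen_t stride[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
    for (int axis = 0; axis < 3; ++axis) {
        double s = sigmaVox[axis];
        if (s <= 0) continue;
        int radius = (int)std::ceil(3.0 * s);
        std::vector<double> k(2 * radius + 1);
        double ksum = 0;
        for (int i = -radius; i <= radius; ++i) {
            k[i + radius] = std::exp(-0.5 * i * i / (s * s));
            ksum += k[i + radius];
        }
        for (double &kv : k) kv /= ksum;
        const int len = d[axis];
        const R_xlen_t st = stride[axis];
        // iterate over all lines along `axis`
        for (R_xlen_t base = 0; base < n; ++base) {
            // base must be the first voxel of a line
            R_xlen_t rem = base;
            int idxAlong = (int)((rem / st) % len);
            if (idxAlong != 0) continue;
            for (int i = 0; i < len; ++i) {
                double acc = 0;
                for (int j = -radius; j <= radius; ++j) {
                    int src = i + j;
                    if (src < 0) src = -src - 1;          // reflect
                    if (src >= len) src = 2 * len - src - 1;
                    if (src < 0) src = 0;
                    if (src >= len) src = len - 1;
                    acc += k[j + radius] * buf[base + (R_xlen_t)src * st];
                }
                out[base + (R_xlen_t)i * st] = acc;
            }
        }
        buf = out;
    }
    return NumericVector(buf.begin(), buf.end());
}
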