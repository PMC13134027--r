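#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform on a 3-D lattice with per-axis spacing,
// by the separable lower-envelope-of-parabolas algorithm. Distances are
// between voxel centers, in the units of `spacing` (mm). Squared distances are
// propagated axis by axis; the result is exact, not an approximation.

static const double INF = 1e30;

// 1-D squared distance transform of sampled function f at positions i*h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h) {
    // envelope boundaries use true infinities so no finite intersection
    // abscissa can ever pop the stack below index 0
    const double NINF = -std::numeric_limits<double>::infinity();
    const double PINF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = NINF;
    z[1] = PINF;
    const double h2 = h * h;
    for (int q = 1; q < n; ++q) {
        double s;
        for (;;) {
            int p = v[k];
            // intersection abscissa of the parabolas rooted at p*h and q*h,
            // in world units (matches the q*h query below)
            s = ((f[q] + q * (double)q * h2) - (f[p] + p * (double)p * h2)) /
                (2.0 * h * (q - p));
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = PINF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q * h) ++k;
        double dq = (q - v[k]) * h;
        d[q] = dq * dq + f[v[k]];
    }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);

    // seed: 0 on mask voxels, +inf elsewhere
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying index)
    for (int kz = 0; kz < nz; ++kz)
        for (int ky = 0; ky < ny; ++ky) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y
    for (int kz = 0; kz < nz; ++kz)
        for (int kx = 0; kx < nx; ++kx) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    const R_xlen_t sz = (R_xlen_t)nx * ny;
    for (int ky = 0; ky < ny; ++ky)
        for (int kx = 0; kx < nx; ++kx) {
            R_xlen_t base = (R_xlen_t)ky * nx + kx;
            for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * sz];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * sz] = d[k];
        }

    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (out[i] >= INF) ? R_PosInf : std::sqrt(out[i]);
    return out;
}
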