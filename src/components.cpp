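#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labelling of a 3-D binary lattice by breadth-first
// search under 6-, 18- or 26-connectivity. Labels are 1..k in discovery
// order (first-voxel column-major order), 0 for background — deterministic.

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector lab(n);

    std::vector<int> ox, oy, oz;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
            }
    const int nb = (int)ox.size();

    int next = 0;
    std::queue<R_xlen_t> q;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        lab[s] = ++next;
        q.push(s);
        while (!q.empty()) {
            R_xlen_t cur = q.front(); q.pop();
            int cx = (int)(cur % nx);
            int cy = (int)((cur / nx) % ny);
            int cz = (int)(cur / ((R_xlen_t)nx * ny));
            for (int t = 0; t < nb; ++t) {
                int x = cx + ox[t], y = cy + oy[t], z = cz + oz[t];
                if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
                    continue;
                R_xlen_t idx = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
                if (mask[idx] && lab[idx] == 0) {
                    lab[idx] = next;
                    q.push(idx);
                }
            }
        }
    }
    return lab;
}
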