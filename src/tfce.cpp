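#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static inline int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

// Threshold-free cluster enhancement of a 3D statistic map.
//
// Only the positive part of the map is enhanced (one-sided contrast).
// Integration uses nsteps midpoint thresholds h_k = (k - 1/2) * dh with
// dh = max(stat)/nsteps; at each threshold the suprathreshold voxels are
// clustered with 6-connectivity (incremental union-find over voxels sorted
// by value) and every member voxel accrues extent^E * h^H * dh.
//
// [[Rcpp::export]]
NumericVector tfce_enhance_cpp(NumericVector stat, IntegerVector dims,
                               double E, double H, int nsteps) {
    const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
    const int n = d1 * d2 * d3;
    if (stat.size() != n) stop("stat length does not match dims");
    NumericVector out(n, 0.0);

    double hmax = 0.0;
    for (int i = 0; i < n; ++i) if (stat[i] > hmax) hmax = stat[i];
    if (hmax <= 0.0 || nsteps < 1) return out;
    const double dh = hmax / nsteps;

    // voxels with positive value, sorted by decreasing value
    std::vector<int> idx;
    idx.reserve(n / 4);
    for (int i = 0; i < n; ++i) if (stat[i] > 0.0) idx.push_back(i);
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return stat[a] > stat[b]; });
    const int npos = (int)idx.size();

    std::vector<int> parent(n, -1);   // -1 = inactive
    std::vector<int> csize(n, 0);

    int ptr = 0;
    for (int k = nsteps; k >= 1; --k) {
        const double h = (k - 0.5) * dh;
        // activate voxels with value >= h
        while (ptr < npos && stat[idx[ptr]] >= h) {
            const int v = idx[ptr];
            parent[v] = v;
            csize[v] = 1;
            const int i = v % d1, j = (v / d1) % d2, kk = v / (d1 * d2);
            const int nb[6] = {
                (i > 0)      ? v - 1       : -1,
                (i < d1 - 1) ? v + 1       : -1,
                (j > 0)      ? v - d1      : -1,
                (j < d2 - 1) ? v + d1      : -1,
                (kk > 0)     ? v - d1 * d2 : -1,
                (kk < d3 - 1)? v + d1 * d2 : -1
            };
            for (int t = 0; t < 6; ++t) {
                const int w = nb[t];
                if (w >= 0 && parent[w] >= 0) {
                    int rv = uf_find(parent, v);
                    int rw = uf_find(parent, w);
                    if (rv != rw) {
                        if (csize[rv] < csize[rw]) std::swap(rv, rw);
                        parent[rw] = rv;
                        csize[rv] += csize[rw];
                    }
                }
            }
            ++ptr;
        }
        // accrue enhancement for all active voxels at this threshold
        const double hterm = std::pow(h, H) * dh;
        for (int t = 0; t < ptr; ++t) {
            const int v = idx[t];
            const int r = uf_find(parent, v);
            out[v] += std::pow((double)csize[r], E) * hterm;
        }
    }
    return out;
}
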