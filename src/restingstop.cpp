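#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <vector>
using namespace Rcpp;

// Average-rank (mid-rank) transform of one time series.
// Returns false if the series is constant (ranking carries no information).
static bool rank_series(const double* x, int n, double* out) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    if (x[idx[0]] == x[idx[n - 1]]) return false;
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
        double r = 0.5 * (i + j) + 1.0;  // average of ranks i+1..j+1
        for (int k = i; k <= j; ++k) out[idx[k]] = r;
        i = j + 1;
    }
    return true;
}

// Regional homogeneity map: Kendall's W of each in-mask voxel with its
// in-mask neighbours (offsets supplied as a k x 3 matrix including (0,0,0)).
// Voxels whose usable neighbourhood has K < 2 members come back NA.
// [[Rcpp::export(name = ".reho_kcc_cpp")]]
List reho_kcc_cpp(NumericVector data, IntegerVector dims,
                  LogicalVector mask, IntegerMatrix offsets) {
    const int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    const int noff = offsets.nrow();

    // per-voxel ranks over time; valid[v] marks non-constant in-mask series
    std::vector<double> ranks((size_t)nvox * nt);
    std::vector<char> valid(nvox, 0);
    std::vector<double> series(nt);
    for (R_xlen_t v = 0; v < nvox; ++v) {
        if (!mask[v]) continue;
        for (int t = 0; t < nt; ++t) series[t] = data[v + nvox * t];
        valid[v] = rank_series(series.data(), nt, &ranks[(size_t)v * nt]) ? 1 : 0;
    }

    NumericVector W(nvox, NA_REAL);
    int n_undefined = 0;
    std::vector<double> S(nt);
    const double n3n = ((double)nt * nt * nt - nt) / 12.0;
    for (R_xlen_t v = 0; v < nvox; ++v) {
        if (!mask[v]) continue;
        const int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
        std::fill(S.begin(), S.end(), 0.0);
        int K = 0;
        for (int o = 0; o < noff; ++o) {
            const int xx = x + offsets(o, 0);
            const int yy = y + offsets(o, 1);
            const int zz = z + offsets(o, 2);
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
            const R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (!mask[u] || !valid[u]) continue;
            const double* r = &ranks[(size_t)u * nt];
            for (int t = 0; t < nt; ++t) S[t] += r[t];
            ++K;
        }
        if (K < 2) { ++n_undefined; continue; }
        const double rbar = K * (nt + 1) / 2.0;
        double ss = 0.0;
        for (int t = 0; t < nt; ++t) ss += S[t] * S[t];
        W[v] = (ss - nt * rbar * rbar) / ((double)K * K * n3n);
    }
    return List::create(_["values"] = W, _["n_undefined"] = n_undefined);
}

// Connected-component labelling of a 3-D binary map under 6/18/26
// connectivity. Labels are dense from 1 in scan order of first encounter.
// [[Rcpp::export(name = ".label_clusters_cpp")]]
List label_clusters_cpp(LogicalVector bin, IntegerVector dims, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    std::vector<std::array<int, 3>> offs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                offs.push_back({dx, dy, dz});
            }
    IntegerVector labels(nvox, 0);
    std::vector<int> sizes;
    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t v0 = 0; v0 < nvox; ++v0) {
        if (!bin[v0] || labels[v0] != 0) continue;
        ++next;
        int sz = 0;
        stack.clear();
        stack.push_back(v0);
        labels[v0] = next;
        while (!stack.empty()) {
            const R_xlen_t v = stack.back();
            stack.pop_back();
            ++sz;
            const int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
            for (const auto& o : offs) {
                const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                const R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (bin[u] && labels[u] == 0) {
                    labels[u] = next;
                    stack.push_back(u);
                }
            }
        }
        sizes.push_back(sz);
    }
    return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}
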