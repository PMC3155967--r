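// Multiscale bootstrap inner loop: resample domain columns, recluster
// (binary distance + UPGMA) and count clade recoveries. Kept in C++ so
// 10 scales x 10^4 replicates complete in seconds.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// xorshift-free deterministic generator: splitmix64. Identical streams on
// every platform for a given seed (std::mt19937's distributions are
// implementation-defined, so it is not used).
static inline uint64_t splitmix64(uint64_t &state) {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

// UPGMA over a dense n x n distance matrix (row-major). Appends the leaf
// bitmask of every internal node to `clades`. Ties break to the
// lowest-index pair (strict < while scanning i < j in ascending order).
static void upgmaClades(std::vector<double> &dist, int n,
                        std::vector<uint64_t> &clades,
                        std::vector<double> *heights = nullptr) {
    std::vector<int> size(n, 1);
    std::vector<uint64_t> mask(n);
    std::vector<char> active(n, 1);
    for (int i = 0; i < n; ++i) mask[i] = 1ULL << i;
    for (int step = 0; step < n - 1; ++step) {
        double best = R_PosInf;
        int bi = -1, bj = -1;
        for (int i = 0; i < n; ++i) {
            if (!active[i]) continue;
            for (int j = i + 1; j < n; ++j) {
                if (!active[j]) continue;
                double v = dist[(size_t)i * n + j];
                if (v < best) { best = v; bi = i; bj = j; }
            }
        }
        for (int k = 0; k < n; ++k) {
            if (!active[k] || k == bi || k == bj) continue;
            double v = (dist[(size_t)bi * n + k] * size[bi] +
                        dist[(size_t)bj * n + k] * size[bj]) /
                       (size[bi] + size[bj]);
            dist[(size_t)bi * n + k] = dist[(size_t)k * n + bi] = v;
        }
        size[bi] += size[bj];
        active[bj] = 0;
        mask[bi] |= mask[bj];
        clades.push_back(mask[bi]);
        if (heights) heights->push_back(best);
    }
}

// Binary (asymmetric Jaccard) distances between the rows of X restricted
// to the sampled columns `cols`. Two rows empty on the resample get
// distance 0 (identical emptiness; full-data rows are never all-zero).
static void binaryDistOnColumns(const IntegerMatrix &X,
                                const std::vector<int> &cols,
                                std::vector<double> &dist, int n) {
    int m = (int)cols.size();
    std::vector<uint64_t> rows(n, 0);  // m <= 64 bits per row
    for (int i = 0; i < n; ++i) {
        uint64_t b = 0;
        for (int k = 0; k < m; ++k)
            if (X(i, cols[k])) b |= (1ULL << k);
        rows[i] = b;
    }
    for (int i = 0; i < n; ++i) {
        dist[(size_t)i * n + i] = 0.0;
        for (int j = i + 1; j < n; ++j) {
            uint64_t u = rows[i] | rows[j];
            double d = 0.0;
            if (u) {
                uint64_t x = rows[i] ^ rows[j];
#if defined(__GNUC__) || defined(__clang__)
                d = (double)__builtin_popcountll(x) /
                    (double)__builtin_popcountll(u);
#else
                int cx = 0, cu = 0;
                for (uint64_t t = x; t; t &= t - 1) ++cx;
                for (uint64_t t = u; t; t &= t - 1) ++cu;
                d = (double)cx / (double)cu;
#endif
            }
            dist[(size_t)i * n + j] = dist[(size_t)j * n + i] = d;
        }
    }
}

// [[Rcpp::export]]
IntegerMatrix cpp_multiscale_counts(IntegerMatrix X, List clades,
                                    NumericVector scales, int n_boot,
                                    int seed) {
    int n = X.nrow(), p = X.ncol(), ns = scales.size();
    if (n > 64) stop("at most 64 rows are supported");
    int nc = clades.size();
    std::unordered_map<uint64_t, int> lookup;
    for (int k = 0; k < nc; ++k) {
        IntegerVector mem = clades[k];
        uint64_t msk = 0;
        for (int i = 0; i < mem.size(); ++i) msk |= 1ULL << (mem[i] - 1);
        lookup[msk] = k;
    }
    IntegerMatrix counts(nc, ns);
    uint64_t state = 0x9E3779B97F4A7C15ULL ^ (uint64_t)(uint32_t)seed;
    std::vector<double> dist((size_t)n * n);
    std::vector<uint64_t> found;
    std::vector<int> cols;
    for (int s = 0; s < ns; ++s) {
        int m = (int)std::lround(scales[s] * p);
        if (m < 2) stop("resample size below 2");
        if (m > 64) stop("resample size above 64 columns");
        for (int b = 0; b < n_boot; ++b) {
            cols.resize(m);
            for (int k = 0; k < m; ++k)
                cols[k] = (int)(splitmix64(state) % (uint64_t)p);
            binaryDistOnColumns(X, cols, dist, n);
            found.clear();
            upgmaClades(dist, n, found);
            for (uint64_t msk : found) {
                auto it = lookup.find(msk);
                if (it != lookup.end()) counts(it->second, s)++;
            }
        }
    }
    return counts;
}

// UPGMA on an arbitrary distance matrix; exposed for cross-checking the
// C++ agglomeration against stats::hclust.
// [[Rcpp::export]]
List cpp_upgma(NumericMatrix d) {
    int n = d.nrow();
    if (n != d.ncol()) stop("square matrix required");
    std::vector<double> dist((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) dist[(size_t)i * n + j] = d(i, j);
    std::vector<uint64_t> clades;
    std::vector<double> heights;
    upgmaClades(dist, n, clades, &heights);
    List out(clades.size());
    for (size_t k = 0; k < clades.size(); ++k) {
        std::vector<int> mem;
        for (int i = 0; i < n; ++i)
            if (clades[k] & (1ULL << i)) mem.push_back(i + 1);
        out[k] = wrap(mem);
    }
    return List::create(_["clades"] = out, _["heights"] = wrap(heights));
}
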