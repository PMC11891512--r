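#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Greedy optimization of a (supra-)modularity matrix B by the classic
// two-phase Louvain procedure: local moves of state nodes between
// communities while the quality gain exceeds a tolerance, followed by
// aggregation of communities into super-nodes; the two-phase cycle repeats
// until a full cycle yields no move. Because B already incorporates the
// null model and interlayer couplings, the gain of moving node v from
// community c to d is simply sum_B(v, d) - sum_B(v, c \ v); no degree
// bookkeeping is needed.
//
// Determinism: node visiting order is shuffled with an explicit
// Fisher-Yates driven by a 64-bit SplitMix/mt19937-free generator so the
// same seed gives the same partition on every platform.

namespace {

struct Rng {
    uint64_t state;
    explicit Rng(uint64_t seed) : state(seed + 0x9E3779B97F4A7C15ULL) {}
    // SplitMix64: standardized output sequence, platform independent
    uint64_t next() {
        uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    int bounded(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Graph {
    int n;
    std::vector<int> ptr;      // CSC/CSR pointers (symmetric, so identical)
    std::vector<int> idx;      // neighbour indices, self excluded
    std::vector<double> w;     // edge weights (off-diagonal B entries)
    std::vector<double> selfw; // diagonal B entries (counted once in Q)
};

void shuffle_order(std::vector<int>& order, Rng& rng) {
    for (int i = static_cast<int>(order.size()) - 1; i > 0; --i) {
        int j = rng.bounded(i + 1);
        std::swap(order[i], order[j]);
    }
}

// One full local-move phase; returns the number of accepted moves.
long local_moves(const Graph& g, std::vector<int>& comm, double gain_tol,
                 Rng& rng, long& sweeps) {
    std::vector<double> wt(g.n, 0.0);
    std::vector<int> touched;
    touched.reserve(64);
    std::vector<int> order(g.n);
    for (int i = 0; i < g.n; ++i) order[i] = i;

    long total_moves = 0;
    bool improved = true;
    while (improved) {
        improved = false;
        ++sweeps;
        shuffle_order(order, rng);
        for (int oi = 0; oi < g.n; ++oi) {
            int v = order[oi];
            touched.clear();
            for (int e = g.ptr[v]; e < g.ptr[v + 1]; ++e) {
                int u = g.idx[e];
                int cu = comm[u];
                if (wt[cu] == 0.0) touched.push_back(cu);
                wt[cu] += g.w[e];
            }
            int cur = comm[v];
            double base = wt[cur]; // cur may be untouched: base 0 then
            int best = cur;
            double best_gain = gain_tol; // moves with gain <= tol rejected
            for (size_t k = 0; k < touched.size(); ++k) {
                int c = touched[k];
                if (c == cur) continue;
                double gain = wt[c] - base;
                if (gain > best_gain) { // strict: first encountered wins ties
                    best_gain = gain;
                    best = c;
                }
            }
            for (size_t k = 0; k < touched.size(); ++k) wt[touched[k]] = 0.0;
            if (best != cur) {
                comm[v] = best;
                improved = true;
                ++total_moves;
            }
        }
    }
    return total_moves;
}

// Collapse communities into super-nodes; comm is relabelled 0..k-1 in place.
Graph aggregate(const Graph& g, std::vector<int>& comm) {
    int n = g.n;
    std::vector<int> relabel(n, -1);
    int k = 0;
    for (int v = 0; v < n; ++v) {
        int c = comm[v];
        if (relabel[c] < 0) relabel[c] = k++;
    }
    for (int v = 0; v < n; ++v) comm[v] = relabel[comm[v]];

    // accumulate edges between communities; internal weight -> self
    std::vector<std::vector<std::pair<int, double> > > rows(k);
    std::vector<double> selfw(k, 0.0);
    std::vector<double> acc(k, 0.0);
    std::vector<int> touched;
    for (int v = 0; v < n; ++v) selfw[comm[v]] += g.selfw[v];
    // scatter per source community
    std::vector<std::vector<int> > members(k);
    for (int v = 0; v < n; ++v) members[comm[v]].push_back(v);
    for (int c = 0; c < k; ++c) {
        touched.clear();
        for (size_t m = 0; m < members[c].size(); ++m) {
            int v = members[c][m];
            for (int e = g.ptr[v]; e < g.ptr[v + 1]; ++e) {
                int d = comm[g.idx[e]];
                if (acc[d] == 0.0) touched.push_back(d);
                acc[d] += g.w[e];
            }
        }
        for (size_t t = 0; t < touched.size(); ++t) {
            int d = touched[t];
            if (d == c) {
                // both directions of internal pairs summed; Q counts both,
                // fold the full amount into the self weight
                selfw[c] += acc[d];
            } else {
                rows[c].push_back(std::make_pair(d, acc[d]));
            }
            acc[d] = 0.0;
        }
    }

    Graph out;
    out.n = k;
    out.selfw = selfw;
    out.ptr.assign(k + 1, 0);
    for (int c = 0; c < k; ++c) out.ptr[c + 1] = out.ptr[c] + static_cast<int>(rows[c].size());
    out.idx.resize(out.ptr[k]);
    out.w.resize(out.ptr[k]);
    for (int c = 0; c < k; ++c) {
        int off = out.ptr[c];
        for (size_t m = 0; m < rows[c].size(); ++m) {
            out.idx[off + static_cast<int>(m)] = rows[c][m].first;
            out.w[off + static_cast<int>(m)] = rows[c][m].second;
        }
    }
    return out;
}

double partition_weight(const Graph& g, const std::vector<int>& comm) {
    double q = 0.0;
    for (int v = 0; v < g.n; ++v) {
        q += g.selfw[v];
        for (int e = g.ptr[v]; e < g.ptr[v + 1]; ++e) {
            if (comm[g.idx[e]] == comm[v]) q += g.w[e];
        }
    }
    return q;
}

} // namespace

// [[Rcpp::export]]
List louvain_supra_cpp(IntegerVector Bi, IntegerVector Bp, NumericVector Bx,
                       int n, double twomu, int seed, double tol) {
    // unpack dgCMatrix slots (symmetric storage assumed) into a graph with
    // the diagonal separated out
    Graph g;
    g.n = n;
    g.selfw.assign(n, 0.0);
    g.ptr.assign(n + 1, 0);
    R_xlen_t nnz = Bx.size();
    std::vector<int> col(nnz);
    {
        for (int j = 0; j < n; ++j)
            for (int e = Bp[j]; e < Bp[j + 1]; ++e) col[e] = j;
        // count off-diagonal entries per column
        for (R_xlen_t e = 0; e < nnz; ++e) {
            if (Bi[e] == col[e]) g.selfw[col[e]] += Bx[e];
            else g.ptr[col[e] + 1]++;
        }
        for (int j = 0; j < n; ++j) g.ptr[j + 1] += g.ptr[j];
        g.idx.resize(g.ptr[n]);
        g.w.resize(g.ptr[n]);
        std::vector<int> fill(n, 0);
        for (R_xlen_t e = 0; e < nnz; ++e) {
            if (Bi[e] == col[e]) continue;
            int j = col[e];
            int off = g.ptr[j] + fill[j]++;
            g.idx[off] = Bi[e];
            g.w[off] = Bx[e];
        }
    }

    Rng rng(static_cast<uint64_t>(static_cast<int64_t>(seed)));
    // tolerance is stated on the Q scale; a move's raw-weight gain counts
    // twice in the symmetric double sum, hence the factor 1/2
    double gain_tol = tol * twomu / 2.0;

    std::vector<int> assign_orig(n);
    for (int v = 0; v < n; ++v) assign_orig[v] = v;

    Graph cur = g;
    std::vector<int> comm(cur.n);
    for (int v = 0; v < cur.n; ++v) comm[v] = v;
    long sweeps = 0;
    while (true) {
        long moves = local_moves(cur, comm, gain_tol, rng, sweeps);
        if (moves == 0) break;
        Graph agg = aggregate(cur, comm);
        for (int v = 0; v < n; ++v) assign_orig[v] = comm[assign_orig[v]];
        if (agg.n == cur.n) break; // no shrinkage possible
        cur = agg;
        comm.assign(cur.n, 0);
        for (int v = 0; v < cur.n; ++v) comm[v] = v;
    }

    double q = partition_weight(g, assign_orig) / twomu;

    IntegerVector labels(n);
    for (int v = 0; v < n; ++v) labels[v] = assign_orig[v] + 1;
    return List::create(_["labels"] = labels,
                        _["Q"] = q,
                        _["n_sweeps"] = static_cast<int>(sweeps));
}
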