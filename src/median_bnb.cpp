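// Exact DCJ median of three circular genomes by branch-and-bound over
// perfect matchings on the 2n gene extremities.
//
// Total distance of a candidate median M is 3n - sum_X c(X, M), so the
// search maximises the total number of alternating cycles. Black (median)
// edges are added one at a time; for each of the three colours the
// alternating (colour, black) paths are maintained by an endpoint map:
// adding a black edge either closes a cycle (+1) or splices two paths.
// Pruning uses the residual form of the triangle-score lower bound: with m
// genes still unfixed, the cycles still obtainable are at most
// floor((3m + c'_AB + c'_AC + c'_BC) / 2), where c' counts alternating
// cycles between the contracted colour matchings on the unmatched vertices.

#include <Rcpp.h>
#include <vector>

namespace {

class MedianSearch {
public:
    MedianSearch(int n, const std::vector<int>& ma, const std::vector<int>& mb,
                 const std::vector<int>& mc)
        : n_(n), N_(2 * n), nodes_(0.0) {
        colour_[0] = ma; colour_[1] = mb; colour_[2] = mc;
        for (int c = 0; c < 3; ++c) endp_[c] = colour_[c];
        matched_.assign(N_, 0);
        mateM_.assign(N_, -1);
        stamp_.assign(N_, -1);
        stampVal_ = 0;
        cycles_ = 0;
        best_ = -1;
    }

    // evaluate a full matching as candidate median (incumbent seeding)
    void seedCandidate(const std::vector<int>& m) {
        int tot = 0;
        for (int c = 0; c < 3; ++c) tot += cycleCount(colour_[c], m);
        if (tot > best_) { best_ = tot; bestMate_ = m; }
    }

    void run() { dfs(); }

    int bestCycles() const { return best_; }
    const std::vector<int>& bestMate() const { return bestMate_; }
    double nodes() const { return nodes_; }

private:
    int n_, N_;
    std::vector<int> colour_[3];  // input matchings, 0-based
    std::vector<int> endp_[3];    // path endpoint maps on unmatched vertices
    std::vector<char> matched_;
    std::vector<int> mateM_, bestMate_;
    std::vector<int> stamp_;
    int stampVal_, cycles_, best_;
    double nodes_;

    static int cycleCount(const std::vector<int>& m1,
                          const std::vector<int>& m2) {
        int N = (int)m1.size(), k = 0;
        std::vector<char> vis(N, 0);
        for (int s = 0; s < N; ++s) {
            if (vis[s]) continue;
            ++k;
            int v = s;
            do { vis[v] = 1; int w = m1[v]; vis[w] = 1; v = m2[w]; }
            while (v != s);
        }
        return k;
    }

    // alternating cycles between endp_[x] and endp_[y] restricted to the
    // unmatched vertices (both maps are perfect matchings there)
    int residualPairCycles(int x, int y) {
        ++stampVal_;
        int k = 0;
        for (int s = 0; s < N_; ++s) {
            if (matched_[s] || stamp_[s] == stampVal_) continue;
            ++k;
            int v = s;
            do {
                stamp_[v] = stampVal_;
                int w = endp_[x][v];
                stamp_[w] = stampVal_;
                v = endp_[y][w];
            } while (v != s);
        }
        return k;
    }

    // upper bound on the total cycles achievable from the current state
    int bound(int m) {
        int cres = residualPairCycles(0, 1) + residualPairCycles(0, 2) +
                   residualPairCycles(1, 2);
        return cycles_ + (3 * m + cres) / 2;
    }

    void dfs() {
        ++nodes_;
        int u = -1;
        for (int v = 0; v < N_; ++v)
            if (!matched_[v]) { u = v; break; }
        if (u < 0) {  // complete matching
            if (cycles_ > best_) { best_ = cycles_; bestMate_ = mateM_; }
            return;
        }
        int m = 0;
        for (int v = 0; v < N_; ++v) if (!matched_[v]) ++m;
        m /= 2;
        for (int v = u + 1; v < N_; ++v) {
            if (matched_[v]) continue;
            // place black edge (u, v)
            int undo[3][2];
            int closedMask = 0, gained = 0;
            for (int c = 0; c < 3; ++c) {
                if (endp_[c][u] == v) {
                    closedMask |= (1 << c);
                    ++gained;
                } else {
                    int a = endp_[c][u], b = endp_[c][v];
                    undo[c][0] = a; undo[c][1] = b;
                    endp_[c][a] = b; endp_[c][b] = a;
                }
            }
            cycles_ += gained;
            matched_[u] = matched_[v] = 1;
            mateM_[u] = v; mateM_[v] = u;
            if (bound(m - 1) > best_) dfs();
            // undo
            matched_[u] = matched_[v] = 0;
            mateM_[u] = mateM_[v] = -1;
            cycles_ -= gained;
            for (int c = 0; c < 3; ++c) {
                if (!(closedMask & (1 << c))) {
                    endp_[c][undo[c][0]] = u;
                    endp_[c][undo[c][1]] = v;
                }
            }
        }
    }
};

std::vector<int> toZeroBased(const Rcpp::IntegerVector& m) {
    std::vector<int> out(m.size());
    for (int i = 0; i < m.size(); ++i) out[i] = m[i] - 1;
    return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List median_bnb_cpp(int n, Rcpp::IntegerVector mateA,
                          Rcpp::IntegerVector mateB,
                          Rcpp::IntegerVector mateC) {
    std::vector<int> ma = toZeroBased(mateA), mb = toZeroBased(mateB),
                     mc = toZeroBased(mateC);
    MedianSearch s(n, ma, mb, mc);
    // incumbent: the given genomes themselves (min-pairwise-sum bound),
    // tried in order A, B, C so ties resolve deterministically
    s.seedCandidate(ma);
    s.seedCandidate(mb);
    s.seedCandidate(mc);
    s.run();
    Rcpp::IntegerVector mate(2 * n);
    const std::vector<int>& bm = s.bestMate();
    for (int i = 0; i < 2 * n; ++i) mate[i] = bm[i] + 1;
    return Rcpp::List::create(
        Rcpp::Named("score") = 3 * n - s.bestCycles(),
        Rcpp::Named("mate") = mate,
        Rcpp::Named("nodes") = s.nodes());
}
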