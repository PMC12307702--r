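#include <Rcpp.h>
#include <vector>
#include <limits>

// Dense square linear assignment by shortest augmenting paths with dual
// potentials (Jonker-Volgenant style), O(n^3). Deterministic: rows are
// inserted in order and column scans run left to right, so exact ties are
// resolved the same way on every platform.
//
// Returns, for each row (1-based), the assigned column.
// [[Rcpp::export]]
Rcpp::IntegerVector lap_solve(Rcpp::NumericMatrix cost) {
    const int n = cost.nrow();
    if (cost.ncol() != n)
        Rcpp::stop("lap_solve: cost matrix must be square");
    if (n == 0) return Rcpp::IntegerVector(0);

    const double INF = std::numeric_limits<double>::infinity();
    // 1-based arrays; column 0 is a virtual column.
    std::vector<double> pu(n + 1, 0.0), pv(n + 1, 0.0);
    std::vector<int> match(n + 1, 0);   // match[j] = row matched to column j
    std::vector<int> way(n + 1, 0);

    for (int i = 1; i <= n; ++i) {
        match[0] = i;
        int j0 = 0;
        std::vector<double> minv(n + 1, INF);
        std::vector<char> used(n + 1, 0);
        do {
            used[j0] = 1;
            const int i0 = match[j0];
            double delta = INF;
            int j1 = -1;
            for (int j = 1; j <= n; ++j) {
                if (used[j]) continue;
                const double cur = cost(i0 - 1, j - 1) - pu[i0] - pv[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            for (int j = 0; j <= n; ++j) {
                if (used[j]) { pu[match[j]] += delta; pv[j] -= delta; }
                else          { minv[j] -= delta; }
            }
            j0 = j1;
        } while (match[j0] != 0);
        do {
            const int j1 = way[j0];
            match[j0] = match[j1];
            j0 = j1;
        } while (j0);
    }

    Rcpp::IntegerVector rowsol(n);
    for (int j = 1; j <= n; ++j) rowsol[match[j] - 1] = j;
    return rowsol;
}
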