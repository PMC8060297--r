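#include <Rcpp.h>
#include <vector>
#include <limits>
#include <queue>
using namespace Rcpp;

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// f: sampled cost, out: lower envelope of parabolas rooted at (i, f[i]).
static void dt1d(const std::vector<double>& f, std::vector<double>& out) {
    const int n = (int)f.size();
    const double INF = std::numeric_limits<double>::infinity();
    // restrict the envelope to parabolas with finite height
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = -1;
    for (int q = 0; q < n; ++q) {
        if (f[q] == INF) continue;
        if (k < 0) {
            k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
            continue;
        }
        double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                   (2.0 * q - 2.0 * v[k]);
        while (k > 0 && s <= z[k]) {
            --k;
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
        }
        if (k == 0 && s <= z[0]) {
            v[0] = q; z[0] = -INF; z[1] = INF;
        } else {
            ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
        }
    }
    if (k < 0) { // no finite source anywhere
        for (int q = 0; q < n; ++q) out[q] = INF;
        return;
    }
    int j = 0;
    for (int q = 0; q < n; ++q) {
        while (z[j + 1] < q) ++j;
        double d = (double)q - v[j];
        out[q] = d * d + f[v[j]];
    }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericMatrix cpp_edt_sq(LogicalMatrix fg) {
    // squared Euclidean distance from each pixel to the nearest TRUE pixel
    const int nr = fg.nrow(), nc = fg.ncol();
    const double INF = std::numeric_limits<double>::infinity();
    NumericMatrix d(nr, nc);
    std::vector<double> f(std::max(nr, nc)), o(std::max(nr, nc));
    for (int j = 0; j < nc; ++j) {          // columns first
        for (int i = 0; i < nr; ++i) f[i] = fg(i, j) ? 0.0 : INF;
        f.resize(nr); o.resize(nr);
        dt1d(f, o);
        for (int i = 0; i < nr; ++i) d(i, j) = o[i];
        f.resize(std::max(nr, nc)); o.resize(std::max(nr, nc));
    }
    for (int i = 0; i < nr; ++i) {          // then rows
        for (int j = 0; j < nc; ++j) f[j] = d(i, j);
        f.resize(nc); o.resize(nc);
        dt1d(f, o);
        for (int j = 0; j < nc; ++j) d(i, j) = o[j];
        f.resize(std::max(nr, nc)); o.resize(std::max(nr, nc));
    }
    return d;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_largest_component")]]
LogicalMatrix cpp_largest_component(LogicalMatrix fg) {
    // keep only the largest 4-connected TRUE component
    const int nr = fg.nrow(), nc = fg.ncol();
    IntegerMatrix label(nr, nc);
    int next_label = 0, best_label = 0;
    long best_size = 0;
    const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
    std::queue<std::pair<int, int> > q;
    for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
        if (!fg(i, j) || label(i, j)) continue;
        ++next_label;
        long size = 0;
        label(i, j) = next_label;
        q.push({i, j});
        while (!q.empty()) {
            std::pair<int, int> p = q.front(); q.pop();
            ++size;
            for (int k = 0; k < 4; ++k) {
                int ni = p.first + di[k], nj = p.second + dj[k];
                if (ni >= 0 && ni < nr && nj >= 0 && nj < nc &&
                    fg(ni, nj) && !label(ni, nj)) {
                    label(ni, nj) = next_label;
                    q.push({ni, nj});
                }
            }
        }
        if (size > best_size) { best_size = size; best_label = next_label; }
    }
    LogicalMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
        out(i, j) = label(i, j) == best_label && best_label > 0;
    }
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_border_reachable")]]
LogicalMatrix cpp_border_reachable(LogicalMatrix open) {
    // 4-connected flood fill of `open` pixels starting from the image border;
    // used to find enclosed holes (open but unreachable).
    const int nr = open.nrow(), nc = open.ncol();
    LogicalMatrix vis(nr, nc);
    std::queue<std::pair<int, int> > q;
    for (int i = 0; i < nr; ++i) {
        if (open(i, 0) && !vis(i, 0)) { vis(i, 0) = true; q.push({i, 0}); }
        if (open(i, nc - 1) && !vis(i, nc - 1)) { vis(i, nc - 1) = true; q.push({i, nc - 1}); }
    }
    for (int j = 0; j < nc; ++j) {
        if (open(0, j) && !vis(0, j)) { vis(0, j) = true; q.push({0, j}); }
        if (open(nr - 1, j) && !vis(nr - 1, j)) { vis(nr - 1, j) = true; q.push({nr - 1, j}); }
    }
    const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
    while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < 4; ++k) {
            int ni = p.first + di[k], nj = p.second + dj[k];
            if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && open(ni, nj) && !vis(ni, nj)) {
                vis(ni, nj) = true;
                q.push({ni, nj});
            }
        }
    }
    return vis;
}
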