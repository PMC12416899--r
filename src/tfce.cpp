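#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling on a 3-D grid (6- or 26-connectivity) and the
// threshold-free cluster enhancement transform built on it.

static void neighbor_offsets(const int dim[3], int connectivity,
                             std::vector<int>& di, std::vector<int>& dj, std::vector<int>& dk) {
    di.clear(); dj.clear(); dk.clear();
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                if (a == 0 && b == 0 && c == 0) continue;
                int manh = std::abs(a) + std::abs(b) + std::abs(c);
                if (connectivity == 6 && manh != 1) continue;
                di.push_back(a); dj.push_back(b); dk.push_back(c);
            }
}

// labels voxels where fg != 0; background label 0, clusters 1..n_clusters
static int label_components(const std::vector<char>& fg, const int dim[3],
                            int connectivity, std::vector<int>& labels) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    size_t V = (size_t)nx * ny * nz;
    labels.assign(V, 0);
    std::vector<int> di, dj, dk;
    neighbor_offsets(dim, connectivity, di, dj, dk);
    int nlab = 0;
    std::vector<size_t> stack;
    for (size_t s = 0; s < V; ++s) {
        if (!fg[s] || labels[s]) continue;
        ++nlab;
        labels[s] = nlab;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            size_t v = stack.back(); stack.pop_back();
            int k = (int)(v / ((size_t)nx * ny));
            int rem = (int)(v % ((size_t)nx * ny));
            int j = rem / nx, i = rem % nx;
            for (size_t t = 0; t < di.size(); ++t) {
                int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
                size_t u = (size_t)ii + (size_t)jj * nx + (size_t)kk * nx * ny;
                if (fg[u] && !labels[u]) { labels[u] = nlab; stack.push_back(u); }
            }
        }
    }
    return nlab;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector vol, IntegerVector dim, int connectivity) {
    if (dim.size() != 3) stop("dim must have length 3");
    int d[3] = { dim[0], dim[1], dim[2] };
    size_t V = (size_t)d[0] * d[1] * d[2];
    if ((size_t)vol.size() != V) stop("volume size does not match dim");
    std::vector<char> fg(V);
    for (size_t s = 0; s < V; ++s) fg[s] = (vol[s] == TRUE) ? 1 : 0;
    std::vector<int> labels;
    label_components(fg, d, connectivity, labels);
    IntegerVector out(V);
    for (size_t s = 0; s < V; ++s) out[s] = labels[s];
    out.attr("dim") = dim;
    return out;
}

// TFCE of the positive part of stat: for each threshold h = dh, 2dh, ... up
// to max(stat), every suprathreshold voxel accumulates e^E * h^H * dh where e
// is the size of its connected component at height h.
// [[Rcpp::export(name = ".tfce_pos_cpp")]]
NumericVector tfce_pos_cpp(NumericVector stat, IntegerVector dim,
                           double E, double H, double dh, int connectivity) {
    if (dim.size() != 3) stop("dim must have length 3");
    int d[3] = { dim[0], dim[1], dim[2] };
    size_t V = (size_t)d[0] * d[1] * d[2];
    if ((size_t)stat.size() != V) stop("volume size does not match dim");
    NumericVector out(V);
    double mx = 0.0;
    for (size_t s = 0; s < V; ++s) if (stat[s] > mx) mx = stat[s];
    if (mx <= 0.0 || dh <= 0.0) { out.attr("dim") = dim; return out; }
    std::vector<char> fg(V);
    std::vector<int> labels;
    for (double h = dh; h <= mx + 1e-12; h += dh) {
        for (size_t s = 0; s < V; ++s) fg[s] = (stat[s] >= h) ? 1 : 0;
        int nlab = label_components(fg, d, connectivity, labels);
        if (nlab == 0) break;
        std::vector<double> csize(nlab + 1, 0.0);
        for (size_t s = 0; s < V; ++s) if (labels[s]) csize[labels[s]] += 1.0;
        std::vector<double> add(nlab + 1, 0.0);
        double hh = std::pow(h, H) * dh;
        for (int l = 1; l <= nlab; ++l) add[l] = std::pow(csize[l], E) * hh;
        for (size_t s = 0; s < V; ++s) if (labels[s]) out[s] += add[labels[s]];
    }
    out.attr("dim") = dim;
    return out;
}
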