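#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear C-SVC solved by SMO on the dual (maximal-violating-pair working set,
// LIBSVM formulation: unregularized bias, box constraint [0, C]).
// Problems here are tiny (tens of samples), so the full kernel matrix is
// precomputed densely.

struct SvcModel {
    std::vector<double> w;  // primal weights (linear kernel)
    double rho;             // decision f(x) = w.x - rho
    int iter;
};

static SvcModel smo_linear(const double* X, int n, int p,
                           const std::vector<int>& y,  // +1 / -1
                           double C, double eps) {
    std::vector<double> K((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = i; j < n; ++j) {
            double s = 0.0;
            for (int k = 0; k < p; ++k) s += X[i + (size_t)k * n] * X[j + (size_t)k * n];
            K[i + (size_t)j * n] = s;
            K[j + (size_t)i * n] = s;
        }

    std::vector<double> alpha(n, 0.0), G(n, -1.0);
    int max_iter = 10000 > 100 * n ? 10000 : 100 * n;
    int iter = 0;

    for (; iter < max_iter; ++iter) {
        // second-order working-set selection: i is the maximal violator in
        // the "up" set; j maximizes the quadratic gain b^2 / a with
        // b = gmax - (-y_j G_j) and a = K_ii + K_jj - 2 K_ij (the curvature
        // along the feasible direction, label-independent for the linear
        // kernel)
        int i = -1, j = -1;
        double gmax = -HUGE_VAL, gmin = HUGE_VAL;
        for (int t = 0; t < n; ++t) {
            bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
            double v = -y[t] * G[t];
            if (up && v > gmax) { gmax = v; i = t; }
        }
        double best = -HUGE_VAL;
        for (int t = 0; t < n; ++t) {
            bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
            if (!low) continue;
            double v = -y[t] * G[t];
            if (v < gmin) gmin = v;
            double b = gmax - v;
            if (i >= 0 && b > 0) {
                double a = K[i + (size_t)i * n] + K[t + (size_t)t * n]
                    - 2.0 * K[i + (size_t)t * n];
                if (a <= 0) a = 1e-12;
                double gain = b * b / a;
                if (gain > best) { best = gain; j = t; }
            }
        }
        if (i < 0 || j < 0 || gmax - gmin < eps) break;

        double ai_old = alpha[i], aj_old = alpha[j];
        // curvature along the feasible direction is |x_i - x_j|^2 for the
        // linear kernel in both label configurations
        if (y[i] != y[j]) {
            double quad = K[i + (size_t)i * n] + K[j + (size_t)j * n] - 2.0 * K[i + (size_t)j * n];
            if (quad <= 0) quad = 1e-12;
            double delta = (-G[i] - G[j]) / quad;
            double diff = alpha[i] - alpha[j];
            alpha[i] += delta; alpha[j] += delta;
            if (diff > 0) {
                if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
            } else {
                if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
            }
            if (diff > 0) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
            } else {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
            }
        } else {
            double quad = K[i + (size_t)i * n] + K[j + (size_t)j * n] - 2.0 * K[i + (size_t)j * n];
            if (quad <= 0) quad = 1e-12;
            double delta = (G[i] - G[j]) / quad;
            double sum = alpha[i] + alpha[j];
            alpha[i] -= delta; alpha[j] += delta;
            if (sum > C) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
            } else {
                if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
            }
            if (sum > C) {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
            } else {
                if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
            }
        }

        double di = y[i] * (alpha[i] - ai_old), dj = y[j] * (alpha[j] - aj_old);
        for (int t = 0; t < n; ++t)
            G[t] += y[t] * (K[t + (size_t)i * n] * di + K[t + (size_t)j * n] * dj);
    }

    // rho: average -y*G over free support vectors, else interval midpoint
    double sum_free = 0.0; int n_free = 0;
    double ub = HUGE_VAL, lb = -HUGE_VAL;
    for (int t = 0; t < n; ++t) {
        double yg = y[t] * G[t];
        if (alpha[t] > 0 && alpha[t] < C) { sum_free += yg; ++n_free; }
        else if ((y[t] == 1 && alpha[t] >= C) || (y[t] == -1 && alpha[t] <= 0)) {
            if (yg > lb) lb = yg;
        } else {
            if (yg < ub) ub = yg;
        }
    }
    SvcModel m;
    m.rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;
    m.iter = iter;
    m.w.assign(p, 0.0);
    for (int t = 0; t < n; ++t) {
        if (alpha[t] != 0.0) {
            double c = alpha[t] * y[t];
            for (int k = 0; k < p; ++k) m.w[k] += c * X[t + (size_t)k * n];
        }
    }
    return m;
}

// [[Rcpp::export(name = ".svc_train_cpp")]]
List svc_train_cpp(NumericMatrix X, IntegerVector y, double cost, double eps) {
    int n = X.nrow(), p = X.ncol();
    std::vector<int> yy(n);
    for (int i = 0; i < n; ++i) {
        if (y[i] != 1 && y[i] != -1) stop("labels must be +1/-1");
        yy[i] = y[i];
    }
    SvcModel m = smo_linear(REAL(X), n, p, yy, cost, eps);
    return List::create(_["w"] = NumericVector(m.w.begin(), m.w.end()),
                        _["rho"] = m.rho, _["iter"] = m.iter);
}

// Mean and per-pair accuracy of the six pairwise classifiers.
// Labels in 1..K. Ties on the boundary (score == 0) go to the smaller
// condition id. Pair order: (1,2),(1,3),...,(K-1,K).
static void pairwise_acc(const double* Xtr, int ntr, int p,
                         const int* ytr,
                         const double* Xte, int nte,
                         const int* yte,
                         int K, double C, double eps,
                         double* pair_acc /* K*(K-1)/2 */) {
    std::vector<double> Xp;  // pair submatrix, column-major
    std::vector<int> yp;
    int pr = 0;
    for (int a = 1; a <= K; ++a) {
        for (int b = a + 1; b <= K; ++b, ++pr) {
            // gather training samples of conditions a, b
            int na = 0;
            for (int i = 0; i < ntr; ++i) if (ytr[i] == a || ytr[i] == b) ++na;
            Xp.assign((size_t)na * p, 0.0);
            yp.assign(na, 0);
            int r = 0;
            for (int i = 0; i < ntr; ++i) {
                if (ytr[i] == a || ytr[i] == b) {
                    yp[r] = (ytr[i] == a) ? 1 : -1;
                    for (int k = 0; k < p; ++k) Xp[r + (size_t)k * na] = Xtr[i + (size_t)k * ntr];
                    ++r;
                }
            }
            SvcModel m = smo_linear(Xp.data(), na, p, yp, C, eps);
            int ncorrect = 0, ntot = 0;
            for (int i = 0; i < nte; ++i) {
                if (yte[i] != a && yte[i] != b) continue;
                double f = -m.rho;
                for (int k = 0; k < p; ++k) f += m.w[k] * Xte[i + (size_t)k * nte];
                int pred = (f >= 0) ? a : b;
                if (pred == yte[i]) ++ncorrect;
                ++ntot;
            }
            pair_acc[pr] = ntot > 0 ? (double)ncorrect / ntot : NA_REAL;
        }
    }
}

// [[Rcpp::export(name = ".pairwise_accuracy_cpp")]]
NumericVector pairwise_accuracy_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                    NumericMatrix Xte, IntegerVector yte,
                                    int K, double cost, double eps) {
    int npair = K * (K - 1) / 2;
    NumericVector out(npair);
    pairwise_acc(REAL(Xtr), Xtr.nrow(), Xtr.ncol(), INTEGER(ytr),
                 REAL(Xte), Xte.nrow(), INTEGER(yte), K, cost, eps, REAL(out));
    return out;
}

// Permutation engine for one subject: shuffle training labels within runs
// (Fisher-Yates on R's RNG stream), retrain all pairs, test, return the mean
// pairwise accuracy per iteration. Patterns are assumed already normalized
// (the per-voxel transform does not depend on labels).
// [[Rcpp::export(name = ".perm_null_subject_cpp")]]
NumericVector perm_null_subject_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                    IntegerVector run,
                                    NumericMatrix Xte, IntegerVector yte,
                                    int K, double cost, double eps, int n_perm) {
    int ntr = Xtr.nrow();
    int npair = K * (K - 1) / 2;
    // group sample indices by run
    std::vector<std::vector<int> > by_run;
    std::vector<int> run_ids;
    for (int i = 0; i < ntr; ++i) {
        int g = -1;
        for (size_t r = 0; r < run_ids.size(); ++r) if (run_ids[r] == run[i]) { g = (int)r; break; }
        if (g < 0) { run_ids.push_back(run[i]); by_run.push_back(std::vector<int>()); g = (int)run_ids.size() - 1; }
        by_run[g].push_back(i);
    }
    std::vector<int> yperm(ntr);
    std::vector<double> pacc(npair);
    NumericVector out(n_perm);
    RNGScope scope;
    for (int it = 0; it < n_perm; ++it) {
        for (int i = 0; i < ntr; ++i) yperm[i] = ytr[i];
        for (size_t r = 0; r < by_run.size(); ++r) {
            std::vector<int>& idx = by_run[r];
            for (int k = (int)idx.size() - 1; k > 0; --k) {
                int j = (int)std::floor(unif_rand() * (k + 1));
                if (j > k) j = k;
                std::swap(yperm[idx[k]], yperm[idx[j]]);
            }
        }
        pairwise_acc(REAL(Xtr), ntr, Xtr.ncol(), yperm.data(),
                     REAL(Xte), Xte.nrow(), INTEGER(yte), K, cost, eps, pacc.data());
        double s = 0.0; int nv = 0;
        for (int q = 0; q < npair; ++q) if (!ISNAN(pacc[q])) { s += pacc[q]; ++nv; }
        out[it] = nv > 0 ? s / nv : NA_REAL;
    }
    return out;
}

// Searchlight engine: for each center, take the listed voxel columns,
// z-score each voxel by training statistics, train/test the pairwise bank.
// centers: list of 1-based column index vectors.
// [[Rcpp::export(name = ".searchlight_cpp")]]
NumericVector searchlight_cpp(NumericMatrix Xtr, IntegerVector ytr,
                              NumericMatrix Xte, IntegerVector yte,
                              List centers, int K, double cost, double eps) {
    int ntr = Xtr.nrow(), nte = Xte.nrow();
    int nc = centers.size();
    int npair = K * (K - 1) / 2;
    NumericVector out(nc);
    std::vector<double> pacc(npair);
    for (int c = 0; c < nc; ++c) {
        IntegerVector vox = centers[c];
        int p = vox.size();
        if (p < 2) { out[c] = NA_REAL; continue; }
        std::vector<double> Ztr((size_t)ntr * p), Zte((size_t)nte * p);
        for (int k = 0; k < p; ++k) {
            int col = vox[k] - 1;
            double mu = 0.0;
            for (int i = 0; i < ntr; ++i) mu += Xtr(i, col);
            mu /= ntr;
            double ss = 0.0;
            for (int i = 0; i < ntr; ++i) { double d = Xtr(i, col) - mu; ss += d * d; }
            double sd = ntr > 1 ? std::sqrt(ss / (ntr - 1)) : 0.0;
            if (sd > 0) {
                for (int i = 0; i < ntr; ++i) Ztr[i + (size_t)k * ntr] = (Xtr(i, col) - mu) / sd;
                for (int i = 0; i < nte; ++i) Zte[i + (size_t)k * nte] = (Xte(i, col) - mu) / sd;
            } else {
                for (int i = 0; i < ntr; ++i) Ztr[i + (size_t)k * ntr] = 0.0;
                for (int i = 0; i < nte; ++i) Zte[i + (size_t)k * nte] = 0.0;
            }
        }
        pairwise_acc(Ztr.data(), ntr, p, INTEGER(ytr),
                     Zte.data(), nte, INTEGER(yte), K, cost, eps, pacc.data());
        double s = 0.0; int nv = 0;
        for (int q = 0; q < npair; ++q) if (!ISNAN(pacc[q])) { s += pacc[q]; ++nv; }
        out[c] = nv > 0 ? s / nv : NA_REAL;
    }
    return out;
}
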