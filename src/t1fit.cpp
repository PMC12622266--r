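#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Inversion-recovery signal model, signed form: s(t) = A - B * exp(-t / t1s).
// For fixed t1s the model is linear in (A, B); variable projection solves the
// 2x2 normal equations in closed form and returns the residual sum of squares.
static double vp_rss(const std::vector<double> &ti, const std::vector<double> &s,
                     double t1s, double *A_out, double *B_out) {
    const int n = (int)ti.size();
    double sx = 0.0, sxx = 0.0, sy = 0.0, sxy = 0.0;
    for (int i = 0; i < n; ++i) {
        const double x = std::exp(-ti[i] / t1s);
        sx += x; sxx += x * x; sy += s[i]; sxy += x * s[i];
    }
    // minimize sum (A - B*x_i - s_i)^2 over (A, B):
    //   n*A - sx*B = sy
    //   sx*A - sxx*B = sxy
    const double det = (double)n * sxx - sx * sx;
    double A, B;
    if (std::fabs(det) < 1e-14) {           // x_i all (nearly) equal: degenerate
        A = sy / n; B = 0.0;
    } else {
        A = (sy * sxx - sx * sxy) / det;
        B = (sx * sy - (double)n * sxy) / det;
    }
    double rss = 0.0;
    for (int i = 0; i < n; ++i) {
        const double r = A - B * std::exp(-ti[i] / t1s) - s[i];
        rss += r * r;
    }
    *A_out = A; *B_out = B;
    return rss;
}

// Golden-section minimisation of vp_rss over log(t1s) on [lo, hi].
static double golden_t1s(const std::vector<double> &ti, const std::vector<double> &s,
                         double lo, double hi) {
    const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
    double a = std::log(lo), b = std::log(hi);
    double c = b - gr * (b - a), d = a + gr * (b - a);
    double Adum, Bdum;
    double fc = vp_rss(ti, s, std::exp(c), &Adum, &Bdum);
    double fd = vp_rss(ti, s, std::exp(d), &Adum, &Bdum);
    for (int it = 0; it < 90 && (b - a) > 1e-12; ++it) {
        if (fc < fd) {
            b = d; d = c; fd = fc;
            c = b - gr * (b - a);
            fc = vp_rss(ti, s, std::exp(c), &Adum, &Bdum);
        } else {
            a = c; c = d; fc = fd;
            d = a + gr * (b - a);
            fd = vp_rss(ti, s, std::exp(d), &Adum, &Bdum);
        }
    }
    return std::exp(0.5 * (a + b));
}

// Fit the 3-parameter model to one polarity-restored signal vector.
static void fit_one(const std::vector<double> &ti, const std::vector<double> &s,
                    double t1s_min, double t1s_max, int grid_n,
                    double *A, double *B, double *t1s, double *rss) {
    // coarse log-spaced grid, then golden-section refinement around the best cell
    const double la = std::log(t1s_min), lb = std::log(t1s_max);
    int best = 0;
    double best_rss = R_PosInf, Adum, Bdum;
    std::vector<double> grid(grid_n);
    for (int g = 0; g < grid_n; ++g) {
        grid[g] = std::exp(la + (lb - la) * g / (grid_n - 1));
        const double r = vp_rss(ti, s, grid[g], &Adum, &Bdum);
        if (r < best_rss) { best_rss = r; best = g; }
    }
    const double lo = grid[best > 0 ? best - 1 : 0];
    const double hi = grid[best < grid_n - 1 ? best + 1 : grid_n - 1];
    const double t1s_hat = golden_t1s(ti, s, lo, hi);
    *rss = vp_rss(ti, s, t1s_hat, A, B);
    *t1s = t1s_hat;
}

//' @noRd
// [[Rcpp::export(name = ".fit_t1_vp_cpp")]]
NumericMatrix fit_t1_vp_cpp(NumericMatrix signals, NumericVector ti,
                            bool magnitude, double t1s_min, double t1s_max,
                            int grid_n) {
    const int nv = signals.nrow(), np = signals.ncol();
    if ((int)ti.size() != np) stop("length(ti) must equal ncol(signals)");
    std::vector<double> tvec(ti.begin(), ti.end());
    NumericMatrix out(nv, 5);
    colnames(out) = CharacterVector::create("A", "B", "t1star", "rss", "flip_k");
    std::vector<double> s(np), sflip(np);
    for (int v = 0; v < nv; ++v) {
        for (int j = 0; j < np; ++j) s[j] = signals(v, j);
        // polarity restoration: magnitude IR data lose the sign of the early
        // (pre-null) samples; refit with the first k samples (in TI order)
        // negated for k = 0..np and keep the lowest-residual solution
        const int kmax = magnitude ? np : 0;
        double bA = NA_REAL, bB = NA_REAL, bT = NA_REAL, brss = R_PosInf;
        int bk = 0;
        for (int k = 0; k <= kmax; ++k) {
            for (int j = 0; j < np; ++j) sflip[j] = (j < k) ? -s[j] : s[j];
            double A, B, t1s, rss;
            fit_one(tvec, sflip, t1s_min, t1s_max, grid_n, &A, &B, &t1s, &rss);
            if (rss < brss) { brss = rss; bA = A; bB = B; bT = t1s; bk = k; }
        }
        out(v, 0) = bA; out(v, 1) = bB; out(v, 2) = bT;
        out(v, 3) = brss; out(v, 4) = bk;
    }
    return out;
}
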