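#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static double median_of(std::vector<double> v) {
    size_t n = v.size();
    if (n == 0) return NA_REAL;
    std::sort(v.begin(), v.end());
    if (n % 2 == 1) return v[n / 2];
    return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// normalized MAD (consistent with stats::mad, constant 1.4826)
static double madn_of(const std::vector<double>& v) {
    double med = median_of(v);
    std::vector<double> d(v.size());
    for (size_t i = 0; i < v.size(); ++i) d[i] = std::fabs(v[i] - med);
    return 1.4826 * median_of(d);
}

// Weiszfeld iteration for the bivariate spatial median
static void spatial_median2(const std::vector<double>& x,
                            const std::vector<double>& y,
                            double& cx, double& cy) {
    size_t n = x.size();
    cx = 0.0; cy = 0.0;
    for (size_t i = 0; i < n; ++i) { cx += x[i]; cy += y[i]; }
    cx /= n; cy /= n;
    const double tol = 1e-10;
    for (int it = 0; it < 200; ++it) {
        double sw = 0.0, nx = 0.0, ny = 0.0;
        for (size_t i = 0; i < n; ++i) {
            double dx = x[i] - cx, dy = y[i] - cy;
            double d = std::sqrt(dx * dx + dy * dy);
            if (d < tol) d = tol;
            double w = 1.0 / d;
            sw += w; nx += w * x[i]; ny += w * y[i];
        }
        nx /= sw; ny /= sw;
        double shift = std::sqrt((nx - cx) * (nx - cx) + (ny - cy) * (ny - cy));
        cx = nx; cy = ny;
        if (shift < tol) break;
    }
}

// Projection-type bivariate outlier flags: for every direction through the
// spatial median, apply the MAD-median rule with cutoff sqrt(chi2_{0.975}(2)).
static std::vector<bool> project_flags(const std::vector<double>& x,
                                       const std::vector<double>& y,
                                       double cutoff) {
    size_t n = x.size();
    double cx, cy;
    spatial_median2(x, y, cx, cy);
    std::vector<double> zx(n), zy(n);
    for (size_t i = 0; i < n; ++i) { zx[i] = x[i] - cx; zy[i] = y[i] - cy; }
    std::vector<bool> flag(n, false);
    std::vector<double> proj(n);
    for (size_t d = 0; d < n; ++d) {
        double nr = std::sqrt(zx[d] * zx[d] + zy[d] * zy[d]);
        if (nr < 1e-300) continue;
        double ux = zx[d] / nr, uy = zy[d] / nr;
        for (size_t i = 0; i < n; ++i) proj[i] = zx[i] * ux + zy[i] * uy;
        double med = median_of(proj);
        double madn = madn_of(proj);
        if (madn < 1e-300) continue;
        for (size_t i = 0; i < n; ++i) {
            if (std::fabs(proj[i] - med) / madn > cutoff) flag[i] = true;
        }
    }
    return flag;
}

// [[Rcpp::export]]
LogicalVector project_outliers_cpp(NumericVector x, NumericVector y,
                                   double cutoff) {
    std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
    std::vector<bool> f = project_flags(xv, yv, cutoff);
    LogicalVector out(f.size());
    for (size_t i = 0; i < f.size(); ++i) out[i] = f[i];
    return out;
}

// average ranks with ties
static std::vector<double> rank_avg(const std::vector<double>& v) {
    size_t n = v.size();
    std::vector<size_t> idx(n);
    for (size_t i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&v](size_t a, size_t b) { return v[a] < v[b]; });
    std::vector<double> r(n);
    size_t i = 0;
    while (i < n) {
        size_t j = i;
        while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
        double avg = 0.5 * (i + j) + 1.0;
        for (size_t k = i; k <= j; ++k) r[idx[k]] = avg;
        i = j + 1;
    }
    return r;
}

static double spearman(const std::vector<double>& x,
                       const std::vector<double>& y) {
    std::vector<double> rx = rank_avg(x), ry = rank_avg(y);
    size_t n = x.size();
    double mx = 0, my = 0;
    for (size_t i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
    mx /= n; my /= n;
    double sxy = 0, sxx = 0, syy = 0;
    for (size_t i = 0; i < n; ++i) {
        double dx = rx[i] - mx, dy = ry[i] - my;
        sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
    }
    if (sxx < 1e-300 || syy < 1e-300) return NA_REAL;
    return sxy / std::sqrt(sxx * syy);
}

// Skipped Spearman with a percentile bootstrap of the skipped estimator:
// the cleaned pairs are resampled and every bootstrap resample re-runs the
// outlier detection before correlating, so the selection step's variability
// is reflected in the p value.
// [[Rcpp::export]]
List skipped_spearman_cpp(NumericVector x, NumericVector y, int n_boot,
                          double cutoff) {
    int n = x.size();
    std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
    std::vector<bool> flag = project_flags(xv, yv, cutoff);
    std::vector<double> xc, yc;
    for (int i = 0; i < n; ++i) {
        if (!flag[i]) { xc.push_back(xv[i]); yc.push_back(yv[i]); }
    }
    int m = (int) xc.size();
    double rho = (m >= 2) ? spearman(xc, yc) : NA_REAL;
    int n_lo = 0, n_hi = 0, n_zero = 0, n_ok = 0;
    std::vector<double> xb(m), yb(m);
    for (int b = 0; b < n_boot; ++b) {
        for (int i = 0; i < m; ++i) {
            int j = (int) std::floor(unif_rand() * m);
            if (j >= m) j = m - 1;
            xb[i] = xc[j]; yb[i] = yc[j];
        }
        std::vector<bool> fb = project_flags(xb, yb, cutoff);
        std::vector<double> xcb, ycb;
        for (int i = 0; i < m; ++i) {
            if (!fb[i]) { xcb.push_back(xb[i]); ycb.push_back(yb[i]); }
        }
        if (xcb.size() < 3) continue;
        double rb = spearman(xcb, ycb);
        if (!R_finite(rb)) continue;
        ++n_ok;
        if (rb < 0) ++n_lo;
        else if (rb > 0) ++n_hi;
        else ++n_zero;
    }
    LogicalVector mask(n);
    for (int i = 0; i < n; ++i) mask[i] = flag[i];
    return List::create(_["rho"] = rho,
                        _["mask"] = mask,
                        _["n_used"] = (int) xc.size(),
                        _["n_boot_ok"] = n_ok,
                        _["n_lo"] = n_lo, _["n_hi"] = n_hi,
                        _["n_zero"] = n_zero);
}
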