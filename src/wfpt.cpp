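#include <Rcpp.h>
using namespace Rcpp;

// First-passage density at the LOWER boundary of a zero-drift Wiener process
// with unit boundary separation, relative start w in (0,1), evaluated at
// scaled time tt = t / a^2.  Series representation switched between the
// small-time (image) and large-time (spectral) expansions; the number of
// terms for each is the standard bound guaranteeing absolute error < eps,
// and the cheaper expansion is used.
static double fpt_lower_std(double tt, double w, double eps) {
    if (tt <= 0.0) return 0.0;

    double kl, ks;
    if (M_PI * tt * eps < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt *
                 std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }

    double p = 0.0;
    if (ks < kl) {                       // small-time expansion
        int K = (int)std::ceil(ks);
        int lo = -((K - 1) / 2);
        int hi = (int)std::ceil((K - 1) / 2.0);
        for (int k = lo; k <= hi; k++) {
            double x = w + 2.0 * k;
            p += x * std::exp(-x * x / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {                             // large-time expansion
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; k++) {
            p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                 std::sin(k * M_PI * w);
        }
        p *= M_PI;
    }
    return p;
}

// Log defective first-passage density for one boundary of a Wiener process
// with drift v, boundaries [0, a], start z_rel * a, diffusion coefficient 1,
// at decision time td = rt - t0.  'upper' selects the boundary; under
// accuracy coding the upper boundary is the correct response.
static double wfpt_log1(double rt, bool upper, double t0, double a,
                        double v, double w, double tol) {
    double td = rt - t0;
    if (!(td > 0.0)) return R_NegInf;
    // reflect so we always evaluate the lower-boundary form
    double ww = upper ? (1.0 - w) : w;
    double vv = upper ? -v : v;
    double tt = td / (a * a);
    double log_mult = -vv * a * ww - vv * vv * td / 2.0 - 2.0 * std::log(a);
    // absolute error target 'tol' on the final density scale
    double eps = tol * std::exp(-log_mult);
    if (!(eps > 0.0)) eps = tol;
    double p = fpt_lower_std(tt, ww, eps);
    if (!(p > 0.0)) return R_NegInf;
    return std::log(p) + log_mult;
}

// [[Rcpp::export]]
NumericVector wfpt_log_density_cpp(NumericVector rt, LogicalVector upper,
                                   double t0, double a, double v,
                                   double w, double tol) {
    R_xlen_t n = rt.size();
    NumericVector out(n);
    bool bad = !(a > 0.0) || !(t0 >= 0.0) || !(w > 0.0 && w < 1.0) ||
               !R_finite(v);
    for (R_xlen_t i = 0; i < n; i++) {
        if (bad || !R_finite(rt[i])) {
            out[i] = R_NegInf;
        } else {
            out[i] = wfpt_log1(rt[i], upper[i], t0, a, v, w, tol);
        }
    }
    return out;
}

// Summed trial log-likelihood per subject.  subj is a 1-based index into the
// per-subject parameter vectors; invalid parameter triples give -Inf for
// that subject.
// [[Rcpp::export]]
NumericVector wfpt_loglik_by_subject_cpp(NumericVector rt, LogicalVector upper,
                                         IntegerVector subj,
                                         NumericVector t0, NumericVector a,
                                         NumericVector v, double w,
                                         double tol) {
    int ns = t0.size();
    NumericVector out(ns);
    std::vector<bool> bad(ns);
    for (int s = 0; s < ns; s++) {
        bad[s] = !(a[s] > 0.0) || !(t0[s] >= 0.0) || !R_finite(v[s]);
        out[s] = bad[s] ? R_NegInf : 0.0;
    }
    R_xlen_t n = rt.size();
    for (R_xlen_t i = 0; i < n; i++) {
        int s = subj[i] - 1;
        if (bad[s] || out[s] == R_NegInf) continue;
        double l = wfpt_log1(rt[i], upper[i], t0[s], a[s], v[s], w, tol);
        out[s] = (l == R_NegInf) ? R_NegInf : out[s] + l;
    }
    return out;
}
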