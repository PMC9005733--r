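// Two-boundary Wiener diffusion numerics.
//
// All routines standardise the process by the within-trial noise s
// (a' = a/s, v' = v/s), after which s = 1; densities and probabilities
// are invariant under joint rescaling of (a, z, v, s).
//
// Density: small-time / large-time series with automatic switching
// (truncation chosen so the absolute error is below `err`).
// Defective CDF: large-time exponential series, terms accumulated until
// they fall below the requested tolerance.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-passage density at the LOWER bound for a Wiener process with
// s = 1, boundary separation a, relative start w = z/a, drift v,
// evaluated at decision time t (> 0).
static double dwfpt_lower(double t, double a, double v, double w, double err)
{
    if (!(t > 0.0)) return 0.0;
    double tt = t / (a * a); // time in units of a^2

    double ks, kl;
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt *
                             std::log(2.0 * err * std::sqrt(2.0 * M_PI * tt)));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }
    if (M_PI * tt * err < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }

    double p = 0.0;
    if (ks < kl) { // small-time expansion
        int K = (int)std::ceil(ks);
        int lo = -(int)std::floor((K - 1) / 2.0);
        int hi = (int)std::ceil((K - 1) / 2.0);
        for (int k = lo; k <= hi; ++k) {
            double x = w + 2.0 * k;
            p += x * std::exp(-x * x / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {       // large-time expansion
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; ++k)
            p += k * std::exp(-0.5 * k * k * M_PI * M_PI * tt) *
                 std::sin(k * M_PI * w);
        p *= M_PI;
    }

    double f = p * std::exp(-v * a * w - 0.5 * v * v * t) / (a * a);
    return (std::isfinite(f) && f > 0.0) ? f : 0.0;
}

// Absorption probability at the LOWER bound (t -> infinity), s = 1.
static double plower_inf(double a, double v, double w)
{
    if (std::fabs(v) < 1e-10) return 1.0 - w;
    // P(upper) = (exp(-2 v a w) - 1) / (exp(-2 v a) - 1)
    double pu = std::expm1(-2.0 * v * a * w) / std::expm1(-2.0 * v * a);
    double pl = 1.0 - pu;
    if (pl < 0.0) pl = 0.0;
    if (pl > 1.0) pl = 1.0;
    return pl;
}

// Defective CDF at the LOWER bound, s = 1, decision time t.
// Large-time series: F(t) = P_lower
//   - (2*pi/a^2) * exp(-v a w) * sum_k k sin(k pi w)
//       * exp(-(v^2/2 + k^2 pi^2 / (2 a^2)) t) / (v^2 + k^2 pi^2 / a^2)
static double pwfpt_lower(double t, double a, double v, double w, double err)
{
    if (!(t > 0.0)) return 0.0;
    double pl = plower_inf(a, v, w);
    double tt = t / (a * a);
    double pre = 2.0 * M_PI / (a * a) * std::exp(-v * a * w);
    double kmin = 1.0 / (M_PI * std::sqrt(tt)); // terms decay beyond this
    double sum = 0.0;
    for (int k = 1; k <= 2000000; ++k) {
        double lam = v * v + k * k * M_PI * M_PI / (a * a);
        double env = k * std::exp(-0.5 * lam * t) / lam; // sin-free envelope
        sum += env * std::sin(k * M_PI * w);
        if (k > kmin && pre * env < err * 1e-2) break;
    }
    double F = pl - pre * sum;
    if (F < 0.0) F = 0.0;
    if (F > pl) F = pl;
    return F;
}

// ---- helpers shared by the exported interface ----

struct Std {        // standardised parameters
    double a, w, v; // a/s, z/a, v/s
    bool ok;
};

static Std standardise(double a, double zr, double v, double s)
{
    Std q;
    q.ok = (a > 0.0) && (s > 0.0) && (zr > 0.0) && (zr < 1.0) &&
           std::isfinite(v);
    q.a = a / s;
    q.w = zr;
    q.v = v / s;
    return q;
}

// density of total RT t at a given bound (upper: true/false)
static double dens_at(double t, double a, double zr, double ter, double v,
                      double s, bool upper, double err)
{
    Std q = standardise(a, zr, v, s);
    if (!q.ok) Rcpp::stop("invalid diffusion parameters");
    double td = t - ter;
    if (!(td > 0.0)) return 0.0;
    if (upper) return dwfpt_lower(td, q.a, -q.v, 1.0 - q.w, err);
    return dwfpt_lower(td, q.a, q.v, q.w, err);
}

static double cdf_at(double t, double a, double zr, double ter, double v,
                     double s, bool upper, double err)
{
    Std q = standardise(a, zr, v, s);
    if (!q.ok) Rcpp::stop("invalid diffusion parameters");
    double td = t - ter;
    if (!(td > 0.0)) return 0.0;
    if (upper) return pwfpt_lower(td, q.a, -q.v, 1.0 - q.w, err);
    return pwfpt_lower(td, q.a, q.v, q.w, err);
}

static double surv_at(double deadline, double a, double zr, double ter,
                      double v, double s, double err)
{
    double F = cdf_at(deadline, a, zr, ter, v, s, true, err) +
               cdf_at(deadline, a, zr, ter, v, s, false, err);
    double S = 1.0 - F;
    if (S < 0.0) S = 0.0;
    if (S > 1.0) S = 1.0;
    return S;
}

// [[Rcpp::export(name = ".wfpt_pdf_cpp")]]
NumericVector wfpt_pdf_cpp(NumericVector t, double a, double zr, double ter,
                           double v, double s, bool upper, double err)
{
    int n = t.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = dens_at(t[i], a, zr, ter, v, s, upper, err);
    return out;
}

// [[Rcpp::export(name = ".wfpt_cdf_cpp")]]
NumericVector wfpt_cdf_cpp(NumericVector t, double a, double zr, double ter,
                           double v, double s, bool upper, double err)
{
    int n = t.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = cdf_at(t[i], a, zr, ter, v, s, upper, err);
    return out;
}

// [[Rcpp::export(name = ".wfpt_survivor_cpp")]]
double wfpt_survivor_cpp(double deadline, double a, double zr, double ter,
                         double v, double s, double err)
{
    return surv_at(deadline, a, zr, ter, v, s, err);
}

// Per-participant log-likelihood.
// Trial encoding (prepared in R once per dataset):
//   rt[i]      total RT in seconds (ignored when censored)
//   bound[i]   1 = upper, 0 = lower (ignored when censored)
//   vsign[i]   +1 / -1, multiplies the level drift (stimulus coding)
//   level[i]   1 or 2, selects v1 / v2
//   cens[i]    1 = censored (no response), 0 = responded
// Excluded trials are not passed in at all.
// [[Rcpp::export(name = ".wfpt_loglik_cpp")]]
double wfpt_loglik_cpp(NumericVector rt, IntegerVector bound,
                       IntegerVector vsign, IntegerVector level,
                       IntegerVector cens, double a, double zr, double ter,
                       double v1, double v2, double s, double deadline,
                       double err)
{
    if (!(a > 0.0) || !(s > 0.0) || !(zr > 0.0) || !(zr < 1.0) || ter < 0.0)
        return R_NegInf;
    int n = rt.size();
    double lvl[2] = { v1, v2 };
    // survivor cache per (level, sign): -1 marks unset
    double sc[2][2] = { { -1.0, -1.0 }, { -1.0, -1.0 } };
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
        int li = level[i] - 1;
        double v = lvl[li] * vsign[i];
        if (cens[i]) {
            int si = vsign[i] > 0 ? 1 : 0;
            if (sc[li][si] < 0.0) {
                double S = (ter >= deadline)
                               ? 1.0
                               : surv_at(deadline, a, zr, ter, v, s, err);
                sc[li][si] = S;
            }
            double S = sc[li][si];
            if (S <= 0.0) return R_NegInf;
            ll += std::log(S);
        } else {
            double d = dens_at(rt[i], a, zr, ter, v, s, bound[i] == 1, err);
            if (d <= 0.0) return R_NegInf;
            ll += std::log(d);
        }
        if (!std::isfinite(ll)) return R_NegInf;
    }
    return ll;
}

// Vectorised over participants: trial data concatenated with offsets.
// params: matrix nP x 5 with columns (a, zr, ter, v1, v2).
// [[Rcpp::export(name = ".wfpt_loglik_many_cpp")]]
NumericVector wfpt_loglik_many_cpp(NumericVector rt, IntegerVector bound,
                                   IntegerVector vsign, IntegerVector level,
                                   IntegerVector cens, IntegerVector offset,
                                   NumericMatrix params, double s,
                                   double deadline, double err)
{
    int nP = params.nrow();
    NumericVector out(nP);
    for (int p = 0; p < nP; ++p) {
        int from = offset[p], to = offset[p + 1]; // [from, to)
        double a = params(p, 0), zr = params(p, 1), ter = params(p, 2);
        double v1 = params(p, 3), v2 = params(p, 4);
        if (!(a > 0.0) || !(zr > 0.0) || !(zr < 1.0) || ter < 0.0) {
            out[p] = R_NegInf;
            continue;
        }
        double lvl[2] = { v1, v2 };
        double sc[2][2] = { { -1.0, -1.0 }, { -1.0, -1.0 } };
        double ll = 0.0;
        for (int i = from; i < to; ++i) {
            int li = level[i] - 1;
            double v = lvl[li] * vsign[i];
            if (cens[i]) {
                int si = vsign[i] > 0 ? 1 : 0;
                if (sc[li][si] < 0.0)
                    sc[li][si] = (ter >= deadline)
                                     ? 1.0
                                     : surv_at(deadline, a, zr, ter, v, s, err);
                if (sc[li][si] <= 0.0) { ll = R_NegInf; break; }
                ll += std::log(sc[li][si]);
            } else {
                double d = dens_at(rt[i], a, zr, ter, v, s, bound[i] == 1, err);
                if (d <= 0.0) { ll = R_NegInf; break; }
                ll += std::log(d);
            }
            if (!std::isfinite(ll)) { ll = R_NegInf; break; }
        }
        out[p] = ll;
    }
    return out;
}

// Exact trial sampling by inversion of the defective CDFs.
// Returns rt (NA when censored) and response (1 upper, 0 lower, NA censored).
// Uses R's RNG so set.seed() gives bit-exact reproducibility.
// [[Rcpp::export(name = ".wfpt_sim_inverse_cpp")]]
List wfpt_sim_inverse_cpp(int n, double a, double zr, double ter, double v,
                          double s, double deadline, double err)
{
    Std q = standardise(a, zr, v, s);
    if (!q.ok) Rcpp::stop("invalid diffusion parameters");
    NumericVector rt(n);
    IntegerVector resp(n);
    double tdmax = deadline - ter;
    double Fu_dead = (tdmax > 0.0)
                         ? pwfpt_lower(tdmax, q.a, -q.v, 1.0 - q.w, err)
                         : 0.0;
    double Fl_dead = (tdmax > 0.0)
                         ? pwfpt_lower(tdmax, q.a, q.v, q.w, err)
                         : 0.0;
    double pu_inf = 1.0 - plower_inf(q.a, q.v, q.w);
    for (int i = 0; i < n; ++i) {
        double u = unif_rand();
        bool upper;
        double target, Fdead;
        if (u < pu_inf) {
            upper = true; target = u; Fdead = Fu_dead;
        } else {
            upper = false; target = u - pu_inf; Fdead = Fl_dead;
        }
        if (target >= Fdead) { // decision after the deadline -> censored
            rt[i] = NA_REAL;
            resp[i] = NA_INTEGER;
            continue;
        }
        // bisection on decision time in (0, tdmax]
        double lo = 0.0, hi = tdmax;
        for (int it = 0; it < 80; ++it) {
            double mid = 0.5 * (lo + hi);
            double F = upper ? pwfpt_lower(mid, q.a, -q.v, 1.0 - q.w, err)
                             : pwfpt_lower(mid, q.a, q.v, q.w, err);
            if (F < target) lo = mid; else hi = mid;
            if (hi - lo < 1e-12) break;
        }
        rt[i] = ter + 0.5 * (lo + hi);
        resp[i] = upper ? 1 : 0;
    }
    return List::create(_["rt"] = rt, _["response"] = resp);
}

// Euler-Maruyama sampling with Brownian-bridge crossing correction;
// an independent route used for cross-validation of the analytic code.
// [[Rcpp::export(name = ".wfpt_sim_euler_cpp")]]
List wfpt_sim_euler_cpp(int n, double a, double zr, double ter, double v,
                        double s, double deadline, double dt)
{
    if (!(a > 0.0) || !(s > 0.0) || !(zr > 0.0) || !(zr < 1.0) || !(dt > 0.0))
        Rcpp::stop("invalid parameters");
    NumericVector rt(n);
    IntegerVector resp(n);
    double sdt = s * std::sqrt(dt);
    double s2dt = s * s * dt;
    double z0 = zr * a;
    for (int i = 0; i < n; ++i) {
        double x = z0, t = 0.0;
        int r = NA_INTEGER;
        double hit = NA_REAL;
        while (t + ter < deadline) {
            double xn = x + v * dt + sdt * norm_rand();
            t += dt;
            if (xn >= a) { // linear interpolation of the crossing time
                r = 1; hit = t - dt + dt * (a - x) / (xn - x); break;
            }
            if (xn <= 0.0) {
                r = 0; hit = t - dt + dt * x / (x - xn); break;
            }
            // bridge probability of an unobserved crossing within the step
            double pu = std::exp(-2.0 * (a - x) * (a - xn) / s2dt);
            if (unif_rand() < pu) { r = 1; hit = t - 0.5 * dt; break; }
            double pl = std::exp(-2.0 * x * xn / s2dt);
            if (unif_rand() < pl) { r = 0; hit = t - 0.5 * dt; break; }
            x = xn;
        }
        if (r == NA_INTEGER || hit + ter > deadline) {
            rt[i] = NA_REAL;
            resp[i] = NA_INTEGER;
        } else {
            rt[i] = ter + hit;
            resp[i] = r;
        }
    }
    return List::create(_["rt"] = rt, _["response"] = resp);
}
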