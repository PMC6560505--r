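/* Compiled fast paths for the Laplace individual objective function value
 * (IOFV): the inner Newton search for the random-effect mode plus the
 * Laplace log-determinant correction, for
 *   - the closed-form one-compartment oral model, and
 *   - the two-compartment model with parallel linear and Michaelis-Menten
 *     elimination (RK45 with bolus events).
 *
 * The R implementations in mixture_inference.R / structural_models.R are
 * the reference; agreement is checked in the test suite.
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define MAXP 8

/* ---------- structural predictions ------------------------------------ */

typedef struct {
    int model;               /* 0 = onecmt oral, 1 = twocmt parallel      */
    double th[6];            /* model 0: ka CL V; model 1: CLlin Vmax Km V1 V2 Q */
    const double *obs_t, *obs_y;
    int n_obs;
    const double *dose_t, *dose_a;
    int n_dose;
    const int *eta_idx;
    const double *omega;
    int p;
    double sig_prop, sig_add;
} subj_data;

static void pred_onecmt(const double *ind, const subj_data *d, double *f)
{
    double ka = ind[0], CL = ind[1], V = ind[2];
    double ke = CL / V;
    for (int i = 0; i < d->n_obs; i++) {
        double s = 0.0, t = d->obs_t[i];
        for (int m = 0; m < d->n_dose; m++) {
            double dt = t - d->dose_t[m];
            if (dt <= 0) continue;
            if (fabs(ka - ke) < 1e-8 * ka)
                s += d->dose_a[m] * ka * dt * exp(-ka * dt) / V;
            else
                s += d->dose_a[m] * ka / (V * (ka - ke)) *
                     (exp(-ke * dt) - exp(-ka * dt));
        }
        f[i] = s > 0 ? s : 0;
    }
}

/* two-compartment parallel elimination RHS */
static void rhs_par2(const double *ind, const double *y, double *dy)
{
    double CLlin = ind[0], Vmax = ind[1], Km = ind[2];
    double V1 = ind[3], V2 = ind[4], Q = ind[5];
    double C = y[0] / V1;
    double mm = Vmax * C / (Km + C);
    dy[0] = -(CLlin / V1) * y[0] - mm - (Q / V1) * y[0] + (Q / V2) * y[1];
    dy[1] = (Q / V1) * y[0] - (Q / V2) * y[1];
}

/* Dormand-Prince RK45, adaptive, integrating y from t0 to t1 in place.
 * Returns 0 on failure. */
static int rk45_advance(const double *ind, double *y, double t0, double t1,
                        double rtol, double atol)
{
    static const double
        c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9,
        a21 = 1.0/5,
        a31 = 3.0/40, a32 = 9.0/40,
        a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9,
        a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561,
        a54 = -212.0/729,
        a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
        a64 = 49.0/176, a65 = -5103.0/18656,
        b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
        b5 = -2187.0/6784, b6 = 11.0/84,
        e1 = 35.0/384 - 5179.0/57600, e3 = 500.0/1113 - 7571.0/16695,
        e4 = 125.0/192 - 393.0/640, e5 = -2187.0/6784 + 92097.0/339200,
        e6 = 11.0/84 - 187.0/2100, e7 = -1.0/40;
    double t = t0, h = (t1 - t0) / 10.0;
    if (h <= 0) return 1;
    if (h > 50.0) h = 50.0;
    double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], yt[2], ynew[2];
    rhs_par2(ind, y, k1);
    int nstep = 0;
    while (t < t1 - 1e-12 * (t1 + 1)) {
        if (++nstep > 1000000) return 0;
        if (t + h > t1) h = t1 - t;
        for (int i = 0; i < 2; i++) yt[i] = y[i] + h * a21 * k1[i];
        rhs_par2(ind, yt, k2);
        for (int i = 0; i < 2; i++)
            yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
        rhs_par2(ind, yt, k3);
        for (int i = 0; i < 2; i++)
            yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
        rhs_par2(ind, yt, k4);
        for (int i = 0; i < 2; i++)
            yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                                a54 * k4[i]);
        rhs_par2(ind, yt, k5);
        for (int i = 0; i < 2; i++)
            yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                a64 * k4[i] + a65 * k5[i]);
        rhs_par2(ind, yt, k6);
        for (int i = 0; i < 2; i++)
            ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                  b5 * k5[i] + b6 * k6[i]);
        rhs_par2(ind, ynew, k7);
        double err = 0.0;
        for (int i = 0; i < 2; i++) {
            double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
            double sc = atol + rtol * fmax(fabs(y[i]), fabs(ynew[i]));
            double r = ei / sc;
            err += r * r;
        }
        err = sqrt(err / 2.0);
        if (err <= 1.0) {
            t += h;
            y[0] = ynew[0]; y[1] = ynew[1];
            k1[0] = k7[0]; k1[1] = k7[1];   /* FSAL */
        }
        double fac = err > 0 ? 0.9 * pow(err, -0.2) : 5.0;
        if (fac > 5.0) fac = 5.0;
        if (fac < 0.2) fac = 0.2;
        h *= fac;
        if (h < 1e-10) return 0;
    }
    return 1;
}

/* predict concentrations at the (sorted) observation times; doses sorted */
static int pred_par2(const double *ind, const subj_data *d, double *f)
{
    double y[2] = { 0.0, 0.0 };
    double t = d->dose_t[0];
    int io = 0;
    /* observations at or before the first dose are zero */
    while (io < d->n_obs && d->obs_t[io] <= t) f[io++] = 0.0;
    for (int m = 0; m < d->n_dose; m++) {
        if (m > 0) {
            /* integrate up to this dose time, collecting observations */
            while (io < d->n_obs && d->obs_t[io] <= d->dose_t[m]) {
                if (!rk45_advance(ind, y, t, d->obs_t[io], 1e-8, 1e-10))
                    return 0;
                t = d->obs_t[io];
                f[io++] = y[0] / ind[3] > 0 ? y[0] / ind[3] : 0;
            }
            if (!rk45_advance(ind, y, t, d->dose_t[m], 1e-8, 1e-10))
                return 0;
            t = d->dose_t[m];
        }
        y[0] += d->dose_a[m];
    }
    while (io < d->n_obs) {
        if (!rk45_advance(ind, y, t, d->obs_t[io], 1e-8, 1e-10))
            return 0;
        t = d->obs_t[io];
        f[io++] = y[0] / ind[3] > 0 ? y[0] / ind[3] : 0;
    }
    return 1;
}

/* ---------- -2 log joint density h(eta) -------------------------------- */

static double h_subj(const subj_data *d, const double *eta)
{
    double ind[6];
    int nth = d->model == 0 ? 3 : 6;
    for (int j = 0; j < nth; j++) ind[j] = d->th[j];
    for (int j = 0; j < d->p; j++)
        ind[d->eta_idx[j]] *= exp(eta[j]);
    double f[64];
    if (d->n_obs > 64) error("too many observations per subject");
    if (d->model == 0) {
        pred_onecmt(ind, d, f);
    } else {
        if (!pred_par2(ind, d, f)) return R_PosInf;
    }
    double out = 0.0;
    for (int i = 0; i < d->n_obs; i++) {
        double v = d->sig_prop * f[i] * f[i] + d->sig_add;
        if (v < 1e-12) v = 1e-12;
        double r = d->obs_y[i] - f[i];
        out += log(v) + r * r / v;
    }
    for (int j = 0; j < d->p; j++)
        out += eta[j] * eta[j] / d->omega[j];
    return out;
}

/* ---------- dense linear algebra (p <= MAXP) --------------------------- */

static int chol_logdet(double *A, int p, double *logdet)
{
    double ld = 0.0;
    for (int i = 0; i < p; i++) {
        for (int j = i; j < p; j++) {
            double s = A[i * p + j];
            for (int k = 0; k < i; k++)
                s -= A[k * p + i] * A[k * p + j];
            if (i == j) {
                if (s <= 0) return 0;
                A[i * p + i] = sqrt(s);
                ld += log(s);
            } else {
                A[i * p + j] = s / A[i * p + i];
            }
        }
    }
    *logdet = ld;
    return 1;
}

static int newton_step(const double *H, const double *g, double lambda,
                       int p, double *x)
{
    double A[MAXP * MAXP], ld;
    for (int i = 0; i < p; i++)
        for (int j = 0; j < p; j++)
            A[i * p + j] = H[i * p + j] + (i == j ? lambda : 0.0);
    if (!chol_logdet(A, p, &ld)) return 0;
    double y[MAXP];
    for (int i = 0; i < p; i++) {
        double s = -g[i];
        for (int k = 0; k < i; k++) s -= A[k * p + i] * y[k];
        y[i] = s / A[i * p + i];
    }
    for (int i = p - 1; i >= 0; i--) {
        double s = y[i];
        for (int k = i + 1; k < p; k++) s -= A[i * p + k] * x[k];
        x[i] = s / A[i * p + i];
    }
    return 1;
}

static void fd_grad_hess(const subj_data *d, const double *eta,
                         double *g, double *H)
{
    int p = d->p;
    double hstep[MAXP], e[MAXP];
    double f0 = h_subj(d, eta);
    for (int j = 0; j < p; j++)
        hstep[j] = 1e-4 * (fabs(eta[j]) > 1 ? fabs(eta[j]) : 1.0);
    for (int i = 0; i < p; i++) {
        for (int j = 0; j < p; j++) e[j] = eta[j];
        e[i] = eta[i] + hstep[i];
        double fp = h_subj(d, e);
        e[i] = eta[i] - hstep[i];
        double fm = h_subj(d, e);
        g[i] = (fp - fm) / (2 * hstep[i]);
        H[i * p + i] = (fp - 2 * f0 + fm) / (hstep[i] * hstep[i]);
        for (int j = 0; j < i; j++) {
            double fpp, fpm, fmp, fmm;
            for (int k = 0; k < p; k++) e[k] = eta[k];
            e[i] = eta[i] + hstep[i]; e[j] = eta[j] + hstep[j];
            fpp = h_subj(d, e);
            e[j] = eta[j] - hstep[j];
            fpm = h_subj(d, e);
            e[i] = eta[i] - hstep[i]; e[j] = eta[j] + hstep[j];
            fmp = h_subj(d, e);
            e[j] = eta[j] - hstep[j];
            fmm = h_subj(d, e);
            H[i * p + j] = H[j * p + i] =
                (fpp - fpm - fmp + fmm) / (4 * hstep[i] * hstep[j]);
        }
    }
}

/* ---------- Laplace IOFV ------------------------------------------------ */

static SEXP laplace_core(subj_data *d, const double *eta0)
{
    int p = d->p;
    double eta[MAXP];
    for (int j = 0; j < p; j++) eta[j] = eta0[j];
    double hval = h_subj(d, eta);
    if (!R_FINITE(hval)) {
        for (int j = 0; j < p; j++) eta[j] = 0.0;
        hval = h_subj(d, eta);
    }

    /* coarse coordinate scan from the origin: guards against starts in the
     * wrong basin when the component badly mispredicts the subject */
    {
        double cand[MAXP], hbest;
        for (int j = 0; j < p; j++) cand[j] = 0.0;
        hbest = h_subj(d, cand);
        for (int j = 0; j < p; j++) {
            double bestv = cand[j];
            for (double v = -3.0; v <= 3.0001; v += 0.5) {
                cand[j] = v;
                double hv = h_subj(d, cand);
                if (R_FINITE(hv) && hv < hbest) { hbest = hv; bestv = v; }
            }
            cand[j] = bestv;
        }
        if (hbest < hval) {
            for (int j = 0; j < p; j++) eta[j] = cand[j];
            hval = hbest;
        }
    }

    double g[MAXP], H[MAXP * MAXP], step[MAXP], trial[MAXP];
    for (int it = 0; it < 200; it++) {
        fd_grad_hess(d, eta, g, H);
        double gmax = 0.0;
        for (int j = 0; j < p; j++)
            if (fabs(g[j]) > gmax) gmax = fabs(g[j]);
        if (gmax < 1e-7) break;
        double lambda = 0.0;
        if (!newton_step(H, g, lambda, p, step)) {
            lambda = 1e-4;
            while (!newton_step(H, g, lambda, p, step) && lambda < 1e6)
                lambda *= 10;
        }
        double tstep = 1.0, hnew = R_PosInf;
        int ok = 0;
        for (int ls = 0; ls < 12; ls++) {
            for (int j = 0; j < p; j++) {
                trial[j] = eta[j] + tstep * step[j];
                if (trial[j] > 12) trial[j] = 12;
                if (trial[j] < -12) trial[j] = -12;
            }
            hnew = h_subj(d, trial);
            if (R_FINITE(hnew) && hnew <= hval + 1e-12) { ok = 1; break; }
            tstep *= 0.5;
        }
        if (!ok) break;
        double delta = hval - hnew;
        for (int j = 0; j < p; j++) eta[j] = trial[j];
        hval = hnew;
        if (delta < 1e-12 * (fabs(hval) + 1.0)) break;
    }

    /* Laplace correction: h(mode) + sum log omega + log det(H/2) */
    fd_grad_hess(d, eta, g, H);
    double Hhalf[MAXP * MAXP], ld;
    for (int i = 0; i < p * p; i++) Hhalf[i] = H[i] / 2.0;
    if (!chol_logdet(Hhalf, p, &ld)) {
        ld = 0.0;
        for (int j = 0; j < p; j++) ld += -log(d->omega[j]);
    }
    double iofv = hval + ld;
    for (int j = 0; j < p; j++) iofv += log(d->omega[j]);

    SEXP out = PROTECT(allocVector(REALSXP, 1 + p));
    REAL(out)[0] = iofv;
    for (int j = 0; j < p; j++) REAL(out)[1 + j] = eta[j];
    UNPROTECT(1);
    return out;
}

static void fill_common(subj_data *d, SEXP th_, SEXP obs_t_, SEXP obs_y_,
                        SEXP dose_t_, SEXP dose_a_, SEXP eta_idx_,
                        SEXP omega_, SEXP sig_)
{
    int nth = LENGTH(th_);
    for (int j = 0; j < nth && j < 6; j++) d->th[j] = REAL(th_)[j];
    d->obs_t = REAL(obs_t_); d->obs_y = REAL(obs_y_);
    d->n_obs = LENGTH(obs_t_);
    d->dose_t = REAL(dose_t_); d->dose_a = REAL(dose_a_);
    d->n_dose = LENGTH(dose_t_);
    d->eta_idx = INTEGER(eta_idx_);
    d->omega = REAL(omega_);
    d->p = LENGTH(omega_);
    d->sig_prop = REAL(sig_)[0]; d->sig_add = REAL(sig_)[1];
    if (d->p > MAXP) error("too many random effects for the compiled path");
}

SEXP C_laplace_onecmt(SEXP th_, SEXP obs_t_, SEXP obs_y_, SEXP dose_t_,
                      SEXP dose_a_, SEXP eta_idx_, SEXP omega_, SEXP sig_,
                      SEXP eta0_)
{
    subj_data d;
    d.model = 0;
    fill_common(&d, th_, obs_t_, obs_y_, dose_t_, dose_a_, eta_idx_,
                omega_, sig_);
    return laplace_core(&d, REAL(eta0_));
}

SEXP C_laplace_twocmt(SEXP th_, SEXP obs_t_, SEXP obs_y_, SEXP dose_t_,
                      SEXP dose_a_, SEXP eta_idx_, SEXP omega_, SEXP sig_,
                      SEXP eta0_)
{
    subj_data d;
    d.model = 1;
    fill_common(&d, th_, obs_t_, obs_y_, dose_t_, dose_a_, eta_idx_,
                omega_, sig_);
    return laplace_core(&d, REAL(eta0_));
}
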