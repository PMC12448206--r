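/* Fast event-handling integrator for the quasi-steady-state reduced
 * system (see tk_derivs_qss): a Rosenbrock(2,3) method (the ode23s
 * scheme of Shampine & Reichelt) with analytic Jacobian and bolus
 * events applied inside the C loop. L-stable, so neither the fast gut
 * absorption (ka ~ 1e2/h) nor the deep-compartment exchange limits the
 * step size; built for calibration workloads where repeated-dose
 * schedules make per-event solver restarts in the interpreter the
 * dominant cost.
 *
 * States: y[0] Agut, y[1] Aprim, y[2] Adeep, y[3] Aurine, y[4] Aunabs.
 * Parameter vector matches tk_initmod's layout.
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define NST 5

typedef struct {
    double ka, bioAv, k12, k21, Qfil, Free, Vc, Tm, Kt;
    const double *ft; const double *fv; int fn; /* forcing grid */
} qss_pars;

static void forcing_at(const qss_pars *P, double t, double *rate,
                       double *slope)
{
    *slope = 0.0;
    if (P->fn == 0) { *rate = 0.0; return; }
    if (t <= P->ft[0]) { *rate = P->fv[0]; return; }
    if (t >= P->ft[P->fn - 1]) { *rate = P->fv[P->fn - 1]; return; }
    int lo = 0, hi = P->fn - 1;
    while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (P->ft[mid] <= t) lo = mid; else hi = mid;
    }
    double s = (P->fv[hi] - P->fv[lo]) / (P->ft[hi] - P->ft[lo]);
    *rate = P->fv[lo] + s * (t - P->ft[lo]);
    *slope = s;
}

static double qss_cfil(const qss_pars *P, double Aprim)
{
    double F = P->Qfil * P->Free * Aprim / P->Vc;
    double b = P->Qfil * P->Kt + P->Tm - F;
    double disc = b * b + 4.0 * P->Qfil * F * P->Kt;
    return (-b + sqrt(disc)) / (2.0 * P->Qfil);
}

static void qss_rhs(const qss_pars *P, double t, const double *y,
                    double *dy)
{
    double rate, slope;
    forcing_at(P, t, &rate, &slope);
    double gut_out = P->ka * y[0];
    double Cfil = qss_cfil(P, y[1]);
    dy[0] = rate - gut_out;
    dy[1] = P->bioAv * gut_out + P->k21 * y[2] - P->k12 * y[1]
            - P->Qfil * Cfil;
    dy[2] = P->k12 * y[1] - P->k21 * y[2];
    dy[3] = P->Qfil * Cfil;
    dy[4] = (1.0 - P->bioAv) * gut_out;
}

/* solve (I - hd*J) x = b in place; J is the analytic Jacobian at y.
 * The only state-dependent entry is the elimination slope
 * d(Qfil*Cfil)/dAprim = Qfil^2*Free/Vc / g'(Cfil),
 * g'(C) = Qfil + Tm*Kt/(Kt+C)^2. */
static void w_solve(const qss_pars *P, const double *y, double hd,
                    double *b)
{
    double C = qss_cfil(P, y[1]);
    double gp = P->Qfil + P->Tm * P->Kt /
                ((P->Kt + C) * (P->Kt + C));
    double kel = P->Qfil * P->Qfil * P->Free / (P->Vc * gp);

    /* W row structure (unknowns x0..x4):
       x0: (1 + hd*ka) x0 = b0
       x1,x2: 2x2 block coupled, driven by x0
       x3: x3 - hd*kel*x1 = b3
       x4: x4 - hd*(1-bioAv)*ka*x0 = b4 */
    double x0 = b[0] / (1.0 + hd * P->ka);
    double r1 = b[1] + hd * P->bioAv * P->ka * x0;
    double r2 = b[2];
    double a11 = 1.0 + hd * (P->k12 + kel);
    double a12 = -hd * P->k21;
    double a21 = -hd * P->k12;
    double a22 = 1.0 + hd * P->k21;
    double det = a11 * a22 - a12 * a21;
    double x1 = (r1 * a22 - a12 * r2) / det;
    double x2 = (a11 * r2 - a21 * r1) / det;
    b[0] = x0;
    b[1] = x1;
    b[2] = x2;
    b[3] = b[3] + hd * kel * x1;
    b[4] = b[4] + hd * (1.0 - P->bioAv) * P->ka * x0;
}

/* args: times (sorted output times, first = t0), parms (length-10 vector,
 * tk_initmod layout), ev_time/ev_var/ev_amt (events, sorted by time),
 * forc (2-col matrix or NULL), rtol, atol.
 * Returns length(times) x 6 matrix: 5 states + Cfil. */
SEXP C_rk_sim_qss(SEXP times, SEXP parms, SEXP ev_time, SEXP ev_var,
                  SEXP ev_amt, SEXP forc, SEXP rtol_, SEXP atol_)
{
    const double *tt = REAL(times);
    const int nt = LENGTH(times);
    const double *pp = REAL(parms);
    qss_pars P = {pp[0], pp[1], pp[2], pp[3], pp[4], pp[5], pp[6],
                  pp[8], pp[9], NULL, NULL, 0};
    if (!isNull(forc)) {
        P.fn = nrows(forc);
        P.ft = REAL(forc);
        P.fv = REAL(forc) + P.fn;
    }
    const int nev = LENGTH(ev_time);
    const double *et = REAL(ev_time);
    const int *evar = INTEGER(ev_var);
    const double *eamt = REAL(ev_amt);
    const double rtol = asReal(rtol_), atol = asReal(atol_);

    SEXP out = PROTECT(allocMatrix(REALSXP, nt, NST + 1));
    double *o = REAL(out);

    const double d = 1.0 / (2.0 + sqrt(2.0));
    const double e32 = 6.0 + sqrt(2.0);

    double y[NST] = {0, 0, 0, 0, 0};
    double ymax[NST] = {0, 0, 0, 0, 0};  /* running state maxima */
    double f0[NST], f1[NST], f2[NST], k1[NST], k2[NST], k3[NST],
           ynew[NST], ymid[NST];
    double t = tt[0];
    double h = 1e-2, h_use;
    int iev = 0, iout = 0, i;

    while (iev < nev && et[iev] <= t) {
        y[evar[iev] - 1] += eamt[iev];
        iev++;
    }
    for (i = 0; i < NST; i++) ymax[i] = y[i];
    o[0] = y[0]; o[nt] = y[1]; o[2 * nt] = y[2]; o[3 * nt] = y[3];
    o[4 * nt] = y[4]; o[5 * nt] = qss_cfil(&P, y[1]);
    iout = 1;

    while (iout < nt) {
        double target = tt[iout];
        if (iev < nev && et[iev] < target) target = et[iev];
        long guard = 0;
        while (t < target) {
            if (++guard > 2000000)
                error("rosenbrock integrator: step limit at t = %g", t);
            int clipped = 0;
            h_use = h;
            if (t + h_use >= target) { h_use = target - t; clipped = 1; }
            double hd = h_use * d;

            qss_rhs(&P, t, y, f0);
            /* time-derivative term: forcing slope enters dAgut only */
            double rate, slope;
            forcing_at(&P, t, &rate, &slope);
            for (i = 0; i < NST; i++) k1[i] = f0[i];
            k1[0] += hd * slope;
            w_solve(&P, y, hd, k1);

            for (i = 0; i < NST; i++) ymid[i] = y[i] + 0.5 * h_use * k1[i];
            qss_rhs(&P, t + 0.5 * h_use, ymid, f1);
            for (i = 0; i < NST; i++) k2[i] = f1[i] - k1[i];
            w_solve(&P, y, hd, k2);
            for (i = 0; i < NST; i++) k2[i] += k1[i];

            for (i = 0; i < NST; i++) ynew[i] = y[i] + h_use * k2[i];
            qss_rhs(&P, t + h_use, ynew, f2);
            for (i = 0; i < NST; i++) {
                k3[i] = f2[i] - e32 * (k2[i] - f1[i]) - 2.0 * (k1[i] - f0[i]);
            }
            k3[0] += hd * slope;
            w_solve(&P, y, hd, k3);

            /* error relative to the running maximum of each state:
             * a decayed gut bolus must not throttle the step size */
            double err = 0.0;
            for (i = 0; i < NST; i++) {
                double e = (h_use / 6.0) * (k1[i] - 2.0 * k2[i] + k3[i]);
                double ym = ymax[i];
                double an = fabs(ynew[i]);
                if (an > ym) ym = an;
                double sc = atol + rtol * ym;
                e /= sc;
                err += e * e;
            }
            err = sqrt(err / NST);

            if (err <= 1.0 || h_use <= 1e-12) {
                t += h_use;
                for (i = 0; i < NST; i++) y[i] = ynew[i];
                for (i = 0; i < NST; i++) if (y[i] < 0) y[i] = 0.0;
                /* a gut bolus far below error scale is spent */
                if (y[0] < 1e-9 * ymax[0]) y[0] = 0.0;
                for (i = 0; i < NST; i++)
                    if (y[i] > ymax[i]) ymax[i] = y[i];
                double fac = 0.96 * pow(err > 1e-12 ? err : 1e-12,
                                        -1.0 / 3.0);
                if (fac > 5.0) fac = 5.0;
                if (fac < 0.2) fac = 0.2;
                double h_cand = h_use * fac;
                h = clipped ? (h_cand > h ? h_cand : h) : h_cand;
            } else {
                double fac = 0.96 * pow(err, -1.0 / 3.0);
                if (fac < 0.1) fac = 0.1;
                h = h_use * fac;
            }
        }
        while (iev < nev && et[iev] <= t) {
            y[evar[iev] - 1] += eamt[iev];
            if (y[evar[iev] - 1] > ymax[evar[iev] - 1])
                ymax[evar[iev] - 1] = y[evar[iev] - 1];
            iev++;
        }
        if (tt[iout] <= t) {
            o[iout] = y[0]; o[nt + iout] = y[1]; o[2 * nt + iout] = y[2];
            o[3 * nt + iout] = y[3]; o[4 * nt + iout] = y[4];
            o[5 * nt + iout] = qss_cfil(&P, y[1]);
            iout++;
        }
    }
    UNPROTECT(1);
    return out;
}
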