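/* Three-compartment PFAS toxicokinetic model with saturable renal
 * resorption, as a deSolve compiled model.
 *
 * States (amounts in mg except Cfil in mg/L):
 *   y[0] Agut    amount in gut
 *   y[1] Aprim   amount in central (serum-equilibrated) compartment
 *   y[2] Adeep   amount in deep compartment
 *   y[3] Cfil    concentration in renal filtrate
 *   y[4] Aurine  cumulative urinary elimination (bookkeeping)
 *   y[5] Aunabs  cumulative unabsorbed gut outflow (bookkeeping sink)
 *
 * Parameters (set via initmod):
 *   p[0] ka, p[1] bioAv, p[2] k12, p[3] k21,
 *   p[4] Qfil (L/h), p[5] Free, p[6] Vc (L), p[7] Vfil (L),
 *   p[8] Tm (mg/h), p[9] Kt (mg/L)
 *
 * One forcing: oral intake rate in mg/h (piecewise linear in time).
 */
#include <R.h>
#include <math.h>

static double p[10];
static double forc[1];

void tk_initmod(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, p);
}

void tk_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void tk_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double ka = p[0], bioAv = p[1], k12 = p[2], k21 = p[3];
    const double Qfil = p[4], Free = p[5], Vc = p[6], Vfil = p[7];
    const double Tm = p[8], Kt = p[9];
    const double oral_rate = forc[0];

    const double Cprim = y[1] / Vc;
    const double gut_out = ka * y[0];
    const double filtration = Qfil * Free * Cprim;
    const double resorption = Tm * y[3] / (Kt + y[3]);

    ydot[0] = oral_rate - gut_out;
    ydot[1] = bioAv * gut_out + k21 * y[2] - k12 * y[1]
              - filtration + resorption;
    ydot[2] = k12 * y[1] - k21 * y[2];
    ydot[3] = (filtration - Qfil * y[3] - resorption) / Vfil;
    ydot[4] = Qfil * y[3];
    ydot[5] = (1.0 - bioAv) * gut_out;

    if (ip[0] > 0) yout[0] = Cprim;
}

/* Quasi-steady-state reduction: the filtrate compartment relaxes on a
 * sub-second time scale (Vfil/(Qfil + Tm/Kt) ~ 1e-6 h), so its
 * concentration is taken as the algebraic root of
 *   Qfil*Free*Cprim = Qfil*Cfil + Tm*Cfil/(Kt + Cfil),
 * leaving a non-stiff 5-state system. States:
 *   y[0] Agut, y[1] Aprim, y[2] Adeep, y[3] Aurine, y[4] Aunabs
 * Same parameter block as tk_derivs (Vfil unused).
 */
void tk_derivs_qss(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double ka = p[0], bioAv = p[1], k12 = p[2], k21 = p[3];
    const double Qfil = p[4], Free = p[5], Vc = p[6];
    const double Tm = p[8], Kt = p[9];
    const double oral_rate = forc[0];

    const double Cprim = y[1] / Vc;
    const double gut_out = ka * y[0];
    const double F = Qfil * Free * Cprim;

    /* positive root of Qfil*Cfil^2 + (Qfil*Kt + Tm - F)*Cfil - F*Kt = 0 */
    const double b = Qfil * Kt + Tm - F;
    const double disc = b * b + 4.0 * Qfil * F * Kt;
    const double Cfil = (-b + sqrt(disc)) / (2.0 * Qfil);

    ydot[0] = oral_rate - gut_out;
    ydot[1] = bioAv * gut_out + k21 * y[2] - k12 * y[1] - Qfil * Cfil;
    ydot[2] = k12 * y[1] - k21 * y[2];
    ydot[3] = Qfil * Cfil;
    ydot[4] = (1.0 - bioAv) * gut_out;

    if (ip[0] > 0) yout[0] = Cfil;
}
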