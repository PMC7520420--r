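/* Compiled ODE right-hand sides for deSolve (lsoda).
 *
 * Two models:
 *  - tgi:  transit-compartment tumor-growth-inhibition system driven either
 *          by a closed-form two-compartment plasma concentration (dose events
 *          passed in the parameter vector) or by an externally supplied
 *          forcing function.  Supports several animals integrated at once
 *          (shared drug-effect parameters, per-animal growth parameters and
 *          initial volumes) so pooled-likelihood evaluations need one solver
 *          call per arm.
 *  - tmdd: two-compartment PK with binding to a shed soluble target and
 *          first-order elimination of the drug-target complex, plus a
 *          cumulative-elimination bookkeeping state for mass-balance checks.
 *
 * Parameter vectors are padded on the R side to the fixed lengths below.
 */

#include <R.h>
#include <math.h>

#define TGI_MAXP 400
#define TGI_MAXEV 40
#define TGI_EVOFF 13          /* first event slot */
#define TGI_GROFF (13 + 3 * TGI_MAXEV) /* first per-animal growth slot: 133 */

#define TMDD_MAXP 160
#define TMDD_MAXEV 40
#define TMDD_EVOFF 10

/* ------------------------------------------------------------------ TGI -- */

static double tgi_p[TGI_MAXP];
static double tgi_forc[1];

void tgi_init(void (*odeparms)(int *, double *))
{
    int n = TGI_MAXP;
    odeparms(&n, tgi_p);
}

void tgi_forcinit(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, tgi_forc);
}

/* Central concentration (ug/mL) of a linear 2-cpt model, superposition of
 * bolus and zero-order infusion events.  alpha/beta are the fast/slow
 * exponents, k21 the peripheral-to-central rate. */
static double conc_2cpt(double t)
{
    int nev = (int) tgi_p[12];
    double Vc = tgi_p[8], a = tgi_p[9], b = tgi_p[10], k21 = tgi_p[11];
    double c = 0.0;
    int i;

    for (i = 0; i < nev; i++) {
        double t0   = tgi_p[TGI_EVOFF + 3 * i];
        double dose = tgi_p[TGI_EVOFF + 3 * i + 1];
        double dur  = tgi_p[TGI_EVOFF + 3 * i + 2];
        double s = t - t0;
        if (s < 0.0 || dose <= 0.0)
            continue;
        double D = dose * 1000.0 / Vc; /* mg/kg over mL/kg -> ug/mL */
        if (dur <= 0.0) {
            c += D * ((a - k21) * exp(-a * s) +
                      (k21 - b) * exp(-b * s)) / (a - b);
        } else {
            double R  = D / dur;
            double Fa = (a - k21) / (a * (a - b));
            double Fb = (k21 - b) / (b * (a - b));
            c += R * (Fa * (1.0 - exp(-a * s)) + Fb * (1.0 - exp(-b * s)));
            s -= dur;
            if (s > 0.0)
                c -= R * (Fa * (1.0 - exp(-a * s)) +
                          Fb * (1.0 - exp(-b * s)));
        }
    }
    return c > 0.0 ? c : 0.0;
}

void tgi_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int na = (int) tgi_p[0];
    double Vmax = tgi_p[1], tau = tgi_p[2], kkmax = tgi_p[3];
    double kc50 = tgi_p[4], hn = tgi_p[5], psi = tgi_p[6];
    int forced = tgi_p[7] > 0.5;
    double c = forced ? tgi_forc[0] : conc_2cpt(*t);
    double kkill = 0.0;
    int ia;

    if (c > 0.0) {
        double cn = pow(c, hn);
        kkill = kkmax * cn / (pow(kc50, hn) + cn);
    }

    for (ia = 0; ia < na; ia++) {
        double kgEx = tgi_p[TGI_GROFF + 2 * ia];
        double kg   = tgi_p[TGI_GROFF + 2 * ia + 1];
        double *v  = y + 4 * ia;
        double *dv = ydot + 4 * ia;
        double V1 = v[0] > 0.0 ? v[0] : 0.0;
        double V2 = v[1] > 0.0 ? v[1] : 0.0;
        double V3 = v[2] > 0.0 ? v[2] : 0.0;
        double V4 = v[3] > 0.0 ? v[3] : 0.0;
        double TV = V1 + V2 + V3 + V4;
        double den = 1.0, grow;

        if (TV > 0.0) {
            /* switching denominator in log space: x^psi overflows for
             * x ~ O(10) already at psi = 20 */
            double x = kgEx / kg * TV;
            if (x > 0.0) {
                double z = psi * log(x);
                den = (z > 30.0) ? x : exp(log1p(exp(z)) / psi);
            }
        }
        grow = kgEx * (1.0 - TV / Vmax) / den;

        dv[0] = grow * V1 - kkill * V1;
        dv[1] = kkill * V1 - V2 / tau;
        dv[2] = (V2 - V3) / tau;
        dv[3] = (V3 - V4) / tau;
    }
}

/* ----------------------------------------------------------------- TMDD -- */

static double tmdd_p[TMDD_MAXP];

void tmdd_init(void (*odeparms)(int *, double *))
{
    int n = TMDD_MAXP;
    odeparms(&n, tmdd_p);
}

void tmdd_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double CL = tmdd_p[0], Vc = tmdd_p[1], Vp = tmdd_p[2], Q = tmdd_p[3];
    double kon = tmdd_p[4], koff = tmdd_p[5];
    double kshed = tmdd_p[6], kdeg = tmdd_p[7], kelc = tmdd_p[8];
    int nev = (int) tmdd_p[9];
    double In = 0.0;
    int i;

    for (i = 0; i < nev; i++) {
        double t0   = tmdd_p[TMDD_EVOFF + 3 * i];
        double rate = tmdd_p[TMDD_EVOFF + 3 * i + 1];
        double dur  = tmdd_p[TMDD_EVOFF + 3 * i + 2];
        if (*t >= t0 && *t < t0 + dur)
            In += rate; /* nM/day into central */
    }

    {
        double CA = y[0], CP = y[1], CE = y[2], CX = y[3];
        if (CA < 0.0) CA = 0.0;
        if (CE < 0.0) CE = 0.0;
        if (CX < 0.0) CX = 0.0;
        ydot[0] = In - (CL / Vc) * CA - (Q / Vc) * CA
                  + (Q / Vp) * CP * (Vp / Vc)
                  - kon * CA * CE + koff * CX;
        ydot[1] = (Q / Vc) * CA * (Vc / Vp) - (Q / Vp) * CP;
        ydot[2] = kshed - kdeg * CE - kon * CA * CE + koff * CX;
        ydot[3] = kon * CA * CE - koff * CX - kelc * CX;
        /* cumulative drug eliminated, nmol/kg (volumes are mL/kg) */
        ydot[4] = (CL / 1000.0) * CA + kelc * CX * (Vc / 1000.0);
    }
}
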