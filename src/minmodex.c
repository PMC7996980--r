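/* Exercise-extended minimal model right-hand side for deSolve.
 *
 * States:   y[0] = G (plasma glucose, mmol/L), y[1] = X (remote insulin, 1/min)
 * Forcings: plasma insulin (mU/L), VO2 (same units as vo2_rest/vo2_max),
 *           meal glucose appearance already divided by V_G (mmol/L/min).
 * deSolve interpolates forcings linearly with constant extrapolation.
 */
#include <R.h>

static double parms[12];
static double forcs[3];

#define P1       parms[0]
#define P2       parms[1]
#define P3       parms[2]
#define GP0      parms[3]
#define E1       parms[4]
#define E2       parms[5]
#define VARIANT  parms[6]
#define TSTART   parms[7]
#define TEND     parms[8]
#define VO2REST  parms[9]
#define VO2MAX   parms[10]
#define HASSESS  parms[11]

#define INS forcs[0]
#define VO2 forcs[1]
#define RA  forcs[2]

void minmodex_initpar(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void minmodex_initforc(void (*odeforcs)(int *, double *))
{
    int n = 3;
    odeforcs(&n, forcs);
}

/* Table-driven exercise increments; zero outside the session window. */
static void inc_terms_c(double t, double *inc1, double *inc2)
{
    double pvo2 = 0.0, te, span;
    int v;

    *inc1 = 0.0;
    *inc2 = 0.0;
    if (HASSESS < 0.5 || t < TSTART || t > TEND)
        return;

    span = VO2MAX - VO2REST;
    if (span > 0.0) {
        pvo2 = (VO2 - VO2REST) / span;
        if (pvo2 < 0.0) pvo2 = 0.0;
        else if (pvo2 > 1.0) pvo2 = 1.0;
    }
    te = (t - TSTART) / 60.0;

    v = (int)(VARIANT + 0.5);
    switch (v) {
    case 1: *inc1 = E1;        *inc2 = E2;        break;
    case 2: *inc1 = 0.0;       *inc2 = E1;        break;
    case 3: *inc1 = E1;        *inc2 = 0.0;       break;
    case 4: *inc1 = E1 * pvo2; *inc2 = E2 * pvo2; break;
    case 5: *inc1 = E1 * te;   *inc2 = E2 * te;   break;
    case 6: *inc1 = E1 * pvo2; *inc2 = E2 * (pvo2 + te); break;
    }
}

void minmodex_deriv(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double inc1, inc2, G, X;

    inc_terms_c(*t, &inc1, &inc2);
    /* floor keeps the bilinear X*G term benign on degenerate draws */
    G = (y[0] < 1e-6) ? 1e-6 : y[0];
    X = y[1];

    ydot[0] = -P1 * (1.0 + inc1) * G - X * G + P1 * GP0 + RA;
    ydot[1] = -P2 * X + P3 * (1.0 + inc2) * INS;

    if (ip[0] >= 2) {
        yout[0] = inc1;
        yout[1] = inc2;
    }
}
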