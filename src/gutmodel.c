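/* Segmented gastrointestinal absorption model: pellet transit with
 * pH-triggered Weibull release, lumen/enterocyte layers in 8 absorbing
 * segments, gut CYP3A4 + P-gp efflux, hepatic first pass, two-compartment
 * systemic disposition.  Used as a deSolve compiled model; the parameter
 * vector layout must match model_parms() on the R side exactly.
 *
 * Units: amounts nmol, time h, first-order rates 1/h, P-gp Vmax nmol/h,
 * P-gp half-saturation as an enterocyte amount (nmol).
 */
#include <R.h>
#include <math.h>

#define NP 78
#define NSEG 9              /* stomach, duodenum, jej1, jej2, ile1-4, colon */
#define NABS 8              /* absorbing segments (no stomach) */

/* parameter offsets */
#define P_KS     0          /* [9] solid (pellet) transit out-rate */
#define P_KF     9          /* [9] fluid (dissolved) transit out-rate */
#define P_GOPEN 18          /* [9] coating open (segment pH > trigger pH) */
#define P_FMAX  27
#define P_ALPHA 28
#define P_BETA  29
#define P_TLAG  30
#define P_HCAP  31          /* hazard cap, 1/h */
#define P_KABS  32          /* [8] lumen -> enterocyte (or portal if bypass) */
#define P_KBASO 40          /* [8] enterocyte -> portal */
#define P_KMET  48          /* [8] enterocyte -> gut metabolite */
#define P_PGPV  56          /* [8] P-gp Vmax, nmol/h */
#define P_PGPKA 64          /* [8] P-gp half-saturation amount, nmol */
#define P_EH    72          /* hepatic first-pass extraction ratio */
#define P_KH    73          /* systemic hepatic elimination from central */
#define P_KR    74          /* renal elimination from central */
#define P_K12   75
#define P_K21   76
#define P_BYP   77          /* 1: lumen absorbs straight to portal */

/* state offsets */
#define Y_S     0           /* [9] solid */
#define Y_L     9           /* [9] dissolved in lumen */
#define Y_E    18           /* [8] enterocyte */
#define Y_AC   26
#define Y_AP   27
#define Y_GMET 28
#define Y_LMET 29
#define Y_REN  30
#define Y_FECS 31
#define Y_FECD 32
#define Y_TAU  33           /* release clock */
#define Y_ABS  34           /* [8] cumulative absorbed-to-portal by segment */

static double p[NP];

void gut_init(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

void gut_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int i, j;
    double stot = 0.0, sopen = 0.0;

    for (i = 0; i < NSEG; i++) {
        double s = y[Y_S + i] > 0.0 ? y[Y_S + i] : 0.0;
        stot += s;
        if (p[P_GOPEN + i] > 0.5) sopen += s;
    }
    /* release clock advances with the solid fraction already past its
     * trigger; stalls once essentially no solid remains */
    double w = stot > 1e-10 ? sopen / stot : 0.0;
    ydot[Y_TAU] = w;

    /* Weibull release hazard applied to remaining (100%) solid load */
    double h = 0.0;
    double te = y[Y_TAU] - p[P_TLAG];
    if (te > 0.0) {
        if (te < 1e-9) te = 1e-9;
        double tb  = pow(te, p[P_BETA]);
        double ex  = exp(-tb / p[P_ALPHA]);
        double F   = p[P_FMAX] * (1.0 - ex);
        double dF  = p[P_FMAX] * ex * p[P_BETA] * pow(te, p[P_BETA] - 1.0)
                     / p[P_ALPHA];
        double rem = 100.0 - F;
        h = (rem > 1e-9) ? dF / rem : p[P_HCAP];
        if (h > p[P_HCAP]) h = p[P_HCAP];
        if (h < 0.0) h = 0.0;
    }

    double rel[NSEG];
    for (i = 0; i < NSEG; i++)
        rel[i] = (p[P_GOPEN + i] > 0.5) ? h * y[Y_S + i] : 0.0;

    /* solid transit chain; colon exit is fecal loss of intact pellets */
    ydot[Y_S] = -p[P_KS] * y[Y_S] - rel[0];
    for (i = 1; i < NSEG; i++)
        ydot[Y_S + i] = p[P_KS + i - 1] * y[Y_S + i - 1]
                      - p[P_KS + i] * y[Y_S + i] - rel[i];
    ydot[Y_FECS] = p[P_KS + NSEG - 1] * y[Y_S + NSEG - 1];

    /* lumen: release input, fluid transit, absorption, P-gp efflux input */
    int byp = p[P_BYP] > 0.5;
    double sum_portal = 0.0, sum_met = 0.0;

    ydot[Y_L] = rel[0] - p[P_KF] * y[Y_L];
    for (i = 1; i < NSEG; i++) {
        j = i - 1;
        double Li = y[Y_L + i];
        double Ej = y[Y_E + j];
        double Epos = Ej > 0.0 ? Ej : 0.0;
        double absf = p[P_KABS + j] * Li;
        double pgp  = 0.0;
        if (p[P_PGPV + j] > 0.0)
            pgp = p[P_PGPV + j] * Epos / (p[P_PGPKA + j] + Epos);
        double portal, met;
        if (byp) {
            portal = absf;
            met = 0.0;
            ydot[Y_E + j] = 0.0;
        } else {
            portal = p[P_KBASO + j] * Ej;
            met    = p[P_KMET + j] * Ej;
            ydot[Y_E + j] = absf - portal - met - pgp;
        }
        ydot[Y_L + i] = rel[i] + p[P_KF + i - 1] * y[Y_L + i - 1]
                      - p[P_KF + i] * Li - absf + (byp ? 0.0 : pgp);
        ydot[Y_ABS + j] = portal;
        sum_portal += portal;
        sum_met    += met;
    }
    ydot[Y_FECD] = p[P_KF + NSEG - 1] * y[Y_L + NSEG - 1];

    /* first pass, then two-compartment disposition */
    double Ac = y[Y_AC], Ap = y[Y_AP];
    ydot[Y_AC] = (1.0 - p[P_EH]) * sum_portal
               - (p[P_KH] + p[P_KR] + p[P_K12]) * Ac + p[P_K21] * Ap;
    ydot[Y_AP] = p[P_K12] * Ac - p[P_K21] * Ap;
    ydot[Y_GMET] = sum_met;
    ydot[Y_LMET] = p[P_EH] * sum_portal + p[P_KH] * Ac;
    ydot[Y_REN]  = p[P_KR] * Ac;
}
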