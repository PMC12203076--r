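/* Compiled derivative, root and (delta-linear) companion functions for the
 * anammox isotope mass-balance model, in the deSolve compiled-model style.
 *
 * State vector (14):
 *   y[0]  A     NH4+ concentration (mmol-N L-1)
 *   y[1]  B     NO2- concentration
 *   y[2]  C     NO3- concentration
 *   y[3]  A15   15N amount in NH4+  (A * xA)
 *   y[4]  B15   15N amount in NO2-
 *   y[5]  C15   15N amount in NO3-
 *   y[6]  B18   18O amount in NO2-  (2B * yB; two O atoms per N)
 *   y[7]  C18   18O amount in NO3-  (3C * yC; three O atoms per N)
 *   y[8]  Nrem  cumulative N removed to N2
 *   y[9]  N15rem  cumulative 15N removed to N2
 *   y[10] O18nir  cumulative 18O removed via NO2- reduction
 *   y[11] O18exch cumulative net 18O gained by NO2- from water exchange
 *   y[12] O18w    cumulative 18O incorporated from water into NO3-
 *   y[13] O18rel  cumulative 18O released in the backward-flux branch
 *
 * Parameters (15), see amx_initmod ordering.
 */
#include <R.h>

static double parms[15];
#define F_AMO   parms[0]   /* zero-order NH4+ -> N2 flux            */
#define F_NIR   parms[1]   /* zero-order NO2- -> N2 flux            */
#define F_NXR   parms[2]   /* zero-order NO2- -> NO3- flux          */
#define A15AMO  parms[3]   /* alpha = 1 + e/1000 for each effect    */
#define A15NIR  parms[4]
#define A15NXR  parms[5]
#define A18NIR  parms[6]
#define A18NXR  parms[7]
#define A18H2O  parms[8]
#define KEQ     parms[9]   /* total exchange rate k_abio + k_AMX    */
#define YEQ     parms[10]  /* equilibrium 18O atom fraction of NO2- */
#define R18W    parms[11]  /* 18O/16O ratio of the medium water     */
#define PHI     parms[12]  /* backward flux / NO2- oxidation flux   */
#define PIN     parms[13]  /* >0.5: pin NO2- 18O fraction at YPIN   */
#define YPIN    parms[14]

void amx_initmod(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

static double hfun(double r)     { return r / (1.0 + r); }
static double ratio_of(double x) { return x / (1.0 - x); }

void amx_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double A = y[0], B = y[1], C = y[2];
    double on   = (A > 1e-12 && B > 1e-12) ? 1.0 : 0.0;
    double fam  = on * F_AMO;
    double fnir = on * F_NIR;
    double fnxr = on * F_NXR;

    double xA = (A > 1e-12) ? y[3] / A : 0.0;
    double xB = (B > 1e-12) ? y[4] / B : 0.0;
    double xC = (C > 1e-12) ? y[5] / C : 0.0;
    double yB = (B > 1e-12) ? y[6] / (2.0 * B) : 0.0;
    double yC = (C > 1e-12) ? y[7] / (3.0 * C) : 0.0;

    double rA   = ratio_of(xA);
    double rB   = ratio_of(xB);
    double r18B = (PIN > 0.5) ? ratio_of(YPIN) : ratio_of(yB);

    double hAMO   = hfun(rA / A15AMO);
    double hNIR   = hfun(rB / A15NIR);
    double hNXR   = hfun(rB / A15NXR);
    double h18NIR = hfun(r18B / A18NIR);
    double h18NXR = hfun(r18B / A18NXR);
    double h18W   = hfun(R18W / A18H2O);

    double back = PHI * fnxr;
    double exch = (B > 1e-12) ? 2.0 * B * KEQ * (YEQ - yB) : 0.0;

    ydot[0] = -fam;
    ydot[1] = -(fnir + fnxr) + back;
    ydot[2] = fnxr - back;
    ydot[3] = -fam * hAMO;
    ydot[4] = -fnir * hNIR - fnxr * hNXR + back * xC;
    ydot[5] = fnxr * hNXR - back * xC;
    if (PIN > 0.5) {
        /* hold the NO2- bulk 18O fraction at the pinned value */
        ydot[6] = 2.0 * ydot[1] * YPIN;
    } else {
        ydot[6] = -2.0 * fnir * h18NIR - 2.0 * fnxr * h18NXR
                  + exch + 2.0 * back * yC;
    }
    ydot[7] = 2.0 * fnxr * h18NXR + fnxr * h18W - 3.0 * back * yC;

    ydot[8]  = fam + fnir;
    ydot[9]  = fam * hAMO + fnir * hNIR;
    ydot[10] = 2.0 * fnir * h18NIR;
    ydot[11] = exch;
    ydot[12] = fnxr * h18W;
    ydot[13] = back * yC;
}

/* terminal root: NO2- exhaustion */
void amx_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    gout[0] = y[1];
}
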