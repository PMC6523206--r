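/* Whole-body large-molecule PBPK right-hand side.
 *
 * Compartments per organ: vascular plasma, endothelial endosomal space
 * (free and FcRn-bound drug), interstitial space (free and CD95L-bound
 * drug). Venous and arterial plasma pools close the circulation; the lung
 * is perfused in series (venous -> lung -> arterial), all other organs in
 * parallel from the arterial pool, with the splanchnic organs draining
 * through the liver (portal vein). Transcapillary exchange follows the
 * two-pore formalism (convection with pore-specific reflection
 * coefficients plus Patlak-corrected diffusion); interstitial drug returns
 * to the venous pool with lymph. Unbound endosomal drug is degraded
 * (lysosomal pathway); FcRn-bound drug is recycled to plasma/interstitium.
 * First-order ASGR elimination acts on liver interstitial drug; optional
 * glomerular filtration acts on kidney vascular drug.
 *
 * Units: amounts nmol, time h, volumes L, flows L/h, concentrations
 * nmol/L. Parameter and state layouts are mirrored in R/model.R.
 */
#include <R.h>
#include <math.h>

#define NORG 15
#define NPAR (14 + 14 * NORG)
#define NEQ  (2 + 5 * NORG + 5)

#define I_LUNG   0
#define I_KIDNEY 3
#define I_LIVER  4
/* portal organs: spleen, stomach, small/large intestine, pancreas */
static const int PORTAL[5] = {5, 6, 7, 8, 9};

static double parms[NPAR];

#define P_INF   parms[0]
#define P_VVEN  parms[1]
#define P_VART  parms[2]
#define P_KDEG  parms[3]
#define P_KREC  parms[4]
#define P_FR    parms[5]
#define P_KASS  parms[6]
#define P_KOFFR parms[7]
#define P_KONT  parms[8]
#define P_KOFFT parms[9]
#define P_KASGR parms[10]
#define P_TVEN  parms[11]
#define P_TART  parms[12]
#define P_GFRCL parms[13]

#define A_Q    (parms + 14)
#define A_LF   (parms + 14 + 1 * NORG)
#define A_VPL  (parms + 14 + 2 * NORG)
#define A_VIS  (parms + 14 + 3 * NORG)
#define A_VE   (parms + 14 + 4 * NORG)
#define A_JS   (parms + 14 + 5 * NORG)
#define A_JL   (parms + 14 + 6 * NORG)
#define A_SIGS (parms + 14 + 7 * NORG)
#define A_SIGL (parms + 14 + 8 * NORG)
#define A_PSS  (parms + 14 + 9 * NORG)
#define A_PSL  (parms + 14 + 10 * NORG)
#define A_CLUP (parms + 14 + 11 * NORG)
#define A_TTOT (parms + 14 + 12 * NORG)
#define A_RTOT (parms + 14 + 13 * NORG)

/* state offsets */
#define Y_VEN 0
#define Y_ART 1
#define Y_PL(i)  (2 + (i))
#define Y_E(i)   (2 + NORG + (i))
#define Y_EF(i)  (2 + 2 * NORG + (i))
#define Y_IS(i)  (2 + 3 * NORG + (i))
#define Y_IST(i) (2 + 4 * NORG + (i))
#define Y_VT   (2 + 5 * NORG)
#define Y_AT   (2 + 5 * NORG + 1)
#define Y_CLYS (2 + 5 * NORG + 2)
#define Y_CASG (2 + 5 * NORG + 3)
#define Y_CREN (2 + 5 * NORG + 4)

void asun_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

/* Patlak flux through one pore class (plasma -> interstitium positive) */
static double pore_flux(double J, double sig, double PS,
                        double Cp, double Ci)
{
    double Jeff = J * (1.0 - sig);
    if (PS <= 0.0)
        return (Jeff >= 0.0) ? Jeff * Cp : Jeff * Ci;
    double Pe = Jeff / PS;
    double aPe = fabs(Pe);
    if (aPe < 1e-6)
        return PS * (Cp - Ci) + 0.5 * Jeff * (Cp + Ci);
    if (Pe > 500.0)
        return Jeff * Cp;
    if (Pe < -500.0)
        return Jeff * Ci;
    double em = exp(-Pe);
    return Jeff * (Cp - Ci * em) / (-expm1(-Pe));
}

void asun_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int i, k;
    double Cpl[NORG], Cis[NORG];
    double Cven = y[Y_VEN] / P_VVEN;
    double Cart = y[Y_ART] / P_VART;

    for (i = 0; i < NEQ; i++) ydot[i] = 0.0;
    for (i = 0; i < NORG; i++) {
        Cpl[i] = y[Y_PL(i)] / A_VPL[i];
        Cis[i] = y[Y_IS(i)] / A_VIS[i];
    }

    /* portal inflow into liver vascular space */
    double liver_in = 0.0, q_liver_in = A_Q[I_LIVER];
    for (k = 0; k < 5; k++) {
        int j = PORTAL[k];
        double qout = A_Q[j] - A_LF[j];
        liver_in += qout * Cpl[j];
        q_liver_in += qout;
    }

    double dven = P_INF - A_Q[I_LUNG] * Cven;
    double dart = (A_Q[I_LUNG] - A_LF[I_LUNG]) * Cpl[I_LUNG];

    for (i = 0; i < NORG; i++) {
        double inflow, outflow_q;
        int is_portal = 0;
        for (k = 0; k < 5; k++) if (PORTAL[k] == i) is_portal = 1;

        if (i == I_LUNG) {
            inflow = A_Q[i] * Cven;
            outflow_q = A_Q[i] - A_LF[i]; /* to arterial pool */
        } else if (i == I_LIVER) {
            inflow = A_Q[i] * Cart + liver_in;
            outflow_q = q_liver_in - A_LF[i];
            dven += outflow_q * Cpl[i];
            dart -= A_Q[i] * Cart;
        } else {
            inflow = A_Q[i] * Cart;
            outflow_q = A_Q[i] - A_LF[i];
            dart -= A_Q[i] * Cart;
            if (!is_portal)
                dven += outflow_q * Cpl[i];
            /* portal organ outflow already routed into the liver */
        }

        double flux = pore_flux(A_JS[i], A_SIGS[i], A_PSS[i], Cpl[i], Cis[i])
                    + pore_flux(A_JL[i], A_SIGL[i], A_PSL[i], Cpl[i], Cis[i]);
        double up_pl = A_CLUP[i] * Cpl[i];
        double up_is = A_CLUP[i] * Cis[i];
        double rec = P_KREC * y[Y_EF(i)];
        double rfree = A_RTOT[i] - y[Y_EF(i)];
        if (rfree < 0.0) rfree = 0.0;
        double bind_r = P_KASS * y[Y_E(i)] * rfree / A_VE[i];
        double unbind_r = P_KOFFR * y[Y_EF(i)];
        double deg = P_KDEG * y[Y_E(i)];
        double lymph = A_LF[i] * Cis[i];

        ydot[Y_PL(i)] = inflow - outflow_q * Cpl[i] - flux - up_pl
                        + P_FR * rec;
        ydot[Y_E(i)] = up_pl + up_is - deg - bind_r + unbind_r;
        ydot[Y_EF(i)] = bind_r - unbind_r - rec;

        double bind_t = 0.0, unbind_t = 0.0;
        if (A_TTOT[i] > 0.0) {
            double tfree = A_TTOT[i] - y[Y_IST(i)];
            if (tfree < 0.0) tfree = 0.0;
            bind_t = P_KONT * y[Y_IS(i)] * tfree / A_VIS[i];
            unbind_t = P_KOFFT * y[Y_IST(i)];
            ydot[Y_IST(i)] = bind_t - unbind_t;
        }
        ydot[Y_IS(i)] = flux - lymph - up_is + (1.0 - P_FR) * rec
                        - bind_t + unbind_t;

        dven += lymph;
        ydot[Y_CLYS] += deg;

        /* ASGR on hepatocytes: the sinusoidal endothelium is fenestrated,
         * so both the liver vascular plasma and the interstitial (space of
         * Disse) pools are accessible to the receptor */
        if (i == I_LIVER && P_KASGR > 0.0) {
            double asgr_is = P_KASGR * y[Y_IS(i)];
            double asgr_pl = P_KASGR * y[Y_PL(i)];
            ydot[Y_IS(i)] -= asgr_is;
            ydot[Y_PL(i)] -= asgr_pl;
            ydot[Y_CASG] += asgr_is + asgr_pl;
        }
        if (i == I_KIDNEY && P_GFRCL > 0.0) {
            double ren = P_GFRCL * Cpl[i];
            ydot[Y_PL(i)] -= ren;
            ydot[Y_CREN] += ren;
        }
    }

    /* CD95L on blood cells: binding species in the venous/arterial pools */
    if (P_TVEN > 0.0) {
        double tf = P_TVEN - y[Y_VT];
        if (tf < 0.0) tf = 0.0;
        double b = P_KONT * y[Y_VEN] * tf / P_VVEN;
        double u = P_KOFFT * y[Y_VT];
        dven += u - b;
        ydot[Y_VT] = b - u;
    }
    if (P_TART > 0.0) {
        double tf = P_TART - y[Y_AT];
        if (tf < 0.0) tf = 0.0;
        double b = P_KONT * y[Y_ART] * tf / P_VART;
        double u = P_KOFFT * y[Y_AT];
        dart += u - b;
        ydot[Y_AT] = b - u;
    }

    ydot[Y_VEN] = dven;
    ydot[Y_ART] = dart;
}
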