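/* Whole-body PBPK right-hand side for irinotecan (CPT-11) and four
 * metabolites (SN-38, SN-38G, NPC, APC), used through deSolve's
 * compiled-model interface.
 *
 * State: 5 species x 23 compartments, species-major: y[s*23 + c].
 * Compartments 0..15 circulatory (venous, artery, lung, heart, brain,
 * muscle, adipose, skin, bone, kidney, spleen, pancreas, stomach, S.I.,
 * L.I., liver), 16..18 biliary transit, 19 S.I. lumen, 20 L.I. lumen,
 * 21 urine, 22 feces.  Amounts are ug per kg body weight; volumes ml/kg,
 * flows and clearances ml/min/kg, rate constants /min, so concentrations
 * are ug/ml and time is min.
 *
 * Parameter vector (length 138), set via the initializer:
 *   [0..15]    circulatory volumes (state order)
 *   [16..30]   flows: lung, heart, brain, muscle, adipose, skin, bone,
 *              kidney, spleen, pancreas, stomach, S.I., L.I.,
 *              liver_total, liver_artery
 *   [31..135]  the 105 drug parameters in parameter-id order
 *   [136]      zero-order infusion rate of CPT-11 into venous blood
 *              (ug/kg/min); the R wrapper integrates piecewise and zeroes
 *              this after the infusion stops
 *   [137]      infusion stop time (min); rate applies for t < stop
 */

#include <R.h>

#define NPARMS 138
static double p[NPARMS];

#define NSP 5
#define NCOMP 23

/* circulatory compartment indices */
#define VEN 0
#define ART 1
#define LUNG 2
#define KID 9
#define SPL 10
#define LIV 15
/* elimination chain */
#define B1 16
#define B2 17
#define B3 18
#define SIL 19
#define LIL 20
#define UR 21
#define FE 22

/* flow vector indices */
#define QLUNG 0
#define QKID 7
#define QLIVTOT 13
#define QLIVART 14

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *V = p;            /* 16 volumes  */
    const double *Q = p + 16;       /* 15 flows    */
    const double *dp = p + 31;      /* 105 drug parameters */
    const double rate = p[136];
    const double tstop = p[137];

    /* drug-parameter blocks (0-based within dp) */
    const double *kp = dp;          /* kp[(organ)*5 + s], organ 0=lung..13=liver */
    const double *clr = dp + 70;
    const double *clbile = dp + 75;
    const double cl_ces1 = dp[80], cl_ces2 = dp[81];
    const double cl_3a4_1 = dp[82], cl_3a4_2 = dp[83], cl_ugt = dp[84];
    const double *kbile = dp + 85;
    const double *ka = dp + 90;
    const double *kli = dp + 95;
    const double *kfec = dp + 100;

    double cliv[NSP];   /* liver outflow (emergent plasma) concentration */
    int s, c;

    /* liver outflow concentrations first: metabolic terms couple species */
    for (s = 0; s < NSP; s++) {
        const double *A = y + s * NCOMP;
        cliv[s] = A[LIV] / (V[LIV] * kp[13 * 5 + s]);
    }

    for (s = 0; s < NSP; s++) {
        const double *A = y + s * NCOMP;
        double *dA = ydot + s * NCOMP;
        double cven = A[VEN] / V[VEN];
        double cart = A[ART] / V[ART];
        double cout[16];    /* organ venous-equilibrated outflow conc */
        double venret = 0.0, artout = 0.0, livin;

        for (c = LUNG; c < LIV; c++)
            cout[c] = A[c] / (V[c] * kp[(c - 2) * 5 + s]);
        cout[LIV] = cliv[s];

        /* lung in series between the blood pools */
        dA[LUNG] = Q[QLUNG] * (cven - cout[LUNG]);

        /* systemic organs heart..kidney: artery in, venous pool out */
        for (c = 3; c <= KID; c++) {
            double q = Q[c - 2];
            dA[c] = q * (cart - cout[c]);
            venret += q * cout[c];
            artout += q;
        }
        /* renal elimination from kidney outflow plasma */
        {
            double el = clr[s] * cout[KID];
            dA[KID] -= el;
            dA[UR] = el;
        }

        /* splanchnic organs: artery in, liver inlet out */
        livin = Q[QLIVART] * cart;
        artout += Q[QLIVART];
        for (c = SPL; c < LIV; c++) {
            double q = Q[c - 2];
            dA[c] = q * (cart - cout[c]);
            livin += q * cout[c];
            artout += q;
        }

        /* liver: perfusion + biliary excretion (metabolism added below) */
        dA[LIV] = livin - Q[QLIVTOT] * cliv[s] - clbile[s] * cliv[s];
        venret += Q[QLIVTOT] * cliv[s];

        /* blood pools */
        dA[VEN] = venret - Q[QLUNG] * cven;
        dA[ART] = Q[QLUNG] * cout[LUNG] - artout * cart;

        /* biliary transit chain and gut lumen */
        dA[B1] = clbile[s] * cliv[s] - kbile[s] * A[B1];
        dA[B2] = kbile[s] * (A[B1] - A[B2]);
        dA[B3] = kbile[s] * (A[B2] - A[B3]);
        dA[SIL] = kbile[s] * A[B3] - (ka[s] + kli[s]) * A[SIL];
        dA[LIL] = kli[s] * A[SIL] - kfec[s] * A[LIL];
        dA[FE] = kfec[s] * A[LIL];
    }

    /* intestinal reabsorption into the liver (enterohepatic return);
     * lumenal SN-38G is deconjugated by gut-flora beta-glucuronidase, so
     * its absorbed flux enters the liver as SN-38 */
    for (s = 0; s < NSP; s++) {
        double flux = ka[s] * y[s * NCOMP + SIL];
        int target = (s == 2) ? 1 : s;
        ydot[target * NCOMP + LIV] += flux;
    }

    /* hepatic metabolism, 1:1 in dose-equivalent mass:
     * CPT-11 -> SN-38 (CES1 arm of CES2), CPT-11 -> APC (CYP3A4 #1),
     * CPT-11 -> NPC (CYP3A4 #2), NPC -> SN-38 (CES2), SN-38 -> SN-38G (UGT) */
    {
        double f_ces1 = cl_ces1 * cliv[0];
        double f_3a41 = cl_3a4_1 * cliv[0];
        double f_3a42 = cl_3a4_2 * cliv[0];
        double f_ces2 = cl_ces2 * cliv[3];
        double f_ugt = cl_ugt * cliv[1];

        ydot[0 * NCOMP + LIV] -= f_ces1 + f_3a41 + f_3a42;
        ydot[1 * NCOMP + LIV] += f_ces1 + f_ces2 - f_ugt;
        ydot[2 * NCOMP + LIV] += f_ugt;
        ydot[3 * NCOMP + LIV] += f_3a42 - f_ces2;
        ydot[4 * NCOMP + LIV] += f_3a41;
    }

    /* zero-order infusion of CPT-11 into venous blood */
    if (rate > 0.0 && *t < tstop)
        ydot[0 * NCOMP + VEN] += rate;
}
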