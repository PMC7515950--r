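/* Minimal-PBPK right-hand side for deSolve's compiled-model interface.
 *
 * State layout (NC compounds, 13 states each, then 7 enzyme pools):
 *   per compound c: [0] gut lumen (mg), [1] central (mg), [2] peripheral (mg),
 *                   [3..12] cumulative eliminated mass per pathway (mg):
 *                   pathways 1..7 = metabolism by enzyme pool e (pool 2 = gut
 *                   CYP3A4), 8 = renal, 9 = biliary, 10 = additional systemic.
 *   then: active enzyme fraction per pool (dimensionless, baseline 1).
 *
 * Enzyme pools: 1 CYP3A4_liver, 2 CYP3A4_gut, 3 CYP2C19, 4 CYP2D6,
 *               5 CYP2C8, 6 CYP2C9, 7 HLM_additional.
 *
 * Parameter vector (fixed length NPAR, padded with zeros):
 *   p[0]  n_compounds
 *   p[1]  hepatic blood flow Qh (L/h)
 *   p[2]  enterocyte (villous) blood flow Qent (L/h)
 *   p[3..9] kdeg per enzyme pool (1/h)
 *   per compound c, block of 56 at 10 + 56*c:
 *     0 ka (1/h)            1 Vc (L)        2 Vsac (L)      3 Qsac (L/h)
 *     4 fu (plasma)         5 B/P ratio     6 MW (g/mol)
 *     7 fg_mode (0 fixed / 1 dynamic gut CYP3A4)
 *     8 fg_fixed            9 CLint_gut (L/h, whole gut, baseline)
 *    10 fu_gut             11 CL_renal     12 CL_biliary   13 CL_additional
 *    14..20 whole-liver intrinsic clearance per enzyme pool (L/h; slot for
 *           pool 2 unused)
 *    21..55 per enzyme pool: Ki_rev (uM), kinact (1/h), KI_app (uM),
 *           Ind_max (fold-1 max), Ind_C50 (uM)
 *
 * All interaction constants are on unbound concentrations: liver-inlet
 * unbound plasma for liver pools, enterocyte concentration for the gut pool.
 * A zero Ki/kinact/IndMax switches the corresponding mechanism off.
 */

#include <R.h>
#include <math.h>

#define NCMAX   3
#define NENZ    7
#define NSTC    13          /* states per compound */
#define CBLK    56          /* parameters per compound */
#define NPAR    (10 + NCMAX * CBLK)

static double p[NPAR];

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int nc = (int)(p[0] + 0.5);
    double Qh = p[1], Qent = p[2];
    const double *kdeg = p + 3;
    int eoff = NSTC * nc;            /* enzyme state offset */

    double Ient[NCMAX];              /* unbound enterocyte conc, uM */
    double Iliv[NCMAX];              /* unbound liver-inlet plasma conc, uM */
    double portal[NCMAX];            /* absorption flux to portal blood mg/h */
    double gutmet[NCMAX];

    /* pass 1: enterocyte inhibitor concentrations (needed for every fg) */
    for (int c = 0; c < nc; c++) {
        const double *q = p + 10 + CBLK * c;
        double Agut = pos(y[NSTC * c + 0]);
        double abs_rate = q[0] * Agut;                  /* mg/h */
        double centc = (Qent > 0.0) ? abs_rate / Qent : 0.0;  /* mg/L */
        Ient[c] = q[10] * centc * 1000.0 / q[6];        /* uM, unbound */
    }

    /* pass 2: gut extraction and portal flux per compound */
    for (int c = 0; c < nc; c++) {
        const double *q = p + 10 + CBLK * c;
        double Agut = pos(y[NSTC * c + 0]);
        double abs_rate = q[0] * Agut;
        double fg;
        if (q[7] < 0.5) {
            fg = q[8];
        } else {
            double inh = 1.0;
            for (int k = 0; k < nc; k++) {
                double ki = p[10 + CBLK * k + 21 + 5 * 1 + 0]; /* pool 2 Ki */
                if (ki > 0.0) inh += Ient[k] / ki;
            }
            double Eg = y[eoff + 1];                    /* gut pool state */
            double clg = q[9] * Eg / inh;
            fg = (Qent > 0.0) ? Qent / (Qent + q[10] * clg) : 1.0;
        }
        portal[c] = abs_rate * fg;
        gutmet[c] = abs_rate * (1.0 - fg);
    }

    /* pass 3: liver-inlet unbound concentrations */
    for (int c = 0; c < nc; c++) {
        const double *q = p + 10 + CBLK * c;
        double Ccen = pos(y[NSTC * c + 1]) / q[1];      /* plasma mg/L */
        double CinB = Ccen * q[5] + ((Qh > 0.0) ? portal[c] / Qh : 0.0);
        Iliv[c] = q[4] * (CinB / q[5]) * 1000.0 / q[6];
    }

    /* pass 4: drug mass balances */
    for (int c = 0; c < nc; c++) {
        const double *q = p + 10 + CBLK * c;
        int s = NSTC * c;
        double Agut = pos(y[s + 0]);
        double Ccen = y[s + 1] / q[1];
        double Csac = (q[2] > 0.0) ? y[s + 2] / q[2] : 0.0;
        double CcenB = Ccen * q[5];
        double CinB = CcenB + ((Qh > 0.0) ? portal[c] / Qh : 0.0);
        double fuB = q[4] / q[5];

        /* effective per-enzyme hepatic intrinsic clearances */
        double cl_eff[NENZ], cl_sum = 0.0;
        for (int e = 0; e < NENZ; e++) {
            double cl = q[14 + e];
            if (e == 1 || cl <= 0.0) { cl_eff[e] = 0.0; continue; }
            double inh = 1.0;
            for (int k = 0; k < nc; k++) {
                double ki = p[10 + CBLK * k + 21 + 5 * e + 0];
                if (ki > 0.0) inh += Iliv[k] / ki;
            }
            cl_eff[e] = cl * y[eoff + e] / inh;
            cl_sum += cl_eff[e];
        }
        double S = fuB * cl_sum;
        double Eh = (Qh + S > 0.0) ? S / (Qh + S) : 0.0;
        double hep = Eh * Qh * CinB;                     /* mg/h */

        double other = (q[11] + q[12] + q[13]) * Ccen;   /* renal+bil+add */

        ydot[s + 0] = -q[0] * Agut;
        ydot[s + 1] = (1.0 - Eh) * Qh * CinB - Qh * CcenB - other
                      - q[3] * (Ccen - Csac);
        ydot[s + 2] = q[3] * (Ccen - Csac);

        for (int e = 0; e < NENZ; e++)
            ydot[s + 3 + e] = (cl_sum > 0.0) ? hep * cl_eff[e] / cl_sum : 0.0;
        ydot[s + 3 + 1] = gutmet[c];                     /* gut CYP3A4 path */
        ydot[s + 10] = q[11] * Ccen;
        ydot[s + 11] = q[12] * Ccen;
        ydot[s + 12] = q[13] * Ccen;
    }

    /* pass 5: enzyme turnover */
    for (int e = 0; e < NENZ; e++) {
        double inact = 0.0, ind = 0.0;
        for (int c = 0; c < nc; c++) {
            const double *r = p + 10 + CBLK * c + 21 + 5 * e;
            double I = (e == 1) ? Ient[c] : Iliv[c];
            if (r[1] > 0.0 && r[2] > 0.0) inact += r[1] * I / (r[2] + I);
            if (r[3] > 0.0 && r[4] > 0.0) ind += r[3] * I / (r[4] + I);
        }
        double E = y[eoff + e];
        ydot[eoff + e] = kdeg[e] * (1.0 + ind) - E * (kdeg[e] + inact);
    }
}
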