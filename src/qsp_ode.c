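/* Five-species CAR-T / tumor ODE system for deSolve.
 *
 * States: y[0..3] = T_N, T_CM, T_EM, T_Eff (cells/uL), y[4] = CD19+ MTV (mL).
 * Units are deliberately mixed (cells/uL for T cells, mL for tumor); the
 * expansion rate Vmax1 carries (cells/uL)/day/mL so each term is consistent.
 *
 * parms layout (see .qsp_c_parms in R/ode.R, which must stay in sync):
 *  0 Vmax1   1 KM1    2 kp1    3 kp2    4 kp3
 *  5 k12     6 k23    7 k34
 *  8 ke1     9 ke2   10 ke3   11 ke4
 * 12..15 Vmax5_1..Vmax5_4 (individual scale)
 * 16 KM5   17 k5    18 K0
 * 19 denom_flag: 0 = T-cell concentration in the expansion denominator
 *                (selected model), 1 = tumor volume in the denominator
 *                (explored alternative, kept as a switch).
 */
#include <R.h>

static double parms[20];
#define N_PARMS 20

void qsp_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void qsp_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double TN = y[0], TCM = y[1], TEM = y[2], TEFF = y[3], CD19 = y[4];
    double Vmax1 = parms[0], KM1 = parms[1];
    double kp1 = parms[2], kp2 = parms[3], kp3 = parms[4];
    double k12 = parms[5], k23 = parms[6], k34 = parms[7];
    double ke1 = parms[8], ke2 = parms[9], ke3 = parms[10], ke4 = parms[11];
    double KM5 = parms[16], k5 = parms[17], K0 = parms[18];
    int tumor_denom = parms[19] != 0.0;

    /* solver iterates may undershoot 0 slightly; rate terms use the
       clamped state so transient excursions cannot feed back */
    double tn = TN > 0 ? TN : 0, tcm = TCM > 0 ? TCM : 0;
    double tem = TEM > 0 ? TEM : 0, teff = TEFF > 0 ? TEFF : 0;
    double cd = CD19 > 0 ? CD19 : 0;

    double exp_n, exp_cm, exp_em;
    if (tumor_denom) {
        double f = Vmax1 * cd / (KM1 + cd);
        exp_n = f * tn; exp_cm = f * tcm; exp_em = f * tem;
    } else {
        exp_n  = Vmax1 * cd * tn  / (KM1 + tn);
        exp_cm = Vmax1 * cd * tcm / (KM1 + tcm);
        exp_em = Vmax1 * cd * tem / (KM1 + tem);
    }

    double kill_frac = cd / (KM5 + cd);
    double kill = (parms[12] * tn + parms[13] * tcm +
                   parms[14] * tem + parms[15] * teff) * kill_frac;

    ydot[0] = exp_n + kp1 * tn - k12 * tn - ke1 * tn;
    ydot[1] = exp_cm + kp2 * tcm + k12 * tn - k23 * tcm - ke2 * tcm;
    ydot[2] = exp_em + kp3 * tem + k23 * tcm - k34 * tem - ke3 * tem;
    ydot[3] = k34 * tem - ke4 * teff;
    ydot[4] = k5 * (1.0 - cd / K0) * cd - kill;
}
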