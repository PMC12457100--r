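/* Compiled right-hand side of the tumor-macrophage system for deSolve.
 *
 * State order: T, P1, P2, A, TD, MD.
 * Parameter vector (see simulate_population()):
 *  0 rho_T   1 rho_P   2 rho_A   3 mu_eff  4 lam_eff
 *  5 K_lam   6 phi     7 xi      8 tau_M   9 K
 * 10 v_T    11 v_M    12 tau_TD 13 tau_MD 14 phi_D
 * 15 conv_form (0 = saturated, 1 = michaelis)
 * 16 clamp_recruitment (0/1)
 * 17 ir_active (0/1)
 * 18 v_guard (freeze volume; growth reverses at K, so states beyond the
 *    guard are unreachable for legitimate dynamics)
 */

#include <R.h>
#include <math.h>

static double parms[19];

void gtw_initmod(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, parms);
}

void gtw_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double T = y[0], P1 = y[1], P2 = y[2], A = y[3];
    const double TD = y[4], MD = y[5];
    const double P = P1 + P2;
    const double V = parms[10] * (T + TD) + parms[11] * (P + A + MD);

    if (V > parms[18]) {
        for (int i = 0; i < 6; i++) ydot[i] = 0.0;
        return;
    }

    const double lnKV = (V > 0.0) ? log(parms[9] / V) : 0.0;
    double conv;
    if (parms[15] == 0.0)
        conv = parms[4] * A * T * parms[5] / (parms[5] + T);
    else
        conv = parms[4] * A * T / (parms[5] + T);

    const double dT = parms[0] * T * P * lnKV - parms[3] * T * A;
    double recruit = dT;
    if (parms[16] != 0.0 && recruit < 0.0) recruit = 0.0;

    const double inv_tau = 1.0 / parms[8];
    ydot[0] = dT;
    ydot[1] = parms[1] * P1 * T * lnKV + conv - P1 * inv_tau;
    ydot[2] = parms[1] * P2 * T * lnKV + parms[6] * T - P2 * inv_tau;
    ydot[3] = parms[2] * A * T * lnKV - conv + parms[7] * recruit
              - A * inv_tau;
    if (parms[17] != 0.0) ydot[3] += parms[14] * (TD + MD);
    ydot[4] = -TD / parms[12];
    ydot[5] = -MD / parms[13];
}
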