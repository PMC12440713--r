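/* Autoinduction one-compartment model, right-hand side for deSolve.
 *
 * Integrates N independent copies of the system that differ only in the
 * elimination rate constant ke = CL/V.  State layout (concentration units,
 * mg/L) per copy i: y[3i] depot, y[3i+1] central, y[3i+2] enzyme pool.
 *
 *   dCd/dt  = -ka * Cd
 *   dCc/dt  =  ka * Cd - ke_i * Enz * Cc
 *   dEnz/dt =  Kenz - Kenz * (1 - Cc/(Cc + IC50)) * Enz
 *
 * Doses are handled as deSolve events adding dose/V to the depot states.
 *
 * Parameter vector (fixed length PB_PARMS_LEN so the initializer knows the
 * count): [0] N, [1] ka, [2] Kenz, [3] IC50, [4..4+N-1] ke values.
 */
#include <R.h>

#define PB_MAXSYS   1024
#define PB_PARMS_LEN (4 + PB_MAXSYS)

static double parms[PB_PARMS_LEN];

void pb_init(void (*odeparms)(int *, double *))
{
    int n = PB_PARMS_LEN;
    odeparms(&n, parms);
}

void pb_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int    N    = (int) parms[0];
    double ka   = parms[1];
    double kenz = parms[2];
    double ic50 = parms[3];
    int    i;

    for (i = 0; i < N; i++) {
        double cd  = y[3 * i];
        double cc  = y[3 * i + 1];
        double enz = y[3 * i + 2];
        double ke  = parms[4 + i];
        double inh = (cc > 0.0) ? cc / (cc + ic50) : 0.0;

        ydot[3 * i]     = -ka * cd;
        ydot[3 * i + 1] =  ka * cd - ke * enz * cc;
        ydot[3 * i + 2] =  kenz - kenz * (1.0 - inh) * enz;
    }
}
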