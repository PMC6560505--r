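/* Right-hand side of the two-compartment model with parallel linear and
 * Michaelis-Menten elimination from the central compartment, in the form
 * deSolve expects for compiled models.
 *
 * States: A1 (central amount, mg), A2 (peripheral amount, mg).
 * Parameters (already body-weight scaled where applicable):
 *   0 CLlin (L/h), 1 Vmax (mg/h), 2 Km (mg/L), 3 V1 (L), 4 V2 (L), 5 Q (L/h)
 */
#include <R.h>

static double parms_par2[6];

void init_par2(void (*odeparms)(int *, double *))
{
    int N = 6;
    odeparms(&N, parms_par2);
}

void derivs_par2(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double CLlin = parms_par2[0], Vmax = parms_par2[1], Km = parms_par2[2];
    double V1 = parms_par2[3], V2 = parms_par2[4], Q = parms_par2[5];
    double C = y[0] / V1;
    double mm = Vmax * C / (Km + C);
    ydot[0] = -(CLlin / V1) * y[0] - mm - (Q / V1) * y[0] + (Q / V2) * y[1];
    ydot[1] = (Q / V1) * y[0] - (Q / V2) * y[1];
}
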