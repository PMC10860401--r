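/* Compiled right-hand side for the plant-population epidemic model,
 * used through deSolve's compiled-model interface for speed in the
 * likelihood-heavy diagnostics (profiling, ARE replicates).
 *
 * States: S (susceptible stems), I (infected), R (removed).
 * parms:  b, kappa, lambda0, mu, d, removal-flag.
 * removal-flag != 0 adds the -d*I removal term to dI/dt (the model
 * variant in which N' = b*(kappa - N) decouples); 0 keeps the
 * cumulative-infection form.
 */
#include <R.h>
#include <math.h>

static double parms[6];

void epi_initmod(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void epi_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double b = parms[0], kappa = parms[1], lambda0 = parms[2];
    double mu = parms[3], d = parms[4], removal = parms[5];
    double N = y[0] + y[1] + y[2];
    double infection = lambda0 * exp(-mu * (*t)) * y[0];

    ydot[0] = b * (kappa - N) - infection;
    ydot[1] = infection - (removal != 0.0 ? d * y[1] : 0.0);
    ydot[2] = d * y[1];
}
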