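/* Right-hand sides of the batch-fermentation kinetic models, in the
 * deSolve compiled-model convention (initfunc copies the parameter
 * vector, derivs fills ydot).  Kept in C because the identification
 * routines integrate these systems tens of thousands of times.
 *
 * Parameter slots (see R/simulate.R):
 *   0 mu_m  1 P_i  2 S_m  3 S_i  4 alpha  5 beta
 *   6 k_mu  7 k_alpha  8 theta0  9 T_cs  10 u   (4-state model only)
 */
#include <R.h>

static double p[11];

void ferm_init_fund(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, p);
}

void ferm_init_temp(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, p);
}

/* specific growth rate: mu * (1 - x3/Pi) * x2 / (Sm + x2 + x2^2/Si) */
static double growth(double x2, double x3, double mu, double Pi,
                     double Sm, double Si)
{
    return mu * (1.0 - x3 / Pi) * x2 / (Sm + x2 + x2 * x2 / Si);
}

void ferm_deriv_fund(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double f = growth(y[1], y[2], p[0], p[1], p[2], p[3]);
    ydot[0] = f * y[0];
    ydot[1] = -ydot[0];
    ydot[2] = (p[4] * f + p[5]) * y[0];
}

void ferm_deriv_temp(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double mu = p[0] * (1.0 + p[6] * (y[3] - p[8]));
    double al = p[4] * (1.0 + p[7] * (y[3] - p[8]));
    double f = growth(y[1], y[2], mu, p[1], p[2], p[3]);
    ydot[0] = f * y[0];
    ydot[1] = -ydot[0];
    ydot[2] = (al * f + p[5]) * y[0];
    ydot[3] = (p[10] - y[3]) / p[9];
}
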