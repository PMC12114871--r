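/* Compiled right-hand side of the tumor-growth-inhibition system for use
 * with deSolve. The drug concentration enters as a forcing function
 * (linearly interpolated by the solver from a table supplied from R).
 *
 * States: y[0] proliferating volume X1, y[1..3] transit death compartments.
 * Parameters: lambda0, lambda1, phi, keff (= K * (1 + alpha * flag)), k1.
 */
#include <R.h>
#include <math.h>

static double parms[5];
static double forc[1];

#define lambda0 parms[0]
#define lambda1 parms[1]
#define phi     parms[2]
#define keff    parms[3]
#define k1      parms[4]
#define conc    forc[0]

void tgi_initmod(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms);
}

void tgi_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void tgi_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double x1 = y[0] > 0 ? y[0] : 0;
    double growth = 0;
    if (x1 > 0) {
        /* (1 + r^phi)^(1/phi) evaluated on the log scale so phi = 20
         * cannot overflow for any realistic volume */
        double lr = phi * log(lambda0 * x1 / lambda1);
        double lse = lr > 0 ? lr + log1p(exp(-lr)) : log1p(exp(lr));
        growth = lambda0 * x1 / exp(lse / phi);
    }
    double c = conc > 0 ? conc : 0;
    double kill = keff * c * x1;
    ydot[0] = growth - kill;
    ydot[1] = kill - k1 * y[1];
    ydot[2] = k1 * (y[1] - y[2]);
    ydot[3] = k1 * (y[2] - y[3]);
}
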