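/* Compiled right-hand side of the biomimetic-oxidation ODE system, for use
 * through deSolve's compiled-model interface.  State layout (must match the
 * R side): fetpps, fetpps_star, tbuooh, substrate, metabolite_cat,
 * metabolite_noncat, fetpps_dead.  Parameters: k1, k2, k3, k4, delta.
 * k4 = 0 reduces the extended variant to the standard one. */
#include <R.h>

static double parms[5];
#define K1    parms[0]
#define K2    parms[1]
#define K3    parms[2]
#define K4    parms[3]
#define DELTA parms[4]

void mimox_init(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms);
}

void mimox_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double f  = y[0];   /* FeTPPS        */
    double fs = y[1];   /* FeTPPS*       */
    double x  = y[2];   /* tBuOOH        */
    double s  = y[3];   /* substrate     */

    double act = K1 * f * x;    /* activation            */
    double ox  = K2 * s * fs;   /* catalytic oxidation   */
    double deg = K3 * f * x;    /* catalyst degradation  */
    double nc  = K4 * s * x;    /* non-catalytic channel */

    ydot[0] = -act - deg + ox;
    ydot[1] =  act - ox;
    ydot[2] = -act - deg - nc + DELTA;
    ydot[3] = -ox - nc;
    ydot[4] =  ox;              /* cumulative catalytic product     */
    ydot[5] =  nc;              /* cumulative non-catalytic product */
    ydot[6] =  deg;             /* cumulative degraded catalyst     */
}
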