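/* Mass-action right-hand side of the bacterial-luciferase single-turnover
 * scheme, in the compiled-model form expected by deSolve.
 *
 * State (M):  y[0]=L   free luciferase
 *             y[1]=F   free reduced flavin (FMNH2)
 *             y[2]=I1  Intermediate I   (L.FMNH2)
 *             y[3]=I2  Intermediate II  (peroxyflavin)
 *             y[4]=I2A Intermediate IIA (peroxyflavin-aldehyde)
 *             y[5]=A   free decanal
 *             y[6]=Fox oxidized-flavin sink
 *             y[7]=P   product sink (acid + FMN released with light)
 *
 * Parameters: k1 (1/(M s)), k2 (1/s, pseudo-first-order in O2), k3 (1/(M s)),
 *             km3 (1/s), k4 (1/s), kd (1/s), kdd (1/s).
 */
#include <R.h>

static double parms[7];
#define k1  parms[0]
#define k2  parms[1]
#define k3  parms[2]
#define km3 parms[3]
#define k4  parms[4]
#define kd  parms[5]
#define kdd parms[6]

void lux_initmod(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void lux_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double bindLF = k1 * y[0] * y[1];
    double bindA  = k3 * y[3] * y[5];

    ydot[0] = -bindLF + kdd * y[3] + k4 * y[4];       /* L   */
    ydot[1] = -bindLF - kd * y[1];                    /* F   */
    ydot[2] =  bindLF - k2 * y[2];                    /* I1  */
    ydot[3] =  k2 * y[2] - bindA + km3 * y[4] - kdd * y[3];  /* I2  */
    ydot[4] =  bindA - km3 * y[4] - k4 * y[4];        /* I2A */
    ydot[5] = -bindA + km3 * y[4];                    /* A   */
    ydot[6] =  kd * y[1] + kdd * y[3];                /* Fox */
    ydot[7] =  k4 * y[4];                             /* P   */
}
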