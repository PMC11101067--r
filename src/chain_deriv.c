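/* Right-hand side of the six-mass impaction chain, in the deSolve
 * compiled-model convention (initializer, forcing initializer, derivs).
 *
 * Coordinates: one axis, positive in the impaction (downward) direction.
 * States are displacements (y[0..5]) and velocities (y[6..11]) of the
 * impactor, load cell, tip, head, stem and tissue nodes, measured as
 * deviations from the gravitational static equilibrium.  Element forces are
 * evaluated in absolute (compressive) terms by adding the static preload
 * compressions, so gravity and preloads cancel exactly at t = 0.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 30

static double p[N_PARMS];
static double forc[1]; /* mallet force pulse, linearly interpolated */

/* parameter layout (all SI):
 *  0..5   masses: impactor, load cell, tip, head, stem, tissue [kg]
 *  6, 7   impactor spring stiffness, damping
 *  8, 9   load-cell spring stiffness, damping
 * 10,11   hard-stop full stiffness, full damping
 * 12      hard-stop transition depth delta [m]
 * 13      bilateral-contact flag (>0.5: plain linear spring-damper)
 * 14,15   mu_static, mu_kinetic
 * 16,17   junction normal-force constant N0 [N], quadratic factor beta [N/m^2]
 * 18,19   stem spring stiffness, damping
 * 20,21   tissue spring stiffness, damping
 * 22      gravity [m/s^2]
 * 23      Karnopp stick velocity threshold [m/s]
 * 24..29  static preloads: impactor spring compression, load-cell spring
 *         compression, hard-stop penetration p0, insertion depth d0,
 *         stem spring compression, tissue spring compression [m]
 */

void chain_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void chain_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void chain_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double g = p[22];

    /* serial spring-damper elements (compressive force, upper on lower) */
    double F_imp = p[6] * (p[24] + y[0] - y[1]) + p[7] * (y[6] - y[7]);
    double F_lc  = p[8] * (p[25] + y[1] - y[2]) + p[9] * (y[7] - y[8]);
    double F_stem = p[18] * (p[28] + y[4] - y[5]) + p[19] * (y[10] - y[11]);
    double F_tis  = p[20] * (p[29] + y[5]) + p[21] * y[11];

    /* one-sided hard stop between tip and head, stiffness (and damping)
     * ramping linearly over the transition depth; never tensile */
    double pen = p[26] + y[2] - y[3];
    double vpen = y[8] - y[9];
    double F_stop;
    if (p[13] > 0.5) {
        F_stop = p[10] * pen + p[11] * vpen; /* bilateral variant */
    } else if (pen <= 0.0 || p[10] <= 0.0) {
        F_stop = 0.0;
    } else {
        double r = pen / p[12];
        if (r > 1.0) r = 1.0;
        F_stop = p[10] * r * pen + p[11] * r * vpen;
        if (F_stop < 0.0) F_stop = 0.0;
    }

    /* taper junction: Karnopp stick-slip with N(d) = N0 + beta d^2.
     * d < 0 means the head has lifted off the taper: free junction. */
    double d = p[27] + y[3] - y[4];
    double vrel = y[9] - y[10];
    double Fh = p[3] * g + F_stop;   /* non-friction force on head  */
    double Fs = p[4] * g - F_stem;   /* non-friction force on stem  */
    double f = 0.0, Nd = 0.0;
    if (d >= 0.0) {
        Nd = p[16] + p[17] * d * d;
        double veps = p[23];
        double flim_s = p[14] * Nd;
        double fstick = (p[4] * Fh - p[3] * Fs) / (p[3] + p[4]);
        /* stick: demand clamped to the static cone */
        double f_st = fstick;
        if (f_st > flim_s) f_st = flim_s;
        if (f_st < -flim_s) f_st = -flim_s;
        /* slip: kinetic friction opposing relative sliding */
        double f_sl = p[15] * Nd * (vrel > 0.0 ? 1.0 : -1.0);
        double av = fabs(vrel);
        if (av < veps) {
            f = f_st;
        } else if (av < 2.0 * veps) {
            /* linear blend keeps the force continuous across breakaway */
            double w = (av - veps) / veps;
            f = (1.0 - w) * f_st + w * f_sl;
        } else {
            f = f_sl;
        }
    }

    ydot[0] = y[6];
    ydot[1] = y[7];
    ydot[2] = y[8];
    ydot[3] = y[9];
    ydot[4] = y[10];
    ydot[5] = y[11];
    ydot[6]  = (forc[0] + p[0] * g - F_imp) / p[0];
    ydot[7]  = (p[1] * g + F_imp - F_lc) / p[1];
    ydot[8]  = (p[2] * g + F_lc - F_stop) / p[2];
    ydot[9]  = (Fh - f) / p[3];
    ydot[10] = (Fs + f) / p[4];
    ydot[11] = (p[5] * g + F_stem - F_tis) / p[5];

    if (*ip >= 6) {
        yout[0] = F_lc - p[8] * p[25];     /* impactor PoM, preload removed */
        yout[1] = F_stem - p[18] * p[28];  /* stem PoM, preload removed */
        yout[2] = d > 0.0 ? d : 0.0;       /* insertion depth */
        yout[3] = F_stop;                  /* contact force */
        yout[4] = f;                       /* transmitted friction force */
        yout[5] = Nd;                      /* junction normal force */
    }
}
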