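/* Right-hand side of the coupled bundle/control-parameter system, in the
 * deSolve compiled-model convention.  One call integrates one forcing
 * segment: the forcing structure (additive variant, parametric level and
 * active flag) is constant within a segment, so the only time dependence
 * inside a segment is the smooth rotating force F*exp(i*wp*t).
 *
 * State: y[0] = x (bundle position), y[1] = Im z, y[2] = mu.
 *
 * parms layout (see R/integrate.R, .segment_parms):
 *  0 mu_c   1 omega  2 b_re  3 b_im  4 tau  5 gamma  6 alpha
 *  7 fa_type (0 = constant complex force, 1 = rotating sinusoid)
 *  8 fa_re  9 fa_im  10 F_amp  11 omega_prime
 *  12 fp_value  13 fp_active (0/1)  14 hold_mu (0/1)
 */
#include <R.h>
#include <math.h>

static double parms[15];

void hopf_init(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

void hopf_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double mu_c = parms[0], omega = parms[1];
    const double b_re = parms[2], b_im = parms[3];
    const double tau = parms[4], gamma = parms[5], alpha = parms[6];
    const double fa_type = parms[7];
    double fa_re = parms[8], fa_im = parms[9];
    const double F_amp = parms[10], wp = parms[11];
    const double fp_value = parms[12], fp_active = parms[13];
    const double hold_mu = parms[14];

    const double x = y[0], yy = y[1], mu = y[2];
    const double r2 = x * x + yy * yy;

    if (fa_type > 0.5) {        /* F * exp(i * wp * t) */
        fa_re = F_amp * cos(wp * *t);
        fa_im = F_amp * sin(wp * *t);
    }

    /* linear coefficient: mu_c + mu when parametric forcing is inactive,
     * mu_c + Fp when active (Fp replaces mu, not mu_c) */
    const double c = mu_c + (fp_active > 0.5 ? fp_value : mu);

    ydot[0] = c * x - omega * yy + r2 * (b_re * x - b_im * yy) + fa_re;
    ydot[1] = c * yy + omega * x + r2 * (b_im * x + b_re * yy) + fa_im;
    ydot[2] = (hold_mu > 0.5) ? 0.0
        : -mu / tau - alpha / (1.0 + exp(-gamma * x));
}
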