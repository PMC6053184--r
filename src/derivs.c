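/* Compiled right-hand side of the six-class community model, in the
 * standard deSolve compiled-model form. Window-gated quantities (switching,
 * hatching, winter amplitude, growth rates) are constant within an
 * integration segment and are passed in as part of the parameter vector;
 * the integrator restarts at every window edge, so only the smooth seasonal
 * multiplier is evaluated here.
 *
 * Parameter layout (28 doubles):
 *   0..5   r_j          growth rates for this segment
 *   6      q            Q10 temperature factor
 *   7      eps_base     baseline seasonal amplitude
 *   8      eps_f1       effective amplitude for class 3 in this segment
 *   9      s_now        switching rate (0 outside sexual windows)
 *   10..15 h_j          hatching rates (0 outside the hatching window)
 *   16     m            sexual mortality
 *   17     K            carrying capacity
 *   18     k            ephippia per encounter
 *   19     f            ephippia per day
 *   20     c            within-class mating fraction
 *   21..26 e_j          empty-ephippium fractions
 *   27     bracket_class use class-specific sigma in the density bracket
 *
 * State layout (18 doubles): A1..A6, S1..S6, E1..E6.
 */
#include <R.h>
#include <math.h>

#define NPAR 28
static double parms[NPAR];

void dlh_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

void dlh_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *r = parms;
    const double q = parms[6];
    const double eps_base = parms[7];
    const double eps_f1 = parms[8];
    const double s_now = parms[9];
    const double *h = parms + 10;
    const double m = parms[16];
    const double K = parms[17];
    const double k = parms[18];
    const double f = parms[19];
    const double c = parms[20];
    const double *e = parms + 21;
    const int bracket_class = (int) parms[27];

    const double co = cos(2.0 * M_PI * (*t) / 365.0);
    const double sig_base = (1.0 - eps_base * co) / (1.0 + eps_base);
    const double sig_f1 = (1.0 - eps_f1 * co) / (1.0 + eps_f1);

    const double *A = y;
    const double *S = y + 6;
    const double *E = y + 12;

    double total = 0.0;
    for (int j = 0; j < 6; j++)
        total += A[j] + S[j];

    const double S1 = S[0], S2 = S[1], S3 = S[2];
    const double T = S1 + S2 + S3;
    double phi[6] = {0.0, 0.0, 0.0, 0.0, 0.0, 0.0};
    if (T > 0.0) {
        phi[0] = S1 * (S1 + c * (T - S1)) / (2.0 * T);
        phi[1] = S2 * (S2 + c * (T - S2)) / (2.0 * T);
        phi[2] = (1.0 - c) * S1 * S2 / T;
        phi[3] = (1.0 - c) * S1 * S3 / T;
        phi[4] = (1.0 - c) * S2 * S3 / T;
        phi[5] = S3 * (S3 + c * (S1 + S2)) / (2.0 * T);
    }

    for (int j = 0; j < 6; j++) {
        const double sig_j = (j == 2) ? sig_f1 : sig_base;
        const double sig_den = bracket_class ? sig_j : sig_base;
        const double growth =
            q * r[j] * sig_j * A[j] * (1.0 - total / (sig_den * K));
        ydot[j] = growth - s_now * A[j] + 2.0 * h[j] * E[j];
        ydot[6 + j] = s_now * A[j] - m * S[j];
        ydot[12 + j] = (1.0 - e[j]) * f * k * phi[j] - h[j] * E[j];
    }
}
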