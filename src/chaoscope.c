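/* Compiled right-hand sides for the chemostat community model, the
 * competitive generalised Lotka-Volterra model and the Lorenz system,
 * in the calling convention used by deSolve's compiled-model interface.
 *
 * A "dual" mode stacks two copies of a system plus one accumulator state
 * used by the dual-orbit maximal-Lyapunov-exponent estimator: the orbit
 * separation is logged and renormalised by a timed event function, so a
 * whole Lyapunov run is a single solver call.
 */
#include <R.h>
#include <math.h>

#define NPARMS 128

/* global layout */
#define P_FAMILY   0   /* 0 community, 1 gLV, 2 Lorenz */
#define P_DUAL     1   /* 0 single orbit, 1 dual orbit + accumulator */
#define P_M        2   /* state dimension of one orbit */
#define P_DELTA0   3   /* dual-orbit renormalisation distance */
#define P_EXT      4   /* extinction threshold for the root function */
#define P_NSTRAIN  5   /* number of leading state components checked for extinction */
#define P_RAMP_ON  6
#define P_RAMP_IDX 7   /* 0-based index into the parameter vector */
#define P_RAMP_NK  8
#define P_RAMP_T   9   /* 8 knot times ... */
#define P_RAMP_V   17  /* ... then 8 knot values */
#define FSTART     25  /* family-specific block */

/* community block offsets (relative to FSTART); fixed slots for up to
 * 3 strains, 3 bacteriocins, 2 QS species */
#define C_NN    0
#define C_NB    1
#define C_NA    2
#define C_D     3
#define C_S0    4
#define C_K     5
#define C_GAM   6
#define C_CN    7
#define C_CB    8
#define C_CA    9
#define C_KW    10
#define C_NW    11
#define C_WMAX  12
#define C_MU    13  /* 3 */
#define C_SENS  16  /* 3 */
#define C_KA    19  /* 2 */
#define C_EA    21  /* 3x2 strain-major */
#define C_KBMAX 27  /* 3 */
#define C_NZ    30  /* 3 */
#define C_KAB   33  /* 3 */
#define C_REG   36  /* 3 */
#define C_MODE  39  /* 3 */
#define C_EB    42  /* 3x3 strain-major */

/* gLV block offsets */
#define G_N     0
#define G_R     1   /* 6 */
#define G_ALPHA 7   /* 6x6 row-major */

/* Lorenz block offsets */
#define L_SIGMA 0
#define L_RHO   1
#define L_BETA  2

static double parms[NPARMS];

void chaoscope_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double ramp_value(double t)
{
    int nk = (int) parms[P_RAMP_NK];
    int i;
    if (nk < 1) return parms[(int) parms[P_RAMP_IDX]];
    if (t <= parms[P_RAMP_T]) return parms[P_RAMP_V];
    if (t >= parms[P_RAMP_T + nk - 1]) return parms[P_RAMP_V + nk - 1];
    for (i = 1; i < nk; i++) {
        double t0 = parms[P_RAMP_T + i - 1], t1 = parms[P_RAMP_T + i];
        if (t <= t1) {
            double w = (t - t0) / (t1 - t0);
            return parms[P_RAMP_V + i - 1] * (1.0 - w) + parms[P_RAMP_V + i] * w;
        }
    }
    return parms[P_RAMP_V + nk - 1];
}

static double hillpos(double x, double k, double n)
{
    double xn, kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n); kn = pow(k, n);
    return xn / (kn + xn);
}

/* one-orbit derivative for the active family; y and ydot have length m */
static void rhs_one(double t, double *y, double *ydot)
{
    int fam = (int) parms[P_FAMILY];

    if (parms[P_RAMP_ON] > 0.5)
        parms[(int) parms[P_RAMP_IDX]] = ramp_value(t);

    if (fam == 0) {
        const double *cp = parms + FSTART;
        int nN = (int) cp[C_NN], nB = (int) cp[C_NB], nA = (int) cp[C_NA];
        double D = cp[C_D], S0 = cp[C_S0], K = cp[C_K], gam = cp[C_GAM];
        double CN = cp[C_CN], CB = cp[C_CB], CA = cp[C_CA];
        double Kw = cp[C_KW], nw = cp[C_NW], wmax = cp[C_WMAX];
        double S = y[nN] > 0.0 ? y[nN] : 0.0;
        double mu[3], kb[3], dS;
        int x, z, a;

        for (z = 0; z < nB; z++) {
            int reg = (int) cp[C_REG + z] - 1;        /* QS index, 0-based */
            double Aprime = y[nN + 1 + nB + reg] * CA; /* molar */
            double h = hillpos(Aprime, cp[C_KAB + z], cp[C_NZ + z]);
            kb[z] = cp[C_KBMAX + z] * (cp[C_MODE + z] > 0.5 ? (1.0 - h) : h);
        }
        for (x = 0; x < nN; x++)
            mu[x] = cp[C_MU + x] * S / (K + S);

        dS = D * (S0 - S);
        for (x = 0; x < nN; x++) {
            double N = y[x];
            double kill = 0.0;
            int sz = (int) cp[C_SENS + x];
            if (sz > 0) {
                double Bprime = y[nN + sz] * CB;      /* molar */
                kill = wmax * hillpos(Bprime, Kw, nw);
            }
            ydot[x] = N * (mu[x] - kill - D);
            dS -= mu[x] * (N * CN) / gam;
        }
        ydot[nN] = dS;
        for (z = 0; z < nB; z++) {
            double prod = 0.0;
            for (x = 0; x < nN; x++)
                if (cp[C_EB + 3 * x + z] > 0.5 && y[x] > 0.0)
                    prod += kb[z] * y[x] * CN;
            ydot[nN + 1 + z] = prod / CB - D * y[nN + 1 + z];
        }
        for (a = 0; a < nA; a++) {
            double prod = 0.0;
            for (x = 0; x < nN; x++)
                if (cp[C_EA + 2 * x + a] > 0.5 && y[x] > 0.0)
                    prod += cp[C_KA + a] * y[x] * CN;
            ydot[nN + 1 + nB + a] = prod / CA - D * y[nN + 1 + nB + a];
        }
    } else if (fam == 1) {
        const double *gp = parms + FSTART;
        int n = (int) gp[G_N], i, j;
        for (i = 0; i < n; i++) {
            double s = 0.0;
            for (j = 0; j < n; j++)
                s += gp[G_ALPHA + 6 * i + j] * y[j];
            ydot[i] = gp[G_R + i] * y[i] * (1.0 - s);
        }
    } else if (fam == 2) {
        double s = parms[FSTART + L_SIGMA], r = parms[FSTART + L_RHO],
               b = parms[FSTART + L_BETA];
        ydot[0] = s * (y[1] - y[0]);
        ydot[1] = y[0] * (r - y[2]) - y[1];
        ydot[2] = y[0] * y[1] - b * y[2];
    } else {            /* fam 3: uniform linear decay, exact lambda1 */
        double k = parms[FSTART];
        int m = (int) parms[P_M], i;
        for (i = 0; i < m; i++) ydot[i] = -k * y[i];
    }
}

void chaoscope_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    if (parms[P_DUAL] > 0.5) {
        int m = (int) parms[P_M];
        rhs_one(*t, y, ydot);
        rhs_one(*t, y + m, ydot + m);
        ydot[2 * m] = 0.0;   /* running log-separation sum */
    } else {
        rhs_one(*t, y, ydot);
    }
}

/* terminal root: any monitored component falls to the extinction threshold */
void chaoscope_root(int *neq, double *t, double *y, int *ng, double *gout,
                    double *out, int *ip)
{
    int ns = (int) parms[P_NSTRAIN];
    double thr = parms[P_EXT];
    double g = 1.0e30;
    int i;
    for (i = 0; i < ns; i++)
        if (y[i] < g) g = y[i];
    if (parms[P_DUAL] > 0.5) {
        int m = (int) parms[P_M];
        for (i = 0; i < ns; i++)
            if (y[m + i] < g) g = y[m + i];
    }
    gout[0] = g - thr;
}

/* timed event: log current separation, renormalise companion orbit */
void chaoscope_event(int *n, double *t, double *y)
{
    int m = (int) parms[P_M];
    double d0 = parms[P_DELTA0];
    double d1 = 0.0, sc;
    int i;
    for (i = 0; i < m; i++) {
        double d = y[m + i] - y[i];
        d1 += d * d;
    }
    d1 = sqrt(d1);
    if (d1 <= 0.0) {          /* degenerate: re-seed the perturbation */
        y[m] = y[0] + d0;
        for (i = 1; i < m; i++) y[m + i] = y[i];
        return;
    }
    y[2 * m] += log2(d1 / d0);
    sc = d0 / d1;
    for (i = 0; i < m; i++)
        y[m + i] = y[i] + sc * (y[m + i] - y[i]);
}
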