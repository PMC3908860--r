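/* Right-hand sides for the four-dimensional bursting neuron and for
 * inhibitory chains of such neurons, in the form expected by deSolve's
 * compiled-model interface.
 *
 * Units: volts, seconds, nA, nS, nF (nS * V = nA; nA / nF * s = V).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* ---- single neuron ----------------------------------------------------
 * parms layout (19 doubles):
 *  0 theta_K2   1 theta_h   2 I_pol     3 tau_mh    4 tau_K2
 *  5 tau_hNa    6 C         7 g_Na      8 g_K2      9 g_h
 * 10 g_leak    11 E_Na     12 E_K      13 E_h      14 E_leak
 * 15 pulse_on  16 pulse_off 17 pulse_amp 18 freeze_mK2
 * state: y = (V, h_Na, m_K2, m_h)
 */
#define NP_NEURON 19
static double pn[NP_NEURON];

void bw_neuron_init(void (*odeparms)(int *, double *))
{
    int n = NP_NEURON;
    odeparms(&n, pn);
}

static R_INLINE double boltz(double k, double off, double V)
{
    return 1.0 / (1.0 + exp(k * (V + off)));
}

/* hyperpolarization-activated gate: double-exponential steady state */
static R_INLINE double mh_inf(double V, double theta_h)
{
    return 1.0 / (1.0 + 2.0 * exp(180.0 * (V + theta_h))
                      + exp(500.0 * (V + theta_h)));
}

static void neuron_rhs(const double *p, double t, const double *y,
                       double *ydot)
{
    double V = y[0], hNa = y[1], mK2 = y[2], mh = y[3];
    double th_K2 = p[0], th_h = p[1];
    double Iext = (t >= p[15] && t < p[16]) ? p[17] : 0.0;

    double mNa  = boltz(-150.0, 0.0305, V);
    double hNai = boltz( 500.0, 0.0325, V);
    double mK2i = boltz( -83.0, th_K2, V);
    double mhi  = mh_inf(V, th_h);

    double INa   = p[7] * mNa * mNa * mNa * hNa * (V - p[11]);
    double IK2   = p[8] * mK2 * mK2 * (V - p[12]);
    double Ih    = p[9] * mh * mh * (V - p[13]);
    double Ileak = p[10] * (V - p[14]);

    ydot[0] = (-INa - IK2 - Ih - Ileak + p[2] + Iext) / p[6];
    ydot[1] = (hNai - hNa) / p[5];
    ydot[2] = (p[18] > 0.5) ? 0.0 : (mK2i - mK2) / p[4];
    ydot[3] = (mhi - mh) / p[3];
}

void bw_neuron_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    neuron_rhs(pn, *t, y, ydot);
}

/* ---- chain network ----------------------------------------------------
 * parms layout:
 *  0 ncell, 1..15 as neuron parms 0..14 (shared by all cells),
 * 16 E_syn  17 syn_slope  18 syn_thresh  19 tau_syn,
 * 20 .. : weight matrix padded to a fixed 16 x 16 block, w[i*16 + j] =
 *    weight of the synapse from cell j onto cell i (nS).
 * state: per cell (V, h_Na, m_K2, m_h, s), cell-major; s is the
 * presynaptic activation variable of that cell's output synapses.
 */
#define BW_NCELL_MAX 16
#define NP_CHAIN (20 + BW_NCELL_MAX * BW_NCELL_MAX)
static double pc[NP_CHAIN];

void bw_chain_init(void (*odeparms)(int *, double *))
{
    int n = NP_CHAIN;
    odeparms(&n, pc);
}

void bw_chain_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    int ncell = (int) (pc[0] + 0.5);
    const double *w = pc + 20;
    double Esyn = pc[16], kslope = pc[17], thr = pc[18], tau_s = pc[19];
    /* re-use the single-neuron kernel through a shifted view of parms */
    double psingle[NP_NEURON];
    for (int k = 0; k < 15; k++) psingle[k] = pc[1 + k];
    psingle[15] = 1e300; psingle[16] = 1e300; psingle[17] = 0.0;
    psingle[18] = 0.0;

    for (int i = 0; i < ncell; i++) {
        const double *yi = y + 5 * i;
        double *di = ydot + 5 * i;
        neuron_rhs(psingle, *t, yi, di);
        /* synaptic input: sum_j w(j->i) * s_j * (V_i - E_syn) */
        double Isyn = 0.0;
        for (int j = 0; j < ncell; j++) {
            double wij = w[i * BW_NCELL_MAX + j];
            if (wij > 0.0)
                Isyn += wij * y[5 * j + 4] * (yi[0] - Esyn);
        }
        di[0] -= Isyn / psingle[6];
        /* presynaptic activation of cell i's output */
        double sinf = 1.0 / (1.0 + exp(-kslope * (yi[0] - thr)));
        di[4] = (sinf - yi[4]) / tau_s;
    }
}

static const R_CMethodDef cMethods[] = {
    {"bw_neuron_derivs", (DL_FUNC) &bw_neuron_derivs, 6},
    {"bw_chain_derivs",  (DL_FUNC) &bw_chain_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_burstwave(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
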