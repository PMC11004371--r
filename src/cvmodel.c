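/* Closed-loop lumped-parameter cardiovascular model: compiled right-hand
 * side for deSolve.
 *
 * State vector (15):
 *   y[0..3]  chamber volumes, ml: LA, LV, RA, RV
 *   y[4..14] compartment volumes, ml: aortic_arch, systemic_artery,
 *            coronary, cerebral, skeletal_muscle, splanchnic,
 *            extrasplanchnic, systemic_vein, thoracic_vein,
 *            pulmonary_artery, pulmonary_vein
 *
 * Parameter vector (65 doubles) is packed by .pack_parms() on the R side;
 * the layout here and there must stay in lockstep.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 65
static double parms[N_PARMS];

#define HR        parms[0]   /* bpm */
#define FFR_GAIN  parms[1]   /* force-frequency gain on E_max */
#define ATR_ADV   parms[2]   /* atrial activation lead, s */
#define SYS_K     parms[3]   /* systole duration = SYS_K*sqrt(period), s */
#define P_FLOOR   parms[4]   /* chamber pressure floor, mmHg */
#define EMAX(i)   parms[5 + (i)]
#define EMIN(i)   parms[9 + (i)]
#define V0CH(i)   parms[13 + (i)]
#define ATR_SC    parms[17]  /* atrial systole-duration scale */
#define CC(j)     parms[18 + (j)]   /* compliances, ml/mmHg */
#define VU(j)     parms[29 + (j)]   /* unstressed volumes, ml */
#define R_MV      parms[40]
#define R_AV      parms[41]
#define R_TC      parms[42]
#define R_PU      parms[43]
#define R_AA_OUT  parms[44]  /* aortic arch -> systemic artery */
#define R_IN(k)   parms[45 + (k)]   /* systemic artery -> distal k */
#define R_OUT(k)  parms[50 + (k)]   /* distal k -> systemic vein */
#define R_SV_OUT  parms[55]  /* systemic vein -> thoracic vein */
#define R_TV_OUT  parms[56]  /* thoracic vein -> RA (VCO site) */
#define R_PA_OUT  parms[57]
#define R_PV_OUT  parms[58]
#define VCO_START parms[59]
#define VCO_RAMP  parms[60]
#define VCO_MULT  parms[61]
#define ACT_PEAK  parms[62]  /* fraction of systole at peak elastance */
#define ACT_RISE1 parms[63]  /* activation reached by end of fast phase */
#define VCO_LIN   parms[64]  /* 1 = linear ramp profile, 0 = geometric */

void cv_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* Normalized activation in [0,1]: fast raised-cosine rise to ACT_RISE1 over
 * the first 15% of the rise window (short isovolumic contraction, sets
 * dP/dt_max), linear climb to 1 at tp (sustained ejection), raised-cosine
 * relaxation until the end of systole.  Systole duration follows
 * SYS_K*sqrt(period), capped at 0.66*period so diastole survives pacing. */
static double activation(double tau, double period, double sysk)
{
    double d = sysk * sqrt(period);
    if (d > 0.66 * period) d = 0.66 * period;
    double tp = ACT_PEAK * d;
    double a1 = ACT_RISE1;
    double t1 = 0.15 * tp;
    if (tau < 0.0) tau += period;
    if (tau < t1) return a1 * 0.5 * (1.0 - cos(M_PI * tau / t1));
    if (tau < tp) return a1 + (1.0 - a1) * (tau - t1) / (tp - t1);
    if (tau < d) return 0.5 * (1.0 + cos(M_PI * (tau - tp) / (d - tp)));
    return 0.0;
}

static double elastance(double t, double period, double emax, double emin,
                        double onset, double sysk)
{
    double tau = fmod(t - onset, period);
    if (tau < 0.0) tau += period;
    return emin + (emax - emin) * activation(tau, period, sysk);
}

/* ideal diode valve */
static double vflow(double pu, double pd, double r)
{
    double dp = pu - pd;
    return dp > 0.0 ? dp / r : 0.0;
}

void cv_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double period = 60.0 / HR;
    double g = 1.0 + FFR_GAIN * (HR - 80.0) / 80.0;
    double pch[4], pc[11];
    int i;

    double ela[4];
    ela[0] = elastance(*t, period, EMAX(0), EMIN(0), -ATR_ADV, SYS_K * ATR_SC);
    ela[1] = elastance(*t, period, g * EMAX(1), EMIN(1), 0.0, SYS_K);
    ela[2] = elastance(*t, period, EMAX(2), EMIN(2), -ATR_ADV, SYS_K * ATR_SC);
    ela[3] = elastance(*t, period, g * EMAX(3), EMIN(3), 0.0, SYS_K);
    for (i = 0; i < 4; i++) {
        pch[i] = ela[i] * (y[i] - V0CH(i));
        if (pch[i] < P_FLOOR) pch[i] = P_FLOOR;
    }
    for (i = 0; i < 11; i++)
        pc[i] = (y[4 + i] - VU(i)) / CC(i);

    /* vena caval occlusion: geometric ramp of the thoracic-vein outflow
       resistance from baseline to baseline*multiplier over the ramp */
    double rtv = R_TV_OUT;
    if (VCO_MULT > 1.0 && *t >= VCO_START) {
        double f = (*t - VCO_START) / VCO_RAMP;
        if (f > 1.0) f = 1.0;
        rtv *= (VCO_LIN > 0.5) ? 1.0 + (VCO_MULT - 1.0) * f
                               : pow(VCO_MULT, f);
    }

    double q_pv_la = (pc[10] - pch[0]) / R_PV_OUT;
    double q_mv = vflow(pch[0], pch[1], R_MV);
    double q_av = vflow(pch[1], pc[0], R_AV);
    double q_aa = (pc[0] - pc[1]) / R_AA_OUT;
    double q_in[5], q_out[5], s_in = 0.0, s_out = 0.0;
    for (i = 0; i < 5; i++) {
        q_in[i] = (pc[1] - pc[2 + i]) / R_IN(i);
        q_out[i] = (pc[2 + i] - pc[7]) / R_OUT(i);
        s_in += q_in[i];
        s_out += q_out[i];
    }
    double q_sv = (pc[7] - pc[8]) / R_SV_OUT;
    double q_tv = (pc[8] - pch[2]) / rtv;
    double q_tc = vflow(pch[2], pch[3], R_TC);
    double q_pu = vflow(pch[3], pc[9], R_PU);
    double q_pa = (pc[9] - pc[10]) / R_PA_OUT;

    ydot[0] = q_pv_la - q_mv;
    ydot[1] = q_mv - q_av;
    ydot[2] = q_tv - q_tc;
    ydot[3] = q_tc - q_pu;
    ydot[4] = q_av - q_aa;
    ydot[5] = q_aa - s_in;
    for (i = 0; i < 5; i++)
        ydot[6 + i] = q_in[i] - q_out[i];
    ydot[11] = s_out - q_sv;
    ydot[12] = q_sv - q_tv;
    ydot[13] = q_pu - q_pa;
    ydot[14] = q_pa - q_pv_la;

    if (ip[0] >= 20) {
        for (i = 0; i < 4; i++) yout[i] = pch[i];
        for (i = 0; i < 11; i++) yout[4 + i] = pc[i];
        yout[15] = q_av;
        yout[16] = q_mv;
        yout[17] = q_tc;
        yout[18] = q_pu;
        yout[19] = rtv;
    }
}
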