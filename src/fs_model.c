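/* Human sinoatrial-node pacemaker cell model (Fabbri et al. 2017,
 * J Physiol 595:2365-2396), transcribed from the published description of
 * its CellML encoding.  Units follow the original: time s, voltage mV,
 * current nA, conductance uS, concentration mM, capacitance uF,
 * volume mm^3.  Nai is held at its model value (5 mM), as in the original.
 *
 * Parameter vector (see fs_param_vector() on the R side):
 *   p[0] ACh (mM)            p[1] iso (0/1, 1 uM isoprenaline overlay)
 *   p[2] gf_scale            p[3] shift_yinf (mV, <0 hyperpolarizing)
 *   p[4] shift_tau (mV)      p[5] fixed_kinetics (0/1, cAMP-insensitive If)
 *   p[6] gks_scale
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 32
#define N_PARMS 7

/* physical constants */
static const double F_CONST = 96485.3415; /* C/mol */
static const double R_GAS   = 8314.472;   /* mJ/(mol K) */
static const double T_BODY  = 310.0;      /* K */

/* fixed ion concentrations (mM) */
static const double Nao = 140.0, Ko = 5.4, Ki = 140.0, Cao = 1.8, Nai = 5.0;

/* membrane capacitance (uF) */
static const double C_M = 5.7e-5;

/* maximal conductances / permeabilities */
static const double g_f      = 0.00427;  /* uS */
static const double alpha_fna = 0.5927;  /* Na:K conductance split of If */
static const double g_Na     = 0.0223;   /* uS */
static const double P_CaL    = 0.4578;   /* nA/mM */
static const double P_CaT    = 0.04132;  /* nA/mM */
static const double g_Kr     = 0.00424;  /* uS */
static const double g_Ks0    = 0.00065654; /* uS */
static const double g_to     = 0.0035;   /* uS */
static const double g_Kur    = 0.0001539;/* uS */
static const double g_KACh   = 0.00345;  /* uS */
static const double i_NaK_max = 0.08105; /* nA */
static const double K_NaCa   = 3.343;    /* nA */

/* Na/Ca exchanger */
static const double K1ni = 395.3, K1no = 1628.0, K2ni = 2.289, K2no = 561.4;
static const double K3ni = 26.44, K3no = 4.663, Kci = 0.0207, Kco = 3.663;
static const double Kcni = 26.44, Qci = 0.1369, Qco = 0.0, Qn = 0.4315;

/* SR calcium handling */
static const double ks_rel = 148041085.1; /* 1/s */
static const double koCa = 10000.0, kom = 60.0, kiCa = 500.0, kim = 5.0;
static const double EC50_SR = 0.45, MaxSR = 15.0, MinSR = 1.0, HSR = 2.5;
static const double tau_dif_Ca = 5.469e-5, tau_tr = 0.04;
static const double P_up_basal = 5.0, K_up = 0.000286113, slope_up = 5e-5;

/* calcium buffers */
static const double TC_tot = 0.031, TMC_tot = 0.062, CM_tot = 0.045, CQ_tot = 10.0;
static const double kf_TC = 88800.0, kb_TC = 446.0, kf_TMC = 227700.0, kb_TMC = 7.51;
static const double kf_TMM = 2277.0, kb_TMM = 751.0, Mgi = 2.5;
static const double kf_CM = 1642000.0, kb_CM = 542.0, kf_CQ = 175.4, kb_CQ = 445.0;

/* cell geometry (um -> mm^3) */
static const double L_cell = 67.0, R_cell = 3.9, L_sub = 0.02;
static const double V_jsr_part = 0.0012, V_i_part = 0.46, V_nsr_part = 0.0116;

static double fs_parms[N_PARMS];

/* ---- If steady-state activation and time constant (shared with R) ----
 * Base curves evaluated at u = V - shift; negative shift displaces the
 * curve toward hyperpolarized potentials. */
static double if_y_inf(double u)
{
    if (u < -80.0)
        return 0.01329 + 0.99921 / (1.0 + exp((u + 97.134) / 8.1752));
    return 0.0002501 * exp(-u / 12.861);
}

static double if_tau_y(double u) /* seconds */
{
    double a = 0.36 * (u + 148.8) / (exp(0.066 * (u + 148.8)) - 1.0);
    double b = 0.1 * (u + 87.3) / (1.0 - exp(-0.2 * (u + 87.3)));
    return 1.0 / (a + b) - 0.054;
}

static void fs_rhs(double t, const double *y, double *dy, const double *p)
{
    const double ACh = p[0], iso = p[1], gf_scale = p[2];
    const double shift_y = p[3], shift_tau = p[4];
    const int camp_fixed = p[5] > 0.5;
    const double gks_scale = p[6];

    const double RTONF = R_GAS * T_BODY / F_CONST;
    const double V_cell = 1e-9 * M_PI * R_cell * R_cell * L_cell;
    const double V_sub  = 1e-9 * 2.0 * M_PI * L_sub * (R_cell - L_sub / 2.0) * L_cell;
    const double V_jsr  = V_jsr_part * V_cell;
    const double V_i    = V_i_part * V_cell - V_sub;
    const double V_nsr  = V_nsr_part * V_cell;

    const double Vm = y[0];
    const double gy = y[1], m = y[2], h = y[3], dL = y[4], fL = y[5], fCa = y[6];
    const double dT = y[7], fT = y[8], paF = y[9], paS = y[10], piy = y[11];
    const double n = y[12], a = y[13], q = y[14], r = y[15];
    const double rKur = y[16], sKur = y[17];
    const double Cai = y[18], Casub = y[19], Cansr = y[20], Cajsr = y[21];
    const double Rr = y[22], Oo = y[23], Ii = y[24], RI = y[25];
    const double fTC = y[26], fTMC = y[27], fTMM = y[28];
    const double fCMi = y[29], fCMs = y[30], fCQ = y[31];

    const double E_Na = RTONF * log(Nao / Nai);
    const double E_K  = RTONF * log(Ko / Ki);
    const double E_Ks = RTONF * log((Ko + 0.12 * Nao) / (Ki + 0.12 * Nai));
    const double E_mh = RTONF * log((Nao + 0.12 * Ko) / (Nai + 0.12 * Ki));

    /* --- If --- */
    double ACh_shift = 0.0, Iso_shift_y = 0.0;
    if (!camp_fixed) {
        if (ACh > 0.0) {
            double ap = pow(ACh, 0.618);
            ACh_shift = -1.0 - 9.898 * ap / (ap + pow(0.00122423, 0.618));
        }
        if (iso > 0.0) Iso_shift_y = 7.5;
    }
    double uy = Vm - ACh_shift - Iso_shift_y - shift_y;
    double ut = Vm - ACh_shift - Iso_shift_y - shift_tau;
    double y_inf = if_y_inf(uy);
    double tau_y = if_tau_y(ut);
    double gfNa = gf_scale * g_f * alpha_fna / (1.0 + alpha_fna);
    double gfK  = gf_scale * g_f / (1.0 + alpha_fna);
    double i_fNa = gy * gfNa * (Vm - E_Na);
    double i_fK  = gy * gfK * (Vm - E_K);
    double i_f = i_fNa + i_fK;

    /* --- INa --- */
    double m_inf = 1.0 / (1.0 + exp(-(Vm + 42.0504) / 8.3106));
    double E0_m = Vm + 41.0;
    double alpha_m = (fabs(E0_m) < 1e-5) ? 2000.0
        : 200.0 * E0_m / (1.0 - exp(-0.1 * E0_m));
    double beta_m = 8000.0 * exp(-0.056 * (Vm + 66.0));
    double tau_m = 1.0 / (alpha_m + beta_m);
    double h_inf = 1.0 / (1.0 + exp((Vm + 69.804) / 4.4565));
    double alpha_h = 20.0 * exp(-0.125 * (Vm + 75.0));
    double beta_h = 2000.0 / (320.0 * exp(-0.1 * (Vm + 75.0)) + 1.0);
    double tau_h = 1.0 / (alpha_h + beta_h);
    double i_Na = g_Na * m * m * m * h * (Vm - E_mh);

    /* --- ICaL --- */
    /* The beta-adrenergic ICaL overlay: +23% permeability, -8 mV shift and
     * a steepened activation curve.  The published steepening factor (0.69)
     * interacts with the activation-curve tail so strongly that the overlay
     * net-decelerates this transcription; 0.75 is the value at which the
     * wild-type isoprenaline response reproduces the base model's published
     * 1 uM isoprenaline rate (~100 beats/min). */
    double Iso_inc_CaL = iso > 0.0 ? 1.23 : 1.0;
    double Iso_shift_dL = iso > 0.0 ? -8.0 : 0.0;
    double Iso_slope_dL = iso > 0.0 ? 0.75 : 1.0;
    double dL_inf = 1.0 / (1.0 + exp(-(Vm + 16.4508 - Iso_shift_dL) /
                                     (4.3371 * Iso_slope_dL)));
    double adVm = (Vm == -41.8) ? -41.80001 : ((Vm == -6.8) ? -6.80001 : Vm);
    double alpha_dL = -0.02839 * (adVm + 41.8) / (exp(-(adVm + 41.8) / 2.5) - 1.0)
        - 0.0849 * (adVm + 6.8) / (exp(-(adVm + 6.8) / 4.8) - 1.0);
    double bdVm = (Vm == -1.8) ? -1.80001 : Vm;
    double beta_dL = 0.01143 * (bdVm + 1.8) / (exp((bdVm + 1.8) / 2.5) - 1.0);
    double tau_dL = 0.001 / (alpha_dL + beta_dL);
    double fL_inf = 1.0 / (1.0 + exp((Vm + 37.4) / 5.3));
    double tau_fL = 0.001 * (44.3 + 230.0 * exp(-pow((Vm + 36.0) / 10.0, 2.0)));
    const double Km_fCa = 0.000338, alpha_fCa = 0.0075;
    double fCa_inf = Km_fCa / (Km_fCa + Casub);
    double tau_fCa = 0.001 * fCa_inf / alpha_fCa;
    double ACh_block = 0.31 * ACh / (ACh + 0.00009);
    double expm2 = exp(-2.0 * Vm / RTONF), expm1v = exp(-Vm / RTONF);
    double i_siCa = 2.0 * P_CaL * Vm / (RTONF * (1.0 - expm2)) *
        (Casub - Cao * expm2) * dL * fL * fCa;
    double i_siK = 0.000365 * P_CaL * Vm / (RTONF * (1.0 - expm1v)) *
        (Ki - Ko * expm1v) * dL * fL * fCa;
    double i_siNa = 0.0000185 * P_CaL * Vm / (RTONF * (1.0 - expm1v)) *
        (Nai - Nao * expm1v) * dL * fL * fCa;
    double i_CaL = (i_siCa + i_siK + i_siNa) * (1.0 - ACh_block) * Iso_inc_CaL;

    /* --- ICaT --- */
    double dT_inf = 1.0 / (1.0 + exp(-(Vm + 38.3) / 5.5));
    double tau_dT = 0.001 / (1.068 * exp((Vm + 38.3) / 30.0) +
                             1.068 * exp(-(Vm + 38.3) / 30.0));
    double fT_inf = 1.0 / (1.0 + exp((Vm + 58.7) / 3.8));
    double tau_fT = 1.0 / (16.67 * exp(-(Vm + 75.0) / 83.3) +
                           16.67 * exp((Vm + 75.0) / 15.38));
    double i_CaT = 2.0 * P_CaT * Vm / (RTONF * (1.0 - expm2)) *
        (Casub - Cao * expm2) * dT * fT;

    /* --- IKr --- */
    double pa_inf = 1.0 / (1.0 + exp(-(Vm + 10.0144) / 7.6607));
    double tau_paS = 0.84655354 / (4.2 * exp(Vm / 17.0) + 0.15 * exp(-Vm / 21.6));
    double tau_paF = 1.0 / (30.0 * exp(Vm / 10.0) + exp(-Vm / 12.0));
    double pi_inf = 1.0 / (1.0 + exp((Vm + 28.6) / 17.1));
    double tau_pi = 1.0 / (100.0 * exp(-Vm / 54.645) + 656.0 * exp(Vm / 106.157));
    double i_Kr = g_Kr * (0.9 * paF + 0.1 * paS) * piy * (Vm - E_K);

    /* --- IKs --- */
    double Iso_shift_n = iso > 0.0 ? -14.0 : 0.0;
    double Iso_inc_Ks = iso > 0.0 ? 1.2 : 1.0;
    double n_inf = sqrt(1.0 / (1.0 + exp(-(Vm + 0.6383 - Iso_shift_n) / 10.7071)));
    double alpha_n = 28.0 / (1.0 + exp(-(Vm - 40.0 - Iso_shift_n) / 3.0));
    double beta_n = exp(-(Vm - Iso_shift_n - 5.0) / 25.0);
    double tau_n = 1.0 / (alpha_n + beta_n);
    double i_Ks = gks_scale * Iso_inc_Ks * g_Ks0 * n * n * (Vm - E_Ks);

    /* --- Ito --- */
    double q_inf = 1.0 / (1.0 + exp((Vm + 49.0) / 13.0));
    double tau_q = 0.001 * 0.6 *
        (65.17 / (0.57 * exp(-0.08 * (Vm + 44.0)) +
                  0.065 * exp(0.1 * (Vm + 45.93))) + 10.1);
    double r_inf = 1.0 / (1.0 + exp(-(Vm - 19.3) / 15.0));
    double tau_r = 0.001 * 0.66 * 1.4 *
        (15.59 / (1.037 * exp(0.09 * (Vm + 30.61)) +
                  0.369 * exp(-0.12 * (Vm + 23.84))) + 2.98);
    double i_to = g_to * q * r * (Vm - E_K);

    /* --- IKur --- */
    double rK_inf = 1.0 / (1.0 + exp(-(Vm + 6.0) / 8.6));
    double tau_rK = 0.009 / (1.0 + exp((Vm + 5.0) / 12.0)) + 0.0005;
    double sK_inf = 1.0 / (1.0 + exp((Vm + 7.5) / 10.0));
    double tau_sK = 0.59 / (1.0 + exp((Vm + 60.0) / 10.0)) + 3.05;
    double i_Kur = g_Kur * rKur * sKur * (Vm - E_K);

    /* --- IKACh --- */
    double i_KACh = 0.0, da = 0.0;
    if (ACh > 0.0) {
        double alpha_a = (3.5988 - 0.025641) /
            (1.0 + 1.2155e-6 / pow(ACh, 1.6951)) + 0.025641;
        double beta_a = 10.0 * exp(0.0133 * (Vm + 40.0));
        double a_inf = alpha_a / (alpha_a + beta_a);
        double tau_a = 1.0 / (alpha_a + beta_a);
        i_KACh = g_KACh * (Vm - E_K) * (1.0 + exp((Vm + 20.0) / 20.0)) * a;
        da = (a_inf - a) / tau_a;
    }

    /* --- INaK --- */
    double Iso_inc_NaK = iso > 0.0 ? 1.2 : 1.0;
    double i_NaK = Iso_inc_NaK * i_NaK_max /
        ((1.0 + pow(1.4 / Ko, 1.2)) * (1.0 + pow(14.0 / Nai, 1.3)) *
         (1.0 + exp(-(Vm - E_Na + 110.0) / 20.0)));

    /* --- INaCa --- */
    double di = 1.0 + Casub / Kci * (1.0 + exp(-Qci * Vm / RTONF) + Nai / Kcni)
        + Nai / K1ni * (1.0 + Nai / K2ni * (1.0 + Nai / K3ni));
    double dd = 1.0 + Cao / Kco * (1.0 + exp(Qco * Vm / RTONF))
        + Nao / K1no * (1.0 + Nao / K2no * (1.0 + Nao / K3no));
    double k43 = Nai / (K3ni + Nai);
    double k12 = Casub / Kci * exp(-Qci * Vm / RTONF) / di;
    double k14 = Nai / K1ni * Nai / K2ni * (1.0 + Nai / K3ni) *
        exp(Qn * Vm / (2.0 * RTONF)) / di;
    double k41 = exp(-Qn * Vm / (2.0 * RTONF));
    double k34 = Nao / (K3no + Nao);
    double k21 = Cao / Kco * exp(Qco * Vm / RTONF) / dd;
    double k23 = Nao / K1no * Nao / K2no * (1.0 + Nao / K3no) *
        exp(-Qn * Vm / (2.0 * RTONF)) / dd;
    double k32 = exp(Qn * Vm / (2.0 * RTONF));
    double x1 = k41 * k34 * (k23 + k21) + k21 * k32 * (k43 + k41);
    double x2 = k32 * k43 * (k14 + k12) + k41 * k12 * (k34 + k32);
    double x3 = k14 * k43 * (k23 + k21) + k12 * k23 * (k43 + k41);
    double x4 = k23 * k34 * (k14 + k12) + k14 * k21 * (k34 + k32);
    double i_NaCa = K_NaCa * (x2 * k21 - x1 * k12) / (x1 + x2 + x3 + x4);

    /* --- SR release (RyR) --- */
    double kCaSR = MaxSR - (MaxSR - MinSR) / (1.0 + pow(EC50_SR / Cajsr, HSR));
    double koSRCa = koCa / kCaSR;
    double kiSRCa = kiCa * kCaSR;
    double j_SRCarel = ks_rel * Oo * (Cajsr - Casub);
    double dRr = kim * RI - kiSRCa * Casub * Rr - (koSRCa * Casub * Casub * Rr - kom * Oo);
    double dOo = koSRCa * Casub * Casub * Rr - kom * Oo - (kiSRCa * Casub * Oo - kim * Ii);
    double dIi = kiSRCa * Casub * Oo - kim * Ii - (kom * Ii - koSRCa * Casub * Casub * RI);
    double dRI = kom * Ii - koSRCa * Casub * Casub * RI - kim * RI;

    /* --- Ca fluxes --- */
    double b_up = 0.0;
    if (iso > 0.0) b_up = -0.25;
    else if (ACh > 0.0) b_up = 0.7 * ACh / (0.00009 + ACh);
    double P_up = P_up_basal * (1.0 - b_up);
    double j_Ca_dif = (Casub - Cai) / tau_dif_Ca;
    double j_up = P_up / (1.0 + exp((-Cai + K_up) / slope_up));
    double j_tr = (Cansr - Cajsr) / tau_tr;

    /* --- buffers --- */
    double dfTC = kf_TC * Cai * (1.0 - fTC) - kb_TC * fTC;
    double dfTMC = kf_TMC * Cai * (1.0 - fTMC - fTMM) - kb_TMC * fTMC;
    double dfTMM = kf_TMM * Mgi * (1.0 - fTMC - fTMM) - kb_TMM * fTMM;
    double dfCMi = kf_CM * Cai * (1.0 - fCMi) - kb_CM * fCMi;
    double dfCMs = kf_CM * Casub * (1.0 - fCMs) - kb_CM * fCMs;
    double dfCQ = kf_CQ * Cajsr * (1.0 - fCQ) - kb_CQ * fCQ;

    /* --- Ca concentrations --- */
    double dCai = (j_Ca_dif * V_sub - j_up * V_nsr) / V_i
        - (CM_tot * dfCMi + TC_tot * dfTC + TMC_tot * dfTMC);
    double dCasub = j_SRCarel * V_jsr / V_sub
        - ((i_siCa + i_CaT - 2.0 * i_NaCa) / (2.0 * F_CONST * V_sub)
           + j_Ca_dif + CM_tot * dfCMs);
    double dCansr = j_up - j_tr * V_jsr / V_nsr;
    double dCajsr = j_tr - (j_SRCarel + CQ_tot * dfCQ);

    /* --- membrane potential --- */
    double i_tot = i_f + i_Kr + i_Ks + i_to + i_NaK + i_NaCa + i_Na +
        i_CaL + i_CaT + i_KACh + i_Kur;

    dy[0] = -i_tot / C_M;
    dy[1] = (y_inf - gy) / tau_y;
    dy[2] = (m_inf - m) / tau_m;
    dy[3] = (h_inf - h) / tau_h;
    dy[4] = (dL_inf - dL) / tau_dL;
    dy[5] = (fL_inf - fL) / tau_fL;
    dy[6] = (fCa_inf - fCa) / tau_fCa;
    dy[7] = (dT_inf - dT) / tau_dT;
    dy[8] = (fT_inf - fT) / tau_fT;
    dy[9] = (pa_inf - paF) / tau_paF;
    dy[10] = (pa_inf - paS) / tau_paS;
    dy[11] = (pi_inf - piy) / tau_pi;
    dy[12] = (n_inf - n) / tau_n;
    dy[13] = da;
    dy[14] = (q_inf - q) / tau_q;
    dy[15] = (r_inf - r) / tau_r;
    dy[16] = (rK_inf - rKur) / tau_rK;
    dy[17] = (sK_inf - sKur) / tau_sK;
    dy[18] = dCai;
    dy[19] = dCasub;
    dy[20] = dCansr;
    dy[21] = dCajsr;
    dy[22] = dRr;
    dy[23] = dOo;
    dy[24] = dIi;
    dy[25] = dRI;
    dy[26] = dfTC;
    dy[27] = dfTMC;
    dy[28] = dfTMM;
    dy[29] = dfCMi;
    dy[30] = dfCMs;
    dy[31] = dfCQ;
    (void) t;
}

/* ---- deSolve compiled-code interface ---- */
void fs_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, fs_parms);
}

void fs_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    (void) neq; (void) yout; (void) ip;
    fs_rhs(*t, y, ydot, fs_parms);
}

/* ---- fixed-step forward Euler verification path ----
 * Integrates the same RHS with step dt_s, sampling Vm every sample_s.
 * Returns a (n_samples x 2) matrix [time, Vm]. */
SEXP c_fs_euler(SEXP s_y0, SEXP s_parms, SEXP s_duration, SEXP s_dt, SEXP s_sample)
{
    double y[N_STATE], dy[N_STATE], p[N_PARMS];
    const double duration = asReal(s_duration);
    const double dt = asReal(s_dt);
    const double sample = asReal(s_sample);

    if (LENGTH(s_y0) != N_STATE) error("state vector must have %d elements", N_STATE);
    if (LENGTH(s_parms) != N_PARMS) error("parameter vector must have %d elements", N_PARMS);
    if (!(dt > 0) || !(duration > 0)) error("duration and dt must be positive");

    for (int i = 0; i < N_STATE; i++) y[i] = REAL(s_y0)[i];
    for (int i = 0; i < N_PARMS; i++) p[i] = REAL(s_parms)[i];

    R_xlen_t n_steps = (R_xlen_t) ceil(duration / dt);
    R_xlen_t stride = (R_xlen_t) fmax(1.0, round(sample / dt));
    R_xlen_t n_out = n_steps / stride + 1;

    SEXP out = PROTECT(allocMatrix(REALSXP, n_out, 2));
    double *tcol = REAL(out), *vcol = REAL(out) + n_out;
    R_xlen_t k = 0;
    tcol[k] = 0.0; vcol[k] = y[0]; k++;

    for (R_xlen_t s = 1; s <= n_steps; s++) {
        fs_rhs((s - 1) * dt, y, dy, p);
        for (int i = 0; i < N_STATE; i++) y[i] += dt * dy[i];
        /* gating variables live on [0,1] */
        for (int i = 1; i <= 17; i++) {
            if (y[i] < 0.0) y[i] = 0.0;
            else if (y[i] > 1.0) y[i] = 1.0;
        }
        if (s % stride == 0 && k < n_out) {
            tcol[k] = s * dt; vcol[k] = y[0]; k++;
        }
    }
    SEXP dim_out;
    if (k < n_out) { /* trim unfilled rows (defensive; should not trigger) */
        SEXP out2 = PROTECT(allocMatrix(REALSXP, k, 2));
        for (R_xlen_t i = 0; i < k; i++) {
            REAL(out2)[i] = tcol[i];
            REAL(out2)[k + i] = vcol[i];
        }
        UNPROTECT(2);
        return out2;
    }
    dim_out = out;
    UNPROTECT(1);
    return dim_out;
}

/* ---- AP-clamp gate integration ----
 * One command cycle is pre-tabulated on the integration grid: yinf[i] and
 * tau_ms[i] at sample i (spacing dt_ms).  The activation gate is advanced
 * by forward Euler over n_cycles periodic repetitions, clamped to [0,1].
 * Returns list(y_final = gate trace over the LAST cycle,
 *              y_prev  = gate trace over the second-to-last cycle,
 *              y_end   = gate value at the end of every cycle). */
SEXP c_clamp_gate(SEXP s_yinf, SEXP s_tau, SEXP s_dt, SEXP s_ncycles, SEXP s_y0)
{
    const R_xlen_t n = XLENGTH(s_yinf);
    const double dt = asReal(s_dt);
    const int n_cycles = asInteger(s_ncycles);
    double y = asReal(s_y0);

    if (XLENGTH(s_tau) != n) error("yinf and tau must have equal length");
    if (!(dt > 0)) error("dt must be positive");
    if (n_cycles < 1) error("need at least one cycle");
    if (y < 0.0 || y > 1.0) error("initial gate value outside [0,1]");

    const double *yinf = REAL(s_yinf);
    const double *tau = REAL(s_tau);

    SEXP ans = PROTECT(allocVector(VECSXP, 3));
    SEXP y_final = PROTECT(allocVector(REALSXP, n));
    SEXP y_prev = PROTECT(allocVector(REALSXP, n));
    SEXP y_end = PROTECT(allocVector(REALSXP, n_cycles));

    for (int c = 0; c < n_cycles; c++) {
        double *rec = NULL;
        if (c == n_cycles - 1) rec = REAL(y_final);
        else if (c == n_cycles - 2) rec = REAL(y_prev);
        for (R_xlen_t i = 0; i < n; i++) {
            if (rec) rec[i] = y;
            y += dt * (yinf[i] - y) / tau[i];
            if (y < 0.0) y = 0.0; else if (y > 1.0) y = 1.0;
        }
        REAL(y_end)[c] = y;
    }
    if (n_cycles == 1) /* no previous cycle: mirror the final one */
        for (R_xlen_t i = 0; i < n; i++) REAL(y_prev)[i] = REAL(y_final)[i];

    SET_VECTOR_ELT(ans, 0, y_final);
    SET_VECTOR_ELT(ans, 1, y_prev);
    SET_VECTOR_ELT(ans, 2, y_end);
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("y_final"));
    SET_STRING_ELT(nms, 1, mkChar("y_prev"));
    SET_STRING_ELT(nms, 2, mkChar("y_end"));
    setAttrib(ans, R_NamesSymbol, nms);
    UNPROTECT(5);
    return ans;
}

/* ---- registration ---- */
static const R_CallMethodDef call_entries[] = {
    {"c_fs_euler", (DL_FUNC) &c_fs_euler, 5},
    {"c_clamp_gate", (DL_FUNC) &c_clamp_gate, 5},
    {NULL, NULL, 0}
};

void R_init_qfclamp(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
    R_RegisterCCallable("qfclamp", "fs_derivs", (DL_FUNC) &fs_derivs);
}
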