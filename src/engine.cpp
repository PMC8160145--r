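#include <Rcpp.h>
using namespace Rcpp;

// Stock indices
enum {
  S_WELL = 0, S_DIST, S_AQ, S_GP, S_AS, S_SP, S_CM, S_IP, S_ON, S_DG, S_PA,
  N_STOCK
};
// Cumulative counters follow the stocks in the state vector
enum { C_SUI = 0, C_HOSP, C_ED, C_DIS, N_CUM };

// Parameter vector layout (kept in step with params_layout() on the R side)
enum {
  P_ONSET = 0, P_RECOV_U, P_HELP_SEEK,
  P_GP_COMPL, P_FRAC_GP_REC, P_FRAC_GP_SPEC, P_FRAC_GP_CMHC, P_FRAC_GP_ONLINE,
  P_SPEC_COMPL, P_FRAC_SPEC_SUCC,
  P_CMHC_COMPL, P_FRAC_CMHC_SUCC,
  P_ONLINE_COMPL, P_FRAC_ONLINE_SUCC,
  P_IP_DISCHARGE,
  P_BASE_DISENG, P_WAIT_SENS, P_RE_ENGAGE,
  P_H_UNTREATED, P_H_INCARE, P_H_POST,
  P_CASE_FATALITY, P_HOSP_FRAC,
  P_ED_CRISIS,
  P_POST_EXIT, P_FRAC_POST_CMHC,
  P_SHOCK_START, P_SHOCK_DUR, P_SHOCK_MULT,
  P_BIRTHS, P_MIGRATION, P_MORTALITY,
  P_WAIT_CAP,
  P_SAFE_SPACE, P_ACUTE_DIVERT, P_AFTERCARE_COST,
  P_CONN_COVER, P_EDUC_EFFECT,
  P_CAPM_GP, P_CAPM_SPEC, P_CAPM_IP, P_CMHC_INC,
  N_PAR
};

static const double WEEKS_PER_YEAR = 52.0;

// services/week available at model time t (years since start of 2011).
// Multiplicative levers change the compounding rate from t_switch onward;
// the CMHC lever adds contacts per 10,000 population per week, per year
// elapsed since t_switch.
static double capacity_week(int svc, double t, double t_switch,
                            const NumericVector& cap_base,
                            const NumericVector& cap_growth,
                            const NumericVector& p_post, double pop0) {
  double base = cap_base[svc];
  double g = cap_growth[svc];
  double cap;
  if (t <= t_switch || !R_FINITE(t_switch)) {
    cap = base * std::pow(1.0 + g, t);
  } else {
    double m = 1.0;
    if (svc == 0) m = p_post[P_CAPM_GP];
    else if (svc == 1) m = p_post[P_CAPM_SPEC];
    else if (svc == 2) m = p_post[P_CAPM_IP];
    cap = base * std::pow(1.0 + g, t_switch) *
      std::pow(1.0 + m * g, t - t_switch);
  }
  if (svc == 3 && R_FINITE(t_switch) && t > t_switch) {
    cap += p_post[P_CMHC_INC] * pop0 / 1e4 * (t - t_switch);
  }
  return cap;
}

// Explicit-Euler core. Returns one row per grid point with columns:
// time, 11 stocks, 4 cumulatives, 4 intake flows (/yr), 4 capacities (/yr,
// CMHC net of aftercare consumption), 2 queue waits (weeks), cumulative
// background (non-suicide) deaths.
// [[Rcpp::export]]
NumericMatrix sd_core(NumericVector init, NumericVector p_base,
                      NumericVector p_post, double t_switch,
                      NumericVector cap_base, NumericVector cap_growth,
                      double pop0, double t0, double t_end, double dt) {
  if (init.size() != N_STOCK + N_CUM) stop("init must have %d elements", N_STOCK + N_CUM);
  if (p_base.size() != N_PAR || p_post.size() != N_PAR) stop("parameter vector has wrong length");
  if (dt <= 0) stop("dt must be positive");
  if (t_end <= t0) stop("t_end must exceed t0");

  int n_steps = (int) std::lround((t_end - t0) / dt);
  if (n_steps < 1) stop("time span shorter than one step");

  const int NCOL = 1 + N_STOCK + N_CUM + 4 + 4 + 2 + 1;
  NumericMatrix out(n_steps + 1, NCOL);

  std::vector<double> s(init.begin(), init.begin() + N_STOCK);
  std::vector<double> cum(init.begin() + N_STOCK, init.begin() + N_STOCK + N_CUM);

  double t = t0;
  double cum_bg = 0.0;   // cumulative background deaths (diagnostic)
  // diagnostics recorded for row i describe the flows applied over [t_i, t_i+dt)
  for (int i = 0; i <= n_steps; ++i) {
    const NumericVector& p = (t < t_switch) ? p_base : p_post;

    double W = s[S_WELL], D = s[S_DIST], AQ = s[S_AQ], GC = s[S_GP],
      AS = s[S_AS], SC = s[S_SP], CC = s[S_CM], IP = s[S_IP], ON = s[S_ON],
      DG = s[S_DG], PA = s[S_PA];

    // capacities, services/year
    double Cgp = capacity_week(0, t, t_switch, cap_base, cap_growth, p_post, pop0) * WEEKS_PER_YEAR;
    double Csp = capacity_week(1, t, t_switch, cap_base, cap_growth, p_post, pop0) * WEEKS_PER_YEAR;
    double Cin = capacity_week(2, t, t_switch, cap_base, cap_growth, p_post, pop0) * WEEKS_PER_YEAR;
    double Ccm = capacity_week(3, t, t_switch, cap_base, cap_growth, p_post, pop0) * WEEKS_PER_YEAR;
    // assertive aftercare is delivered through CMHC: enrolled post-attempt
    // clients consume capacity at a fixed services/person/week rate
    double free_cm = Ccm - p[P_AFTERCARE_COST] * WEEKS_PER_YEAR * PA;
    if (free_cm < 0) free_cm = 0;

    double shock = (t >= p[P_SHOCK_START] && t < p[P_SHOCK_START] + p[P_SHOCK_DUR])
      ? p[P_SHOCK_MULT] : 1.0;
    double csf = 1.0 + 0.5 * p[P_CONN_COVER];           // community-support factor
    double hs_eff = p[P_HELP_SEEK] * (1.0 + p[P_EDUC_EFFECT] * csf);

    // ---- proposed gross flows (persons/yr) ----
    double onset = W * p[P_ONSET] * shock;
    double recov_D = D * p[P_RECOV_U];
    double seek = D * hs_eff;

    double thr_gp = Cgp / WEEKS_PER_YEAR;               // persons/week
    double wait_gp = (thr_gp > 0) ? std::min(p[P_WAIT_CAP], AQ / thr_gp)
      : (AQ > 0 ? p[P_WAIT_CAP] : 0.0);
    double gp_intake = std::min(AQ / dt, Cgp);
    double dis_AQ = AQ * (p[P_BASE_DISENG] + p[P_WAIT_SENS] * wait_gp);

    double gp_out = GC * p[P_GP_COMPL];
    double dis_GC = GC * p[P_BASE_DISENG];

    double thr_sp = Csp / WEEKS_PER_YEAR;
    double wait_sp = (thr_sp > 0) ? std::min(p[P_WAIT_CAP], AS / thr_sp)
      : (AS > 0 ? p[P_WAIT_CAP] : 0.0);
    double spec_intake = std::min(AS / dt, Csp);
    double dis_AS = AS * (p[P_BASE_DISENG] + p[P_WAIT_SENS] * wait_sp);

    double spec_out = SC * p[P_SPEC_COMPL];
    double dis_SC = SC * p[P_BASE_DISENG];
    double cmhc_out = CC * p[P_CMHC_COMPL];
    double dis_CC = CC * p[P_BASE_DISENG];
    double on_out = ON * p[P_ONLINE_COMPL];
    double dis_ON = ON * p[P_BASE_DISENG];

    double discharge = IP * p[P_IP_DISCHARGE];
    double post_out = PA * p[P_POST_EXIT];
    double re_eng = DG * p[P_RE_ENGAGE];
    double recov_DG = DG * p[P_RECOV_U];

    // suicide attempts by origin stock
    double A_D = p[P_H_UNTREATED] * D, A_AQ = p[P_H_UNTREATED] * AQ,
      A_AS = p[P_H_UNTREATED] * AS, A_DG = p[P_H_UNTREATED] * DG;
    double A_GC = p[P_H_INCARE] * GC, A_SC = p[P_H_INCARE] * SC,
      A_CC = p[P_H_INCARE] * CC, A_ON = p[P_H_INCARE] * ON;
    double A_PA = p[P_H_POST] * PA;

    double cf = p[P_CASE_FATALITY], hf = p[P_HOSP_FRAC];

    // crisis ED-presentation events from untreated states; the acute-care
    // lever diverts a fraction into CMHC care (a real transition)
    double div_D = p[P_ACUTE_DIVERT] * p[P_ED_CRISIS] * D;
    double div_AQ = p[P_ACUTE_DIVERT] * p[P_ED_CRISIS] * AQ;
    double div_AS = p[P_ACUTE_DIVERT] * p[P_ED_CRISIS] * AS;
    double div_DG = p[P_ACUTE_DIVERT] * p[P_ED_CRISIS] * DG;

    double mortW = W * p[P_MORTALITY], mortD = D * p[P_MORTALITY],
      mortAQ = AQ * p[P_MORTALITY], mortGC = GC * p[P_MORTALITY],
      mortAS = AS * p[P_MORTALITY], mortSC = SC * p[P_MORTALITY],
      mortCC = CC * p[P_MORTALITY], mortIP = IP * p[P_MORTALITY],
      mortON = ON * p[P_MORTALITY], mortDG = DG * p[P_MORTALITY],
      mortPA = PA * p[P_MORTALITY];

    // ---- proportional outflow rationing so no stock can go negative ----
    // The post-attempt stock's attempt departure is bounded above by the
    // deaths-plus-hospitalised share (actual departures never exceed it).
    double tot[N_STOCK];
    tot[S_WELL] = onset + mortW;
    tot[S_DIST] = recov_D + seek + A_D + div_D + mortD;
    tot[S_AQ] = gp_intake + dis_AQ + A_AQ + div_AQ + mortAQ;
    tot[S_GP] = gp_out + dis_GC + A_GC + mortGC;
    tot[S_AS] = spec_intake + dis_AS + A_AS + div_AS + mortAS;
    tot[S_SP] = spec_out + dis_SC + A_SC + mortSC;
    tot[S_CM] = cmhc_out + dis_CC + A_CC + mortCC;
    tot[S_IP] = discharge + mortIP;
    tot[S_ON] = on_out + dis_ON + A_ON + mortON;
    tot[S_DG] = re_eng + recov_DG + A_DG + div_DG + mortDG;
    tot[S_PA] = post_out + (cf + (1.0 - cf) * hf) * A_PA + mortPA;

    double r[N_STOCK];
    for (int k = 0; k < N_STOCK; ++k) {
      r[k] = (tot[k] * dt > s[k] && tot[k] > 0) ? s[k] / (tot[k] * dt) : 1.0;
    }

    onset *= r[S_WELL]; mortW *= r[S_WELL];
    recov_D *= r[S_DIST]; seek *= r[S_DIST]; A_D *= r[S_DIST];
    div_D *= r[S_DIST]; mortD *= r[S_DIST];
    gp_intake *= r[S_AQ]; dis_AQ *= r[S_AQ]; A_AQ *= r[S_AQ];
    div_AQ *= r[S_AQ]; mortAQ *= r[S_AQ];
    gp_out *= r[S_GP]; dis_GC *= r[S_GP]; A_GC *= r[S_GP]; mortGC *= r[S_GP];
    spec_intake *= r[S_AS]; dis_AS *= r[S_AS]; A_AS *= r[S_AS];
    div_AS *= r[S_AS]; mortAS *= r[S_AS];
    spec_out *= r[S_SP]; dis_SC *= r[S_SP]; A_SC *= r[S_SP]; mortSC *= r[S_SP];
    cmhc_out *= r[S_CM]; dis_CC *= r[S_CM]; A_CC *= r[S_CM]; mortCC *= r[S_CM];
    discharge *= r[S_IP]; mortIP *= r[S_IP];
    on_out *= r[S_ON]; dis_ON *= r[S_ON]; A_ON *= r[S_ON]; mortON *= r[S_ON];
    re_eng *= r[S_DG]; recov_DG *= r[S_DG]; A_DG *= r[S_DG];
    div_DG *= r[S_DG]; mortDG *= r[S_DG];
    post_out *= r[S_PA]; A_PA *= r[S_PA]; mortPA *= r[S_PA];

    // ---- attempt consequences (after rationing) ----
    double A_sum = A_D + A_AQ + A_AS + A_DG + A_GC + A_SC + A_CC + A_ON + A_PA;
    double suicide_flow = cf * A_sum;
    double hosp_flow = (1.0 - cf) * hf * A_sum;
    double admit = std::min(hosp_flow, Cin);
    double admit_ratio = (hosp_flow > 0) ? admit / hosp_flow : 0.0;

    // ---- CMHC intake with priority: aftercare linkage, GP referral, acute diversion
    double req_post = p[P_FRAC_POST_CMHC] * post_out;
    double req_gp = p[P_FRAC_GP_CMHC] * gp_out;
    double req_acute = div_D + div_AQ + div_AS + div_DG;
    double take_post = std::min(req_post, free_cm);
    double take_gp = std::min(req_gp, free_cm - take_post);
    double take_acute = std::min(req_acute, free_cm - take_post - take_gp);
    double q_acute = (req_acute > 0) ? take_acute / req_acute : 0.0;
    double cmhc_intake = take_post + take_gp + take_acute;
    double over_post = req_post - take_post;   // linkage blocked -> distressed
    double over_gp = req_gp - take_gp;         // referral blocked -> distressed

    // ---- event counters ----
    // diverted contacts (safe space, acute-care response) never count as ED
    // presentations; the acute-care *transition into CMHC care* is what is
    // capacity-limited above
    double crisis = p[P_ED_CRISIS] * (D + AQ + AS + DG); // events, not rationed
    double ed_flow = crisis * (1.0 - p[P_SAFE_SPACE] - p[P_ACUTE_DIVERT]) + A_sum;
    if (ed_flow < 0) ed_flow = 0;
    double dis_flow = dis_AQ + dis_AS + dis_GC + dis_SC + dis_CC + dis_ON;

    // ---- record current row, then update ----
    out(i, 0) = t;
    for (int k = 0; k < N_STOCK; ++k) out(i, 1 + k) = s[k];
    for (int k = 0; k < N_CUM; ++k) out(i, 1 + N_STOCK + k) = cum[k];
    out(i, 16) = gp_intake; out(i, 17) = spec_intake;
    out(i, 18) = cmhc_intake; out(i, 19) = admit;
    out(i, 20) = Cgp; out(i, 21) = Csp; out(i, 22) = Cin; out(i, 23) = free_cm;
    out(i, 24) = wait_gp; out(i, 25) = wait_sp;
    out(i, 26) = cum_bg;
    if (i == n_steps) break;

    double B = p[P_BIRTHS] + p[P_MIGRATION];
    double frac_rem = 1.0 - p[P_FRAC_GP_REC] - p[P_FRAC_GP_SPEC]
      - p[P_FRAC_GP_CMHC] - p[P_FRAC_GP_ONLINE];

    double surv_to_PA = (1.0 - cf) * (1.0 - hf * admit_ratio);

    s[S_WELL] += dt * (B + recov_D + recov_DG + p[P_FRAC_GP_REC] * gp_out
                       + p[P_FRAC_SPEC_SUCC] * spec_out
                       + p[P_FRAC_CMHC_SUCC] * cmhc_out
                       + p[P_FRAC_ONLINE_SUCC] * on_out
                       - onset - mortW);
    s[S_DIST] += dt * (onset + frac_rem * gp_out + over_gp + over_post
                       + (1.0 - p[P_FRAC_POST_CMHC]) * post_out
                       + (1.0 - p[P_FRAC_SPEC_SUCC]) * spec_out
                       + (1.0 - p[P_FRAC_CMHC_SUCC]) * cmhc_out
                       + (1.0 - p[P_FRAC_ONLINE_SUCC]) * on_out
                       - recov_D - seek - A_D - q_acute * div_D - mortD);
    s[S_AQ] += dt * (seek + re_eng - gp_intake - dis_AQ - A_AQ
                     - q_acute * div_AQ - mortAQ);
    s[S_GP] += dt * (gp_intake - gp_out - dis_GC - A_GC - mortGC);
    s[S_AS] += dt * (p[P_FRAC_GP_SPEC] * gp_out - spec_intake - dis_AS - A_AS
                     - q_acute * div_AS - mortAS);
    s[S_SP] += dt * (spec_intake - spec_out - dis_SC - A_SC - mortSC);
    s[S_CM] += dt * (cmhc_intake - cmhc_out - dis_CC - A_CC - mortCC);
    s[S_IP] += dt * (admit - discharge - mortIP);
    s[S_ON] += dt * (p[P_FRAC_GP_ONLINE] * gp_out - on_out - dis_ON - A_ON - mortON);
    s[S_DG] += dt * (dis_flow - re_eng - recov_DG - A_DG - q_acute * div_DG - mortDG);
    s[S_PA] += dt * (surv_to_PA * (A_D + A_AQ + A_AS + A_DG + A_GC + A_SC + A_CC + A_ON)
                     + discharge
                     - cf * A_PA - (1.0 - cf) * hf * admit_ratio * A_PA
                     - post_out - mortPA);

    cum_bg += dt * (mortW + mortD + mortAQ + mortGC + mortAS + mortSC +
                    mortCC + mortIP + mortON + mortDG + mortPA);
    cum[C_SUI] += dt * suicide_flow;
    cum[C_HOSP] += dt * hosp_flow;
    cum[C_ED] += dt * ed_flow;
    cum[C_DIS] += dt * dis_flow;

    for (int k = 0; k < N_STOCK; ++k) {
      if (!R_FINITE(s[k]))
        stop("non-finite stock %d at t = %.4f (integration failure)", k + 1, t);
      if (s[k] < -1e-6 * (1.0 + std::abs(tot[k]) * dt))
        stop("negative stock %d at t = %.4f (integration failure)", k + 1, t);
      if (s[k] < 0) s[k] = 0.0;   // clip float round-off only
    }
    t = t0 + (i + 1) * dt;
  }
  return out;
}
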