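// Cycle-level engine for the schema / basal-ganglia WCST simulator.
//
// One synchronous update per cycle of two segregated cortico-BG-thalamic
// loops (cognitive N=3 rule schemas, sensorimotor N=4 placement schemas),
// plus trial-level feedback, striatal threshold learning and conflict-driven
// gain adaptation. Uses R's RNG throughout so that set.seed() in R makes a
// session fully deterministic, and so the pure-R reference engine can replay
// the exact same draws (the draw order per trial is: 4 stimulus-noise
// uniforms, one truncated normal per layer for the integration threshold,
// mid-trial redraws on cognitive deselection, then after a response 3
// striatal-noise uniforms, 1 gain-noise uniform, and finally the schedule's
// rule-switch / run-length uniforms).

#include <Rcpp.h>
using namespace Rcpp;

static inline double logistic_fn(double x, double beta, double alpha) {
  return 1.0 / (1.0 + std::exp(-alpha * (x - beta)));
}

static inline double runif_sym(double half) {
  return R::runif(-half, half);
}

static inline double trunc_norm_pos(double mean, double sd) {
  double x;
  do {
    x = R::rnorm(mean, sd);
  } while (x <= 0.0);
  return x;
}

struct Nucleus {
  std::vector<double> a, o;
  Nucleus(int n, double beta, double alpha) : a(n, 0.0), o(n, 0.0) {
    for (int i = 0; i < n; ++i) o[i] = logistic_fn(0.0, beta, alpha);
  }
};

// [[Rcpp::export(name = ".engine_run_session")]]
List engine_run_session(IntegerMatrix cards,      // n x 3 target indices (1-based)
                        List par,
                        int sched_mode,           // 0 criterion, 1 random_run
                        int criterion_length,
                        IntegerVector run_support,
                        int active_rule,          // 1..3
                        int run_target,
                        bool record_traces) {
  const int n_trials = cards.nrow();

  const double delta   = par["delta"];
  const double o_ext   = par["o_ext"];
  const double o_stim  = par["o_stim"];
  const double w_rule  = par["w_rule"];
  const double w_neg   = par["w_neg"];
  const double m_r     = par["m_r"];
  const double w_ctx_stn = par["w_ctx_stn"], w_gpe_stn = par["w_gpe_stn"];
  const double w_stn_gpe = par["w_stn_gpe"], w_strd2_gpe = par["w_strd2_gpe"];
  const double w_stn_gpi = par["w_stn_gpi"], w_gpe_gpi = par["w_gpe_gpi"];
  const double w_strd1_gpi = par["w_strd1_gpi"];
  const double eps_str = par["eps_str"], eps_sma = par["eps_sma"];
  const double thA_mean = par["theta_a_mean"], thA_sd = par["theta_a_sd"];
  const double theta_s = par["theta_s"];
  const double alpha_pfc = par["alpha_pfc"], alpha_stn = par["alpha_stn"];
  const double alpha_gpe = par["alpha_gpe"], alpha_gpi = par["alpha_gpi"];
  const double alpha_thal = par["alpha_thal"], alpha_str = par["alpha_str"];
  const double beta_pfc = par["beta_pfc"], beta_sma = par["beta_sma"];
  const double beta_str0 = par["beta_str"], beta_stn = par["beta_stn"];
  const double beta_gpe = par["beta_gpe"], beta_gpi = par["beta_gpi"];
  const double beta_thal = par["beta_thal"];
  const double z_stim = par["zeta_stim"], z_str = par["zeta_str"];
  const double z_sma = par["zeta_sma"];
  const double area_scale = par["area_scale"];
  const int cycle_cap = as<int>(par["cycle_cap"]);
  const int iti_cycles = as<int>(par["iti_cycles"]);
  const bool d2_adapts = as<bool>(par["d2_adapts"]);
  const std::string rpe_form = as<std::string>(par["rpe_form"]);
  const bool rpe_signed_match = (rpe_form == "signed_match");
  const bool sel_displacement = as<bool>(par["sel_displacement"]);
  const bool stim_noise_per_trial =
      as<std::string>(par["stim_noise"]) == "per_trial";
  const bool area_cumulative =
      as<std::string>(par["cog_area_policy"]) == "cumulative";

  // cognitive loop (3 channels)
  Nucleus pfc(3, beta_pfc, alpha_pfc);
  Nucleus d1c(3, beta_str0, alpha_str), d2c(3, beta_str0, alpha_str);
  Nucleus stnc(3, beta_stn, alpha_stn), gpec(3, beta_gpe, alpha_gpe);
  Nucleus gpic(3, beta_gpi, alpha_gpi), thalc(3, beta_thal, alpha_thal);
  for (int i = 0; i < 3; ++i) thalc.o[i] = -thalc.o[i];

  // sensorimotor loop (4 channels)
  double alpha_sma = par["alpha_sma"];
  Nucleus sma(4, beta_sma, alpha_sma);
  Nucleus d1s(4, beta_str0, alpha_str), d2s(4, beta_str0, alpha_str);
  Nucleus stns(4, beta_stn, alpha_stn), gpes(4, beta_gpe, alpha_gpe);
  Nucleus gpis(4, beta_gpi, alpha_gpi), thals(4, beta_thal, alpha_thal);
  for (int i = 0; i < 4; ++i) thals.o[i] = -thals.o[i];

  std::vector<double> beta_c(3, beta_str0);
  std::vector<double> f_prev(3, 0.0);
  double r_prev = 0.0;
  int sel_c = -1;   // selected cognitive schema (0-based; -1 none)
  double thA_c = 0.0, thA_s = 0.0;
  // cognitive evidence accumulates across trials; a node's accumulator
  // restarts when it loses selection (it must re-earn entry), whereas the
  // sensorimotor accumulators restart at every card onset (response timing)
  double area_c[3] = {0, 0, 0};

  // per-trial log
  IntegerVector L_trial(n_trials), L_resp(n_trials), L_applied(n_trials),
      L_active(n_trials), L_fb(n_trials), L_rt(n_trials), L_selc(n_trials),
      L_onset(n_trials), L_respcyc(n_trials);
  NumericMatrix L_beta(n_trials, 3);
  NumericVector L_alpha(n_trials);
  int categories = 0, run_counter = 0;

  // traces
  std::vector<double> tr_pfc, tr_sma, tr_gpis;
  long max_cycles = record_traces ? (long)n_trials * cycle_cap : 0;
  if (record_traces) {
    // reserve lazily; sessions rarely exceed ~200 cycles/trial
    tr_pfc.reserve(3 * 200 * n_trials);
    tr_sma.reserve(4 * 200 * n_trials);
    tr_gpis.reserve(4 * 200 * n_trials);
  }
  (void)max_cycles;

  std::vector<double> pfc_hist(3 * cycle_cap);  // within-trial history for medians
  long global_cycle = 0;

  for (int t = 0; t < n_trials; ++t) {
    const int ct[3] = {cards(t, 0), cards(t, 1), cards(t, 2)};

    bool match[4] = {false, false, false, false};
    for (int d = 0; d < 3; ++d) match[ct[d] - 1] = true;
    double stim[4];
    double zstim_trial[4] = {0, 0, 0, 0};
    if (stim_noise_per_trial)
      for (int i = 0; i < 4; ++i) zstim_trial[i] = runif_sym(z_stim);

    thA_c = trunc_norm_pos(thA_mean, thA_sd);
    thA_s = trunc_norm_pos(thA_mean, thA_sd);

    double area_s[4] = {0, 0, 0, 0};
    double o_resp[4] = {0, 0, 0, 0};  // sensorimotor outputs at response
    int response = -1, rt = 0;

    L_onset[t] = (int)global_cycle + 1;

    for (int cyc = 1; cyc <= cycle_cap; ++cyc) {
      // noisy stimulus drive on matching targets (noise held for the trial
      // or redrawn each cycle)
      for (int i = 0; i < 4; ++i) {
        double z = stim_noise_per_trial ? zstim_trial[i] : runif_sym(z_stim);
        stim[i] = match[i] ? o_stim + z : 0.0;
      }

      // ---- cognitive loop ----
      for (int i = 0; i < 3; ++i) {
        double u = o_ext + thalc.o[i];
        pfc.a[i] = delta * pfc.a[i] + (1 - delta) * u;
        pfc.o[i] = logistic_fn(pfc.a[i], beta_pfc, alpha_pfc);
      }
      double d2c_prev[3] = {d2c.o[0], d2c.o[1], d2c.o[2]};
      double gpec_prev[3] = {gpec.o[0], gpec.o[1], gpec.o[2]};
      for (int i = 0; i < 3; ++i) {
        d1c.a[i] = delta * d1c.a[i] + (1 - delta) * pfc.o[i];
        d1c.o[i] = logistic_fn(d1c.a[i], beta_c[i], alpha_str);
        double b2 = d2_adapts ? beta_c[i] : beta_str0;
        d2c.a[i] = delta * d2c.a[i] + (1 - delta) * pfc.o[i];
        d2c.o[i] = logistic_fn(d2c.a[i], b2, alpha_str);
      }
      for (int i = 0; i < 3; ++i) {
        double u = w_ctx_stn * pfc.o[i] + w_gpe_stn * gpec_prev[i];
        stnc.a[i] = delta * stnc.a[i] + (1 - delta) * u;
        stnc.o[i] = logistic_fn(stnc.a[i], beta_stn, alpha_stn);
      }
      double sum_stnc = stnc.o[0] + stnc.o[1] + stnc.o[2];
      for (int i = 0; i < 3; ++i) {
        double u = w_stn_gpe * sum_stnc + w_strd2_gpe * d2c_prev[i];
        gpec.a[i] = delta * gpec.a[i] + (1 - delta) * u;
        gpec.o[i] = logistic_fn(gpec.a[i], beta_gpe, alpha_gpe);
      }
      for (int i = 0; i < 3; ++i) {
        double u = w_stn_gpi * sum_stnc + w_gpe_gpi * gpec.o[i] +
                   w_strd1_gpi * d1c.o[i];
        gpic.a[i] = delta * gpic.a[i] + (1 - delta) * u;
        gpic.o[i] = logistic_fn(gpic.a[i], beta_gpi, alpha_gpi);
      }
      for (int i = 0; i < 3; ++i) {
        thalc.a[i] = delta * thalc.a[i] + (1 - delta) * gpic.o[i];
        thalc.o[i] = -logistic_fn(thalc.a[i], beta_thal, alpha_thal);
      }

      // cognitive selection: persistence while above theta_s; the area
      // criterion gates (re)selection after deselection
      for (int i = 0; i < 3; ++i) area_c[i] += pfc.o[i];
      if (sel_c >= 0 && pfc.o[sel_c] <= theta_s) {
        if (!area_cumulative) area_c[sel_c] = 0.0;
        sel_c = -1;
        thA_c = trunc_norm_pos(thA_mean, thA_sd);
      }
      if (sel_c < 0 || sel_displacement) {
        // highest-output node exceeding the static threshold with enough
        // accumulated evidence; under displacement it must also beat the
        // incumbent's current output
        int best = sel_c;
        double best_o = (sel_c >= 0) ? pfc.o[sel_c] : -1.0;
        for (int i = 0; i < 3; ++i) {
          if (i == sel_c) continue;
          if (pfc.o[i] > theta_s && area_scale * area_c[i] >= thA_c &&
              pfc.o[i] > best_o) {
            best = i;
            best_o = pfc.o[i];
          }
        }
        sel_c = best;
      }

      // ---- sensorimotor loop ----
      for (int i = 0; i < 4; ++i) {
        double topdown = 0.0;
        if (sel_c >= 0 && ct[sel_c] - 1 == i) topdown = w_rule * pfc.o[sel_c];
        double u = topdown + stim[i] + thals.o[i];
        sma.a[i] = delta * sma.a[i] + (1 - delta) * u;
        sma.o[i] = logistic_fn(sma.a[i], beta_sma, alpha_sma);
      }
      double d2s_prev[4] = {d2s.o[0], d2s.o[1], d2s.o[2], d2s.o[3]};
      double gpes_prev[4] = {gpes.o[0], gpes.o[1], gpes.o[2], gpes.o[3]};
      for (int i = 0; i < 4; ++i) {
        d1s.a[i] = delta * d1s.a[i] + (1 - delta) * sma.o[i];
        d1s.o[i] = logistic_fn(d1s.a[i], beta_str0, alpha_str);
        d2s.a[i] = delta * d2s.a[i] + (1 - delta) * sma.o[i];
        d2s.o[i] = logistic_fn(d2s.a[i], beta_str0, alpha_str);
      }
      for (int i = 0; i < 4; ++i) {
        double u = w_ctx_stn * sma.o[i] + w_gpe_stn * gpes_prev[i];
        stns.a[i] = delta * stns.a[i] + (1 - delta) * u;
        stns.o[i] = logistic_fn(stns.a[i], beta_stn, alpha_stn);
      }
      double sum_stns = stns.o[0] + stns.o[1] + stns.o[2] + stns.o[3];
      for (int i = 0; i < 4; ++i) {
        double u = w_stn_gpe * sum_stns + w_strd2_gpe * d2s_prev[i];
        gpes.a[i] = delta * gpes.a[i] + (1 - delta) * u;
        gpes.o[i] = logistic_fn(gpes.a[i], beta_gpe, alpha_gpe);
      }
      for (int i = 0; i < 4; ++i) {
        double u = w_stn_gpi * sum_stns + w_gpe_gpi * gpes.o[i] +
                   w_strd1_gpi * d1s.o[i];
        gpis.a[i] = delta * gpis.a[i] + (1 - delta) * u;
        gpis.o[i] = logistic_fn(gpis.a[i], beta_gpi, alpha_gpi);
      }
      for (int i = 0; i < 4; ++i) {
        thals.a[i] = delta * thals.a[i] + (1 - delta) * gpis.o[i];
        thals.o[i] = -logistic_fn(thals.a[i], beta_thal, alpha_thal);
      }

      // history / traces (the learning rule's median uses the smoothed
      // activation a, not the squashed output)
      for (int i = 0; i < 3; ++i) pfc_hist[(cyc - 1) * 3 + i] = pfc.a[i];
      if (record_traces) {
        for (int i = 0; i < 3; ++i) tr_pfc.push_back(pfc.o[i]);
        for (int i = 0; i < 4; ++i) tr_sma.push_back(sma.o[i]);
        for (int i = 0; i < 4; ++i) tr_gpis.push_back(gpis.o[i]);
      }
      ++global_cycle;

      // sensorimotor selection -> response
      for (int i = 0; i < 4; ++i) area_s[i] += sma.o[i];
      int best = -1;
      double best_o = -1.0;
      for (int i = 0; i < 4; ++i) {
        if (sma.o[i] > theta_s && area_scale * area_s[i] >= thA_s &&
            sma.o[i] > best_o) {
          best = i;
          best_o = sma.o[i];
        }
      }
      if (best >= 0) {
        response = best;
        rt = cyc;
        for (int i = 0; i < 4; ++i) o_resp[i] = sma.o[i];
        break;
      }
    }

    L_trial[t] = t + 1;
    L_selc[t] = sel_c + 1;  // 0 = none
    L_respcyc[t] = (int)global_cycle;

    if (response < 0) {
      // omission: no feedback, no learning, schedule untouched
      L_resp[t] = 0;
      L_applied[t] = 0;
      L_active[t] = active_rule;
      L_fb[t] = 0;
      L_rt[t] = cycle_cap;
      for (int i = 0; i < 3; ++i) L_beta(t, i) = beta_c[i];
      L_alpha[t] = alpha_sma;
      continue;
    }

    // applied rule: feature dimension shared by card and chosen target
    int applied = 0;
    for (int d = 0; d < 3; ++d)
      if (ct[d] - 1 == response) { applied = d + 1; break; }
    bool correct = (applied == active_rule);
    int r = correct ? 1 : -1;

    L_resp[t] = response + 1;
    L_applied[t] = applied;
    L_active[t] = active_rule;
    L_fb[t] = r;
    L_rt[t] = rt;

    // striatal threshold learning (cognitive channels only)
    double med[3];
    for (int i = 0; i < 3; ++i) {
      std::vector<double> v(rt);
      for (int c = 0; c < rt; ++c) v[c] = pfc_hist[c * 3 + i];
      std::sort(v.begin(), v.end());
      med[i] = (rt % 2) ? v[rt / 2] : 0.5 * (v[rt / 2 - 1] + v[rt / 2]);
    }
    double f_now[3];
    for (int i = 0; i < 3; ++i) {
      bool match_i = (ct[i] - 1 == response);
      f_now[i] = match_i ? 1.0 : (2.0 * w_neg - 1.0) - m_r * f_prev[i] * r_prev;
    }
    for (int i = 0; i < 3; ++i) {
      double rpe = rpe_signed_match ? (r * f_now[i] - med[i])
                                    : r * (f_now[i] - med[i]);
      double zeta = runif_sym(z_str);
      double b = (beta_c[i] - eps_str * rpe) * (1.0 + zeta);
      beta_c[i] = std::min(1.0, std::max(0.0, b));
    }
    // conflict-driven gain adaptation (sensorimotor layer)
    {
      double zeta = runif_sym(z_sma);
      double prodv = 1.0;
      for (int i = 0; i < 4; ++i) prodv *= (1.0 + eps_sma + o_resp[i]);
      alpha_sma = (1.0 + zeta) * prodv;
    }
    for (int i = 0; i < 3; ++i) f_prev[i] = f_now[i];
    r_prev = (double)r;

    for (int i = 0; i < 3; ++i) L_beta(t, i) = beta_c[i];
    L_alpha[t] = alpha_sma;

    // schedule
    if (correct) {
      ++run_counter;
      if (run_counter >= run_target) {
        ++categories;
        int others[2], k = 0;
        for (int rr = 1; rr <= 3; ++rr)
          if (rr != active_rule) others[k++] = rr;
        active_rule = others[(int)(unif_rand() * 2)];
        run_counter = 0;
        if (sched_mode == 1) {
          int ns = run_support.size();
          run_target = run_support[(int)(unif_rand() * ns)];
        }
      }
    } else {
      run_counter = 0;
    }

    // inter-trial interval: the card is withdrawn while the network keeps
    // integrating; the executed placement schema decays through the leaky
    // integrators and its channel's disinhibition fades, so the next card
    // meets a released (not latched) sensorimotor loop
    for (int k = 0; k < iti_cycles; ++k) {
      for (int i = 0; i < 3; ++i) {
        double u = o_ext + thalc.o[i];
        pfc.a[i] = delta * pfc.a[i] + (1 - delta) * u;
        pfc.o[i] = logistic_fn(pfc.a[i], beta_pfc, alpha_pfc);
      }
      double d2c_prev[3] = {d2c.o[0], d2c.o[1], d2c.o[2]};
      double gpec_prev[3] = {gpec.o[0], gpec.o[1], gpec.o[2]};
      for (int i = 0; i < 3; ++i) {
        d1c.a[i] = delta * d1c.a[i] + (1 - delta) * pfc.o[i];
        d1c.o[i] = logistic_fn(d1c.a[i], beta_c[i], alpha_str);
        double b2 = d2_adapts ? beta_c[i] : beta_str0;
        d2c.a[i] = delta * d2c.a[i] + (1 - delta) * pfc.o[i];
        d2c.o[i] = logistic_fn(d2c.a[i], b2, alpha_str);
      }
      for (int i = 0; i < 3; ++i) {
        double u = w_ctx_stn * pfc.o[i] + w_gpe_stn * gpec_prev[i];
        stnc.a[i] = delta * stnc.a[i] + (1 - delta) * u;
        stnc.o[i] = logistic_fn(stnc.a[i], beta_stn, alpha_stn);
      }
      double sum_stnc = stnc.o[0] + stnc.o[1] + stnc.o[2];
      for (int i = 0; i < 3; ++i) {
        double u = w_stn_gpe * sum_stnc + w_strd2_gpe * d2c_prev[i];
        gpec.a[i] = delta * gpec.a[i] + (1 - delta) * u;
        gpec.o[i] = logistic_fn(gpec.a[i], beta_gpe, alpha_gpe);
      }
      for (int i = 0; i < 3; ++i) {
        double u = w_stn_gpi * sum_stnc + w_gpe_gpi * gpec.o[i] +
                   w_strd1_gpi * d1c.o[i];
        gpic.a[i] = delta * gpic.a[i] + (1 - delta) * u;
        gpic.o[i] = logistic_fn(gpic.a[i], beta_gpi, alpha_gpi);
      }
      for (int i = 0; i < 3; ++i) {
        thalc.a[i] = delta * thalc.a[i] + (1 - delta) * gpic.o[i];
        thalc.o[i] = -logistic_fn(thalc.a[i], beta_thal, alpha_thal);
      }
      for (int i = 0; i < 3; ++i) area_c[i] += pfc.o[i];
      if (sel_c >= 0 && pfc.o[sel_c] <= theta_s) {
        if (!area_cumulative) area_c[sel_c] = 0.0;
        sel_c = -1;
        thA_c = trunc_norm_pos(thA_mean, thA_sd);
      }
      if (sel_c < 0 || sel_displacement) {
        int best = sel_c;
        double best_o = (sel_c >= 0) ? pfc.o[sel_c] : -1.0;
        for (int i = 0; i < 3; ++i) {
          if (i == sel_c) continue;
          if (pfc.o[i] > theta_s && area_scale * area_c[i] >= thA_c &&
              pfc.o[i] > best_o) {
            best = i;
            best_o = pfc.o[i];
          }
        }
        sel_c = best;
      }
      // sensorimotor loop with no card: no stimulus, no rule routing
      for (int i = 0; i < 4; ++i) {
        double u = thals.o[i];
        sma.a[i] = delta * sma.a[i] + (1 - delta) * u;
        sma.o[i] = logistic_fn(sma.a[i], beta_sma, alpha_sma);
      }
      double d2s_prev[4] = {d2s.o[0], d2s.o[1], d2s.o[2], d2s.o[3]};
      double gpes_prev[4] = {gpes.o[0], gpes.o[1], gpes.o[2], gpes.o[3]};
      for (int i = 0; i < 4; ++i) {
        d1s.a[i] = delta * d1s.a[i] + (1 - delta) * sma.o[i];
        d1s.o[i] = logistic_fn(d1s.a[i], beta_str0, alpha_str);
        d2s.a[i] = delta * d2s.a[i] + (1 - delta) * sma.o[i];
        d2s.o[i] = logistic_fn(d2s.a[i], beta_str0, alpha_str);
      }
      for (int i = 0; i < 4; ++i) {
        double u = w_ctx_stn * sma.o[i] + w_gpe_stn * gpes_prev[i];
        stns.a[i] = delta * stns.a[i] + (1 - delta) * u;
        stns.o[i] = logistic_fn(stns.a[i], beta_stn, alpha_stn);
      }
      double sum_stns = stns.o[0] + stns.o[1] + stns.o[2] + stns.o[3];
      for (int i = 0; i < 4; ++i) {
        double u = w_stn_gpe * sum_stns + w_strd2_gpe * d2s_prev[i];
        gpes.a[i] = delta * gpes.a[i] + (1 - delta) * u;
        gpes.o[i] = logistic_fn(gpes.a[i], beta_gpe, alpha_gpe);
      }
      for (int i = 0; i < 4; ++i) {
        double u = w_stn_gpi * sum_stns + w_gpe_gpi * gpes.o[i] +
                   w_strd1_gpi * d1s.o[i];
        gpis.a[i] = delta * gpis.a[i] + (1 - delta) * u;
        gpis.o[i] = logistic_fn(gpis.a[i], beta_gpi, alpha_gpi);
      }
      for (int i = 0; i < 4; ++i) {
        thals.a[i] = delta * thals.a[i] + (1 - delta) * gpis.o[i];
        thals.o[i] = -logistic_fn(thals.a[i], beta_thal, alpha_thal);
      }
      if (record_traces) {
        for (int i = 0; i < 3; ++i) tr_pfc.push_back(pfc.o[i]);
        for (int i = 0; i < 4; ++i) tr_sma.push_back(sma.o[i]);
        for (int i = 0; i < 4; ++i) tr_gpis.push_back(gpis.o[i]);
      }
      ++global_cycle;
    }
  }

  List out = List::create(
      _["trial"] = L_trial, _["response"] = L_resp, _["applied_rule"] = L_applied,
      _["active_rule"] = L_active, _["feedback"] = L_fb, _["rt_cycles"] = L_rt,
      _["selected_cognitive"] = L_selc, _["onset_cycle"] = L_onset,
      _["response_cycle"] = L_respcyc, _["beta_str"] = L_beta,
      _["alpha_sma"] = L_alpha, _["categories"] = categories);

  if (record_traces) {
    long T = global_cycle;
    NumericMatrix m_pfc(3, T), m_sma(4, T), m_gpis(4, T);
    std::copy(tr_pfc.begin(), tr_pfc.end(), m_pfc.begin());
    std::copy(tr_sma.begin(), tr_sma.end(), m_sma.begin());
    std::copy(tr_gpis.begin(), tr_gpis.end(), m_gpis.begin());
    out["trace_pfc"] = m_pfc;
    out["trace_sma"] = m_sma;
    out["trace_gpi_sma"] = m_gpis;
  }
  return out;
}
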