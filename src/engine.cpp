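// Weekly population engine. Applies the same fixed decision sequence as the
// single-patient reference implementation in R/weekly_update.R:
// (1) critical outcomes, (2) crisis resolution, (3) adherence chart,
// (4) appointments, (5) refill, (6) environment countdown/transition,
// (7) score updates, (8) finances. Patients are processed in shuffled order
// each week because shared provider capacity makes order matter.
// All randomness comes from R's RNG, so runs are reproducible from set.seed.

#include <Rcpp.h>
using namespace Rcpp;

// environment indices
enum { ENV_PRIVATE = 0, ENV_ASSISTED = 1, ENV_HOMELESS = 2,
       ENV_HOSPITAL = 3, ENV_JAIL = 4 };
// provider indices
enum { PR_CMHC = 0, PR_CW = 1, PR_CSU = 2, PR_HOSP = 3 };
// crisis outcomes
enum { CO_HOSP = 0, CO_ARREST = 1, CO_HOMELESS = 2, CO_SUICIDE = 3,
       CO_STAB = 4 };

// event kinds (documented in R/engine.R)
enum {
  EV_CRISIS = 1, EV_CRIME = 2, EV_SUB_START = 3, EV_SUB_STOP = 4,
  EV_EMP_FOUND = 5, EV_EMP_LOST = 6, EV_CRISIS_HOSP = 7, EV_CRISIS_ARREST = 8,
  EV_CRISIS_HOMELESS = 9, EV_CRISIS_SUICIDE = 10, EV_CRISIS_STAB = 11,
  EV_CSU_CONTACT = 12, EV_CIT = 13, EV_DIVERSION = 14, EV_INCARCERATE = 15,
  EV_RELEASE = 16, EV_HOMELESS_ENTRY = 17, EV_APPT_KEPT = 18,
  EV_APPT_MISSED = 19, EV_REFILL_FAIL = 20, EV_MED_START = 21,
  EV_MED_STOP = 22, EV_REFERRAL_OK = 23, EV_REFERRAL_FAIL = 24,
  EV_OUTREACH = 25, EV_ENV_MOVE = 26,
  EV_COST_BASE = 30  // 30..35: cost postings per category
};

// cost categories
enum { CC_MED = 0, CC_OUTP = 1, CC_HOSP = 2, CC_JAILC = 3, CC_HOUS = 4,
       CC_CRIS = 5 };

// metric columns
enum {
  M_ALIVE = 0, M_CAT0 = 1, M_ENV0 = 5, M_ONMED = 10, M_LOST = 11,
  M_CRISES = 12, M_HOSPADM = 13, M_ARRESTS = 14, M_INCARC = 15,
  M_SUICIDES = 16, M_HOMELESS_IN = 17, M_STAB = 18, M_CIT = 19,
  M_DIVERT = 20, M_RELEASES = 21, M_REARREST = 22, M_SCHED = 23,
  M_KEPT = 24, M_MISSED = 25, M_REF_ATT = 26, M_REF_FAIL = 27,
  M_CRIMES = 28, M_CMHC = 29, M_CW = 30, M_CSU = 31, M_INDIV = 32,
  M_EMPLOYED = 33, M_SUBSTANCE = 34, M_MEANMH = 35, M_MEANPH = 36,
  M_MEDSTART = 37, M_MEDSTOP = 38, M_CLASSMH0 = 39, N_METRICS = 43
};

static inline int cat_idx(double mh) {
  int band = (int)std::ceil(mh) - 1;
  if (band < 0) band = 0;
  band /= 10;
  if (band > 9) band = 9;
  static const int coarse[10] = {0, 0, 0, 1, 1, 2, 2, 3, 3, 3};
  return coarse[band];
}

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline int draw_cat(const double *p, int k) {
  double u = unif_rand(), c = 0.0;
  for (int i = 0; i < k; ++i) {
    c += p[i];
    if (u < c) return i;
  }
  return k - 1;
}

struct EventLog {
  bool on;
  std::vector<int> week, pid, kind;
  std::vector<double> value;
  void emit(int w, int p, int k, double v = 0.0) {
    if (!on) return;
    week.push_back(w); pid.push_back(p); kind.push_back(k); value.push_back(v);
  }
};

// [[Rcpp::export(name = ".cpp_run_engine")]]
List cpp_run_engine(List pack, List pop, int n_weeks, bool log_events) {
  // --- unpack configuration -------------------------------------------------
  const double handoff = pack["handoff"];
  const double compliance = pack["compliance"];
  const double outreach = pack["outreach"];

  const NumericVector aw = pack["adherence_weights"]; // stress, substance,
    // side_effects, cost_factor, family, lai, contact
  const double stop_thr = pack["stop_threshold"];
  const double start_thr = pack["start_threshold"];

  const double med_mh = pack["medication_mh_effect"];
  const double untreated = pack["untreated_decline"];
  const double crisis_shock_delta = pack["crisis_mh_shock"];
  const double stress_coef = pack["stress_mh_coef"];
  const double support_coef = pack["support_mh_coef"];
  const double mh_ph = pack["mh_ph_coupling"];
  const double ph_mh = pack["ph_mh_coupling"];
  const double se_ph = pack["side_effect_ph_coef"];
  const double fin_strain = pack["financial_strain_stress"];
  const double noise_sd = pack["stress_noise_sd"];

  const double res_ref = pack["resources_ref"];
  const double acc_floor = pack["access_floor"];
  const double copay_med = pack["copay_per_factor_medication"];
  const double copay_visit = pack["copay_per_factor_visit"];
  const double low_res = pack["low_resources_threshold"];

  const double plan_transfer = pack["plan_transfer_weekly"];
  const double sub_start = pack["substance_start_weekly"];
  const double sub_stop = pack["substance_stop_weekly"];
  const double emp_gain = pack["employment_gain_weekly"];
  const double emp_loss = pack["employment_loss_weekly"];
  const double emp_min_mh = pack["employment_min_mh"];
  const double income_w = pack["income_employed_weekly"];
  const double benefits_w = pack["benefits_weekly"];

  const NumericVector crisis_onset = pack["crisis_onset"];   // by category
  const NumericVector crime_prop = pack["crime_propensity"]; // by category
  const NumericVector crisis_out = pack["crisis_outcomes"];  // 5

  const IntegerVector med_refill = pack["med_refill"];
  const IntegerVector med_costf = pack["med_cost_factor"];
  const NumericVector med_syscost = pack["med_system_cost"];
  const NumericVector med_se = pack["med_side_effect_total"];
  const NumericVector med_long_se = pack["med_long_se"];
  const LogicalVector med_is_lai = pack["med_is_lai"];
  const int lai_idx = pack["lai_idx"];   // 0-based
  const int oral_idx = pack["oral_idx"]; // 0-based

  const NumericVector prov_cap = pack["provider_capacity"]; // weekly totals
  const NumericVector prov_lai = pack["provider_lai_prob"];
  const IntegerVector prov_costf = pack["provider_cost_factor"];
  const NumericVector prov_third = pack["provider_third_cost"];
  const NumericVector prov_eff = pack["provider_mh_effect"];

  const NumericVector env_ploc = pack["env_p_located"];
  const NumericVector env_cap = pack["env_capacity"];
  const NumericVector env_mh = pack["env_mh_effect"];
  const NumericVector env_ph = pack["env_ph_effect"];
  const NumericVector env_cpat = pack["env_cost_patient"];
  const NumericVector env_cthird = pack["env_cost_third"];
  const NumericVector env_stress = pack["env_stress"];
  const double hosp_los_mean = pack["hospital_los_mean"];
  const double hosp_los_min = pack["hospital_los_min"];

  const NumericVector trans = pack["transitions"]; // [env(3)][cat(4)][dest(3)]

  const double p_cit = pack["cit_probability"];
  const double p_misd = pack["p_misdemeanor"];
  const NumericVector sent_mean = pack["sentence_mean"]; // misd, felony
  const NumericVector sent_min = pack["sentence_min"];
  const double p_div = pack["diversion_probability"];
  const int div_weeks = pack["diversion_weeks"];
  const NumericVector discharge = pack["discharge_location"]; // 3 stable envs

  const int cmhc_every = pack["cmhc_every"];
  const int cw_every = pack["cw_every"];

  // --- unpack population ----------------------------------------------------
  NumericVector mh = clone(as<NumericVector>(pop["mental_health"]));
  NumericVector mh_floor = as<NumericVector>(pop["mh_floor"]);
  NumericVector ph = clone(as<NumericVector>(pop["physical_health"]));
  NumericVector ph_decl = as<NumericVector>(pop["ph_decline_factor"]);
  NumericVector stress_base = as<NumericVector>(pop["stress_base"]);
  NumericVector fam = as<NumericVector>(pop["family_support"]);
  LogicalVector substance = clone(as<LogicalVector>(pop["substance_abuse"]));
  LogicalVector employed = clone(as<LogicalVector>(pop["employed"]));
  LogicalVector on_med = clone(as<LogicalVector>(pop["on_medication"]));
  IntegerVector med = clone(as<IntegerVector>(pop["medicine_idx"])); // -1 none
  NumericVector lai_left = clone(as<NumericVector>(pop["lai_weeks_left"]));
  IntegerVector env = clone(as<IntegerVector>(pop["environment_idx"]));
  IntegerVector weeks_rem = clone(as<IntegerVector>(pop["weeks_remaining"]));
  NumericVector res = clone(as<NumericVector>(pop["financial_resources"]));
  IntegerVector history = clone(as<IntegerVector>(pop["criminal_history_idx"]));
  LogicalVector in_div = clone(as<LogicalVector>(pop["in_jail_diversion"]));
  LogicalVector lost = clone(as<LogicalVector>(pop["lost_to_system"]));
  IntegerVector appt_phase = as<IntegerVector>(pop["appointment_phase"]);
  IntegerVector refill_phase = as<IntegerVector>(pop["refill_phase"]);

  const int n = mh.size();
  // patient class for the internal-dynamics variability check: coarse
  // category of the initial mental-health score, fixed for the whole run
  std::vector<int> init_cat(n);
  for (int i = 0; i < n; ++i) init_cat[i] = cat_idx(mh[i]);
  std::vector<int> alive(n, 1), prev_env(n, ENV_PRIVATE), div_left(n, 0);
  std::vector<int> released(n, 0), rearrested(n, 0), contact_last(n, 0);
  for (int i = 0; i < n; ++i) {
    if (env[i] < ENV_HOSPITAL) prev_env[i] = env[i];
    if (in_div[i]) div_left[i] = div_weeks;
  }

  // shared state
  double occ[5] = {0, 0, 0, 0, 0};
  for (int i = 0; i < n; ++i) occ[env[i]] += 1;
  double cap_left[4];

  NumericMatrix metrics(n_weeks, N_METRICS);
  NumericMatrix costs(n_weeks, 12); // category*2 + (0 patient, 1 third)
  EventLog ev; ev.on = log_events;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int w = 1; w <= n_weeks; ++w) {
    const int wr = w - 1; // row index
    for (int k = 0; k < 4; ++k) cap_left[k] = prov_cap[k];
    // Fisher-Yates shuffle of processing order
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    double cost_w[12] = {0};
    auto post = [&](int cat, double pat, double third, int pid) {
      cost_w[cat * 2] += pat;
      cost_w[cat * 2 + 1] += third;
      if (pat != 0.0 || third != 0.0)
        ev.emit(w, pid, EV_COST_BASE + cat, pat + third);
    };

    for (int oi = 0; oi < n; ++oi) {
      const int i = order[oi];
      if (!alive[i]) continue;

      bool contact = false;
      double provider_mh = 0.0, crisis_shock = 0.0, pat_cost = 0.0;
      bool episodic = env[i] >= ENV_HOSPITAL;
      bool crisis = false, crime = false, entered_episodic = false;

      // (1) critical outcomes ----------------------------------------------
      if (!episodic) {
        const int cat = cat_idx(mh[i]);
        if (unif_rand() < crisis_onset[cat]) {
          crisis = true;
          metrics(wr, M_CRISES) += 1;
          ev.emit(w, i + 1, EV_CRISIS);
        } else if (unif_rand() < crime_prop[cat]) {
          crime = true;
          metrics(wr, M_CRIMES) += 1;
          ev.emit(w, i + 1, EV_CRIME);
        } else {
          if (substance[i]) {
            if (unif_rand() < sub_stop) {
              substance[i] = false;
              ev.emit(w, i + 1, EV_SUB_STOP);
            }
          } else if (unif_rand() < sub_start) {
            substance[i] = true;
            ev.emit(w, i + 1, EV_SUB_START);
          }
          if (employed[i]) {
            if (unif_rand() < emp_loss) {
              employed[i] = false;
              ev.emit(w, i + 1, EV_EMP_LOST);
            }
          } else if (mh[i] >= emp_min_mh && unif_rand() < emp_gain) {
            employed[i] = true;
            ev.emit(w, i + 1, EV_EMP_FOUND);
          }
        }
        if (lost[i] && outreach > 0 && !crisis && !crime) {
          if (unif_rand() < outreach * env_ploc[env[i]]) {
            lost[i] = false;
            ev.emit(w, i + 1, EV_OUTREACH);
          }
        }
      }

      // helpers shared by crisis/arrest handling ----------------------------
      auto attempt_referral = [&](void) -> bool {
        metrics(wr, M_REF_ATT) += 1;
        bool ok = unif_rand() < handoff * env_ploc[env[i]];
        if (!ok) metrics(wr, M_REF_FAIL) += 1;
        ev.emit(w, i + 1, ok ? EV_REFERRAL_OK : EV_REFERRAL_FAIL);
        lost[i] = !ok;
        return ok;
      };

      auto csu_contact = [&](void) {
        if (cap_left[PR_CSU] >= 1) {
          cap_left[PR_CSU] -= 1;
          metrics(wr, M_CSU) += 1;
          contact = true;
          provider_mh += prov_eff[PR_CSU];
          double pc = prov_costf[PR_CSU] * copay_visit;
          pat_cost += pc;
          post(CC_CRIS, pc, prov_third[PR_CSU], i + 1);
          ev.emit(w, i + 1, EV_CSU_CONTACT);
          if (lost[i] && attempt_referral()) {
            // re-engagement comes with a renewed plan and prescription
            if (med[i] < 0) med[i] = oral_idx;
            if (!on_med[i]) {
              on_med[i] = true;
              metrics(wr, M_MEDSTART) += 1;
              ev.emit(w, i + 1, EV_MED_START);
            }
            if (med_is_lai[med[i]]) lai_left[i] = med_refill[med[i]];
          }
        }
      };
      auto process_arrest = [&](void) {
        metrics(wr, M_ARRESTS) += 1;
        if (released[i]) {
          if (!rearrested[i]) rearrested[i] = 1;
          metrics(wr, M_REARREST) += 1;
        }
        if (unif_rand() < p_cit) {
          metrics(wr, M_CIT) += 1;
          ev.emit(w, i + 1, EV_CIT);
          csu_contact();
          return;
        }
        const bool misd = unif_rand() < p_misd;
        const int deg = misd ? 1 : 2;
        if (deg > history[i]) history[i] = deg;
        if (misd && unif_rand() < p_div) {
          metrics(wr, M_DIVERT) += 1;
          ev.emit(w, i + 1, EV_DIVERSION);
          in_div[i] = true;
          div_left[i] = div_weeks;
          lost[i] = false;
          if (med[i] < 0) med[i] = oral_idx;
          if (!on_med[i]) {
            on_med[i] = true; // supervised treatment plan
            metrics(wr, M_MEDSTART) += 1;
            ev.emit(w, i + 1, EV_MED_START);
          }
          return;
        }
        // incarceration
        metrics(wr, M_INCARC) += 1;
        const int d = misd ? 0 : 1;
        int sentence = (int)(sent_min[d] +
                             R::rpois(std::max(0.0, sent_mean[d] - sent_min[d])));
        if (env[i] < ENV_HOSPITAL) prev_env[i] = env[i];
        occ[env[i]] -= 1; occ[ENV_JAIL] += 1;
        env[i] = ENV_JAIL;
        weeks_rem[i] = sentence;
        entered_episodic = true;
        employed[i] = false;
        ev.emit(w, i + 1, EV_INCARCERATE, sentence);
      };

      // (2) crisis resolution ----------------------------------------------
      if (crisis) {
        crisis_shock = crisis_shock_delta;
        int out = draw_cat(&crisis_out[0], 5);
        if (out == CO_HOSP) {
          bool can = cap_left[PR_HOSP] >= 1 &&
            (env_cap[ENV_HOSPITAL] < 0 || occ[ENV_HOSPITAL] < env_cap[ENV_HOSPITAL]);
          if (!can) out = CO_STAB;
        }
        switch (out) {
        case CO_HOSP: {
          cap_left[PR_HOSP] -= 1;
          metrics(wr, M_HOSPADM) += 1;
          ev.emit(w, i + 1, EV_CRISIS_HOSP);
          int los = (int)(hosp_los_min +
                          R::rpois(std::max(0.0, hosp_los_mean - hosp_los_min)));
          prev_env[i] = env[i];
          occ[env[i]] -= 1; occ[ENV_HOSPITAL] += 1;
          env[i] = ENV_HOSPITAL;
          weeks_rem[i] = los;
          entered_episodic = true;
          employed[i] = false;
          break;
        }
        case CO_ARREST:
          ev.emit(w, i + 1, EV_CRISIS_ARREST);
          process_arrest();
          break;
        case CO_HOMELESS:
          ev.emit(w, i + 1, EV_CRISIS_HOMELESS);
          if (env[i] != ENV_HOMELESS) {
            occ[env[i]] -= 1; occ[ENV_HOMELESS] += 1;
            env[i] = ENV_HOMELESS;
            metrics(wr, M_HOMELESS_IN) += 1;
            ev.emit(w, i + 1, EV_HOMELESS_ENTRY);
          }
          break;
        case CO_SUICIDE:
          ev.emit(w, i + 1, EV_CRISIS_SUICIDE);
          alive[i] = 0;
          occ[env[i]] -= 1;
          metrics(wr, M_SUICIDES) += 1;
          if (on_med[i]) { on_med[i] = false; metrics(wr, M_MEDSTOP) += 1;
                           ev.emit(w, i + 1, EV_MED_STOP); }
          break;
        default:
          metrics(wr, M_STAB) += 1;
          ev.emit(w, i + 1, EV_CRISIS_STAB);
          csu_contact();
        }
        if (!alive[i]) continue;
      } else if (crime) {
        process_arrest();
      }
      episodic = env[i] >= ENV_HOSPITAL;

      // (3) adherence state chart ------------------------------------------
      const double noise = noise_sd > 0 ? norm_rand() * noise_sd : 0.0;
      double stress = stress_base[i] + env_stress[env[i]] +
        (res[i] < low_res ? fin_strain : 0.0) + noise;
      stress = clamp(stress, 0.0, 1.0);
      if (med[i] >= 0) {
        const bool lai_active = lai_left[i] > 0;
        const double score =
          aw[0] * stress + aw[1] * (substance[i] ? 1.0 : 0.0) +
          aw[2] * med_se[med[i]] + aw[3] * (double)med_costf[med[i]] +
          aw[4] * fam[i] + aw[5] * (lai_active ? 1.0 : 0.0) +
          aw[6] * (contact_last[i] ? 1.0 : 0.0);
        if (on_med[i]) {
          if (score < stop_thr && !lai_active) {
            on_med[i] = false;
            metrics(wr, M_MEDSTOP) += 1;
            ev.emit(w, i + 1, EV_MED_STOP);
          }
        } else if (score > start_thr && !lost[i]) {
          on_med[i] = true;
          metrics(wr, M_MEDSTART) += 1;
          ev.emit(w, i + 1, EV_MED_START);
        }
      }

      // (4) appointments ----------------------------------------------------
      if (!episodic && !lost[i]) {
        bool due[2];
        due[0] = (w + appt_phase[i]) % cmhc_every == 0;
        due[1] = ((w + appt_phase[i]) % cw_every == 0) || in_div[i];
        for (int k = 0; k < 2; ++k) {
          if (!due[k]) continue;
          metrics(wr, M_SCHED) += 1;
          const double af = 1.0 - (prov_costf[k] / 5.0) * (1.0 - acc_floor) *
            (1.0 - std::min(1.0, res[i] / res_ref) / 2.0);
          bool kept = false;
          if (unif_rand() < compliance * af && cap_left[k] >= 1) {
            cap_left[k] -= 1;
            kept = true;
            contact = true;
            provider_mh += prov_eff[k];
            const double pc = prov_costf[k] * copay_visit;
            pat_cost += pc;
            post(CC_OUTP, pc, prov_third[k], i + 1);
            metrics(wr, k == 0 ? M_CMHC : M_CW) += 1;
            if (med[i] >= 0 && unif_rand() < prov_lai[k]) {
              med[i] = lai_idx;
              lai_left[i] = med_refill[lai_idx];
            }
            if (med[i] >= 0 && med_is_lai[med[i]] && on_med[i]) {
              lai_left[i] = med_refill[med[i]]; // depot re-injection
            }
          }
          metrics(wr, kept ? M_KEPT : M_MISSED) += 1;
          ev.emit(w, i + 1, kept ? EV_APPT_KEPT : EV_APPT_MISSED);
        }
      }
      if (env[i] == ENV_HOSPITAL) {
        contact = true;
        if (med[i] >= 0 && unif_rand() < prov_lai[PR_HOSP]) {
          med[i] = lai_idx;
          lai_left[i] = med_refill[lai_idx];
        }
        if (med[i] >= 0 && med_is_lai[med[i]] && on_med[i]) {
          lai_left[i] = med_refill[med[i]]; // administered on the ward
        }
      }
      // routine plan transfer between providers: a handoff that can fail
      if (!episodic && !lost[i] && plan_transfer > 0 &&
          unif_rand() < plan_transfer) {
        attempt_referral();
      }

      // (5) medication refill ----------------------------------------------
      if (med[i] >= 0) {
        if (med_is_lai[med[i]] && lai_left[i] > 0) lai_left[i] -= 1;
        if (med_is_lai[med[i]] && on_med[i] && lai_left[i] <= 0) {
          // depot coverage lapsed without a re-injection
          on_med[i] = false;
          metrics(wr, M_MEDSTOP) += 1;
          ev.emit(w, i + 1, EV_MED_STOP);
        }
        if (on_med[i]) {
          if (!med_is_lai[med[i]] &&
              (w + refill_phase[i]) % med_refill[med[i]] == 0) {
            bool ok;
            if (lost[i]) ok = false;
            else if (episodic) ok = true;
            else {
              const double af = 1.0 - (med_costf[med[i]] / 5.0) *
                (1.0 - acc_floor) *
                (1.0 - std::min(1.0, res[i] / res_ref) / 2.0);
              ok = unif_rand() < af;
            }
            if (!ok) {
              on_med[i] = false;
              metrics(wr, M_MEDSTOP) += 1;
              ev.emit(w, i + 1, EV_REFILL_FAIL);
              ev.emit(w, i + 1, EV_MED_STOP);
            }
          }
          if (on_med[i]) {
            const double copay =
              episodic ? 0.0 : med_costf[med[i]] * copay_med;
            pat_cost += copay;
            post(CC_MED, copay, med_syscost[med[i]], i + 1);
          }
        }
      }

      // (6) environment countdown / transition ------------------------------
      if (in_div[i]) {
        if (--div_left[i] <= 0) { in_div[i] = false; div_left[i] = 0; }
      }
      if (env[i] == ENV_HOSPITAL || env[i] == ENV_JAIL) {
        // the admission week does not count against the stay
        if (!entered_episodic && --weeks_rem[i] <= 0) {
          int dest;
          if (env[i] == ENV_HOSPITAL) {
            dest = prev_env[i];
            if (med[i] < 0) med[i] = oral_idx;
            if (!on_med[i]) {
              on_med[i] = true; // discharged with an active prescription
              metrics(wr, M_MEDSTART) += 1;
              ev.emit(w, i + 1, EV_MED_START);
            }
            if (med_is_lai[med[i]]) lai_left[i] = med_refill[med[i]];
          } else {
            dest = draw_cat(&discharge[0], 3);
            released[i] = 1;
            metrics(wr, M_RELEASES) += 1;
            ev.emit(w, i + 1, EV_RELEASE);
            if (med[i] < 0) med[i] = oral_idx;
          }
          if (dest == ENV_ASSISTED && env_cap[ENV_ASSISTED] >= 0 &&
              occ[ENV_ASSISTED] >= env_cap[ENV_ASSISTED]) {
            dest = ENV_HOMELESS;
          }
          occ[env[i]] -= 1; occ[dest] += 1;
          const int from = env[i];
          env[i] = dest;
          weeks_rem[i] = -1;
          if (dest == ENV_HOMELESS && from != ENV_HOMELESS) {
            metrics(wr, M_HOMELESS_IN) += 1;
            ev.emit(w, i + 1, EV_HOMELESS_ENTRY);
          }
          attempt_referral(); // care continuity across the transfer
        }
      } else {
        const int cat = cat_idx(mh[i]);
        const double *row = &trans[(env[i] * 4 + cat) * 3];
        int dest = draw_cat(row, 3);
        if (dest != env[i]) {
          if (dest == ENV_ASSISTED && env_cap[ENV_ASSISTED] >= 0 &&
              occ[ENV_ASSISTED] >= env_cap[ENV_ASSISTED]) {
            dest = ENV_HOMELESS; // overflow destination for full housing
          }
          if (dest != env[i]) {
            occ[env[i]] -= 1; occ[dest] += 1;
            if (dest == ENV_HOMELESS) {
              metrics(wr, M_HOMELESS_IN) += 1;
              ev.emit(w, i + 1, EV_HOMELESS_ENTRY);
            }
            env[i] = dest;
            ev.emit(w, i + 1, EV_ENV_MOVE, dest);
          }
        }
      }

      // (7) score updates ---------------------------------------------------
      {
        const bool untr = !on_med[i] && !contact;
        double m = mh[i] + med_mh * (on_med[i] ? 1.0 : 0.0) + provider_mh +
          env_mh[env[i]] - untreated * (untr ? 1.0 : 0.0) -
          stress_coef * stress + support_coef * fam[i] +
          mh_ph * (ph[i] - mh[i]) / 100.0 + crisis_shock;
        m = clamp(m, mh_floor[i], 100.0);
        double se = (med[i] >= 0 && on_med[i]) ? se_ph * med_long_se[med[i]] : 0.0;
        double q = ph[i] + ph_decl[i] + env_ph[env[i]] - se +
          ph_mh * (mh[i] - ph[i]) / 100.0;
        ph[i] = clamp(q, 1.0, 100.0);
        mh[i] = m;
      }

      // (8) finances --------------------------------------------------------
      pat_cost += env_cpat[env[i]];
      {
        const int cc = env[i] == ENV_HOSPITAL ? CC_HOSP :
          (env[i] == ENV_JAIL ? CC_JAILC : CC_HOUS);
        post(cc, env_cpat[env[i]], env_cthird[env[i]], i + 1);
      }
      const double income = employed[i] ? income_w : benefits_w;
      res[i] = std::max(0.0, res[i] + income - pat_cost);
      contact_last[i] = contact ? 1 : 0;
    }

    // --- end-of-week aggregates ------------------------------------------
    double sum_mh = 0, sum_ph = 0;
    double cls_sum[4] = {0, 0, 0, 0};
    int cls_n[4] = {0, 0, 0, 0};
    int n_alive = 0;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      ++n_alive;
      sum_mh += mh[i]; sum_ph += ph[i];
      cls_sum[init_cat[i]] += mh[i]; cls_n[init_cat[i]] += 1;
      metrics(wr, M_CAT0 + cat_idx(mh[i])) += 1;
      metrics(wr, M_ENV0 + env[i]) += 1;
      if (on_med[i]) metrics(wr, M_ONMED) += 1;
      if (lost[i]) metrics(wr, M_LOST) += 1;
      if (in_div[i]) metrics(wr, M_INDIV) += 1;
      if (employed[i]) metrics(wr, M_EMPLOYED) += 1;
      if (substance[i]) metrics(wr, M_SUBSTANCE) += 1;
    }
    metrics(wr, M_ALIVE) = n_alive;
    metrics(wr, M_MEANMH) = n_alive ? sum_mh / n_alive : NA_REAL;
    metrics(wr, M_MEANPH) = n_alive ? sum_ph / n_alive : NA_REAL;
    for (int c = 0; c < 4; ++c) {
      metrics(wr, M_CLASSMH0 + c) = cls_n[c] ? cls_sum[c] / cls_n[c] : NA_REAL;
    }
    for (int c = 0; c < 12; ++c) costs(wr, c) = cost_w[c];
  }

  int n_released = 0, n_rearrested = 0, n_suicides = 0;
  for (int i = 0; i < n; ++i) {
    n_released += released[i];
    n_rearrested += rearrested[i];
    n_suicides += 1 - alive[i];
  }

  List final_state = List::create(
    _["mental_health"] = mh, _["physical_health"] = ph,
    _["on_medication"] = on_med, _["lost_to_system"] = lost,
    _["environment_idx"] = env, _["alive"] = LogicalVector(alive.begin(), alive.end()),
    _["financial_resources"] = res, _["medicine_idx"] = med,
    _["employed"] = employed, _["substance_abuse"] = substance,
    _["criminal_history_idx"] = history,
    _["released_ever"] = LogicalVector(released.begin(), released.end()),
    _["in_jail_diversion"] = in_div);

  List events = R_NilValue;
  if (log_events) {
    events = List::create(
      _["week"] = IntegerVector(ev.week.begin(), ev.week.end()),
      _["patient"] = IntegerVector(ev.pid.begin(), ev.pid.end()),
      _["kind"] = IntegerVector(ev.kind.begin(), ev.kind.end()),
      _["value"] = NumericVector(ev.value.begin(), ev.value.end()));
  }

  return List::create(
    _["metrics"] = metrics, _["costs"] = costs,
    _["final_state"] = final_state,
    _["n_released"] = n_released, _["n_rearrested"] = n_rearrested,
    _["n_suicides"] = n_suicides, _["events"] = events);
}
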