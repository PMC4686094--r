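#include <Rcpp.h>
using namespace Rcpp;

// Trial-level engine shared by simulation and likelihood evaluation.
//
// Agent codes (parameter vector layout in brackets):
//   0 q_lambda         [alpha, T, lambda, perseveration]
//   1 model_based      [alpha, T, eta (<0: true transition matrix), perseveration]
//   2 reward_as_cue    [alpha1, T1, alpha2, T2]   (second-step pars used on original task)
//   3 latent_state     [omega, epsilon, p_good, p_bad, alpha, T]
//   4 det_reward_as_cue[alpha2, T2]               (deterministic first-step policy)
//   5 random           []                          (uniform at both steps)
//   6 random_mf2       [alpha, T]                  (uniform first step, Q-learning second)
//
// Task list fields: variant (0 reduced / 1 original), p_common,
//   process (0 blocks / 1 walk / 2 fixed), block_length, block_hi, block_lo,
//   walk_lo, walk_hi, walk_sd, fixed_a, fixed_b, n2 (second-step actions per state).
//
// Event matrix columns (0-based):
//   0 choice1 (1=A,2=B)  1 common (1/0)  2 second_state (1=a,2=b)
//   3 choice2 (1/2, NA on reduced)  4 outcome (0/1)
//   5 rp_a1  6 rp_b1  7 rp_a2  8 rp_b2   (true reward probs in force at trial time)
//   9 p1A (agent's P(choose A))  10 p2_chosen  11 q1A  12 q1B  13 posterior

struct Task {
  int variant, process, block_length, n2;
  double p_common, block_hi, block_lo, walk_lo, walk_hi, walk_sd, fixed_a, fixed_b;
};

static Task as_task(const List& tl) {
  Task t;
  t.variant       = as<int>(tl["variant_code"]);
  t.p_common      = as<double>(tl["p_common"]);
  t.process       = as<int>(tl["process_code"]);
  t.block_length  = as<int>(tl["block_length"]);
  t.block_hi      = as<double>(tl["block_hi"]);
  t.block_lo      = as<double>(tl["block_lo"]);
  t.walk_lo       = as<double>(tl["walk_lo"]);
  t.walk_hi       = as<double>(tl["walk_hi"]);
  t.walk_sd       = as<double>(tl["walk_sd"]);
  t.fixed_a       = as<double>(tl["fixed_a"]);
  t.fixed_b       = as<double>(tl["fixed_b"]);
  t.n2            = as<int>(tl["n_second_actions"]);
  return t;
}

// fold a proposed walk value back into [lo, hi], iterating if it overshoots both
static double fold_reflect(double x, double lo, double hi) {
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x; else x = 2.0 * hi - x;
  }
  return x;
}

// overflow-safe two-action softmax: P(action 0)
static double softmax2(double v0, double v1, double T) {
  double z = T * (v0 - v1);
  if (z > 0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
double fold_reflect_cpp(double x, double lo, double hi) {
  return fold_reflect(x, lo, hi);
}

// [[Rcpp::export]]
List engine_cpp(int mode, int agent, NumericVector par, List task_list,
                int n_trials, Nullable<NumericMatrix> events_ = R_NilValue) {
  Task tk = as_task(task_list);
  const bool original = (tk.variant == 1);
  const bool simulate = (mode == 0);

  NumericMatrix ev;
  if (!simulate) {
    if (events_.isNull()) stop("evaluation mode requires an events matrix");
    ev = NumericMatrix(events_);
    n_trials = ev.nrow();
  }

  // --- task reward-probability state (simulation only; no RNG touched in eval) ---
  double rp[2][2] = {{0.5, 0.5}, {0.5, 0.5}};
  int block_phase = 0;
  if (simulate) {
    if (tk.process == 0) {            // blocks: first good state chosen at random
      int good = (unif_rand() < 0.5) ? 0 : 1;
      rp[good][0] = tk.block_hi; rp[1 - good][0] = tk.block_lo;
    } else if (tk.process == 1) {     // walks start uniform within bounds
      for (int s = 0; s < 2; ++s)
        for (int j = 0; j < tk.n2; ++j)
          rp[s][j] = tk.walk_lo + unif_rand() * (tk.walk_hi - tk.walk_lo);
    } else {                          // fixed
      for (int j = 0; j < tk.n2; ++j) { rp[0][j] = tk.fixed_a; rp[1][j] = tk.fixed_b; }
    }
  }

  // --- agent state ---
  double q1[2]      = {0.5, 0.5};
  double q2[2][2]   = {{0.5, 0.5}, {0.5, 0.5}};
  double qrc[4][2]  = {{0.5, 0.5}, {0.5, 0.5}, {0.5, 0.5}, {0.5, 0.5}};
  double that[2];                       // P(state a | action A), P(state a | action B)
  double post = 0.5;                    // P(state a is the good state)
  int last = -1, cue = -1;

  double alpha = 0, T = 0, lam = 0, persev = 0, eta = -1;
  double alpha2 = 0, T2 = 0, omega = 0, eps = 0, p_good = 0, p_bad = 0;
  switch (agent) {
  case 0: alpha = par[0]; T = par[1]; lam = par[2]; persev = par[3]; break;
  case 1: alpha = par[0]; T = par[1]; eta = par[2]; persev = par[3]; break;
  case 2: alpha = par[0]; T = par[1]; alpha2 = par[2]; T2 = par[3]; break;
  case 3: omega = par[0]; eps = par[1]; p_good = par[2]; p_bad = par[3];
          alpha = par[4]; T = par[5]; break;
  case 4: alpha2 = par[0]; T2 = par[1]; break;
  case 5: break;
  case 6: alpha = par[0]; T = par[1]; break;
  default: stop("unknown agent code");
  }
  that[0] = (eta >= 0) ? 0.5 : tk.p_common;       // learned estimates start uniform
  that[1] = (eta >= 0) ? 0.5 : 1.0 - tk.p_common;
  static const int det_map[4] = {0, 1, 1, 0};     // cue (r,s2) -> action: (1,a)A (1,b)B (0,a)B (0,b)A

  NumericMatrix out;
  NumericVector p1vec, trial_ll;
  if (simulate) out = NumericMatrix(n_trials, 14);
  else { p1vec = NumericVector(n_trials); trial_ll = NumericVector(n_trials); }

  double loglik = 0.0;

  for (int t = 0; t < n_trials; ++t) {
    // ---- first-step choice probabilities ----
    double pA = 0.5, q1A = NA_REAL, q1B = NA_REAL, postrec = NA_REAL;
    double b0 = (last == 0) ? persev : 0.0, b1 = (last == 1) ? persev : 0.0;
    switch (agent) {
    case 0:
      q1A = q1[0]; q1B = q1[1];
      pA = softmax2(q1[0] + b0, q1[1] + b1, T);
      break;
    case 1: {
      double V0 = original ? std::max(q2[0][0], q2[0][1]) : q2[0][0];
      double V1 = original ? std::max(q2[1][0], q2[1][1]) : q2[1][0];
      q1A = that[0] * V0 + (1.0 - that[0]) * V1;
      q1B = that[1] * V0 + (1.0 - that[1]) * V1;
      pA = softmax2(q1A + b0, q1B + b1, T);
      break;
    }
    case 2:
      if (cue >= 0) {
        q1A = qrc[cue][0]; q1B = qrc[cue][1];
        pA = softmax2(q1A, q1B, T);
      }
      break;
    case 3:
      postrec = post;
      pA = (post > 0.5) ? 1.0 - eps : (post < 0.5 ? eps : 0.5);
      break;
    case 4:
      if (cue >= 0) pA = (det_map[cue] == 0) ? 1.0 : 0.0;
      break;
    default: break;                      // random agents: 0.5
    }

    // ---- sample or read trial events ----
    int c1, s2, c2 = 0, common, r;
    if (simulate) {
      c1 = (unif_rand() < pA) ? 0 : 1;
      common = (unif_rand() < tk.p_common) ? 1 : 0;
      s2 = common ? c1 : 1 - c1;
    } else {
      c1 = (int)ev(t, 0) - 1;
      s2 = (int)ev(t, 2) - 1;
      common = (c1 == s2) ? 1 : 0;
    }

    double p2c = NA_REAL;
    if (original) {
      double Tsec = (agent == 2 || agent == 4) ? T2 : T;
      double p2A = (agent == 5) ? 0.5 : softmax2(q2[s2][0], q2[s2][1], Tsec);
      if (simulate) c2 = (unif_rand() < p2A) ? 0 : 1;
      else c2 = (int)ev(t, 3) - 1;
      p2c = (c2 == 0) ? p2A : 1.0 - p2A;
    }

    if (simulate) {
      r = (unif_rand() < rp[s2][c2]) ? 1 : 0;
    } else {
      r = (int)ev(t, 4);
    }

    double ll_t = std::log(c1 == 0 ? pA : 1.0 - pA);
    if (original) ll_t += std::log(p2c);
    loglik += ll_t;

    if (simulate) {
      out(t, 0) = c1 + 1; out(t, 1) = common; out(t, 2) = s2 + 1;
      out(t, 3) = original ? c2 + 1 : NA_REAL; out(t, 4) = r;
      out(t, 5) = rp[0][0]; out(t, 6) = rp[1][0];
      out(t, 7) = original ? rp[0][1] : NA_REAL;
      out(t, 8) = original ? rp[1][1] : NA_REAL;
      out(t, 9) = pA; out(t, 10) = p2c;
      out(t, 11) = q1A; out(t, 12) = q1B; out(t, 13) = postrec;
    } else {
      p1vec[t] = pA; trial_ll[t] = ll_t;
    }

    // ---- value / belief updates (end of trial, sequential) ----
    switch (agent) {
    case 0: {
      double q2c = q2[s2][c2];           // pre-update second-step value
      q1[c1] = (1.0 - alpha) * q1[c1] + alpha * (q2c + lam * (r - q2c));
      q2[s2][c2] = (1.0 - alpha) * q2c + alpha * r;
      break;
    }
    case 1:
      q2[s2][c2] = (1.0 - alpha) * q2[s2][c2] + alpha * r;
      if (eta >= 0) that[c1] = (1.0 - eta) * that[c1] + eta * (s2 == 0 ? 1.0 : 0.0);
      break;
    case 2:
      if (cue >= 0) qrc[cue][c1] = (1.0 - alpha) * qrc[cue][c1] + alpha * r;
      if (original) q2[s2][c2] = (1.0 - alpha2) * q2[s2][c2] + alpha2 * r;
      cue = (r ? 0 : 2) + s2;
      break;
    case 3: {
      // Bayes step on the outcome given the reached second-step state, then
      // mixing for the possibility that the world reversed between trials.
      double la = (s2 == 0) ? (r ? p_good : 1.0 - p_good) : (r ? p_bad : 1.0 - p_bad);
      double lb = (s2 == 0) ? (r ? p_bad : 1.0 - p_bad) : (r ? p_good : 1.0 - p_good);
      double num = post * la, den = num + (1.0 - post) * lb;
      if (den > 0) post = num / den;
      post = (1.0 - omega) * post + omega * (1.0 - post);
      if (original) q2[s2][c2] = (1.0 - alpha) * q2[s2][c2] + alpha * r;
      break;
    }
    case 4:
      if (original) q2[s2][c2] = (1.0 - alpha2) * q2[s2][c2] + alpha2 * r;
      cue = (r ? 0 : 2) + s2;
      break;
    case 6:
      q2[s2][c2] = (1.0 - alpha) * q2[s2][c2] + alpha * r;
      break;
    default: break;
    }
    last = c1;

    // ---- advance reward probabilities (trial end; simulation only) ----
    if (simulate) {
      if (tk.process == 0) {
        if (++block_phase >= tk.block_length) {
          std::swap(rp[0][0], rp[1][0]);
          block_phase = 0;
        }
      } else if (tk.process == 1) {
        for (int s = 0; s < 2; ++s)
          for (int j = 0; j < tk.n2; ++j)
            rp[s][j] = fold_reflect(rp[s][j] + tk.walk_sd * norm_rand(),
                                    tk.walk_lo, tk.walk_hi);
      }
    }
  }

  int n_obs = original ? 2 * n_trials : n_trials;
  if (simulate)
    return List::create(_["events"] = out, _["loglik"] = loglik, _["n_obs"] = n_obs);
  return List::create(_["loglik"] = loglik, _["n_obs"] = n_obs,
                      _["p1A"] = p1vec, _["trial_loglik"] = trial_ll);
}
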