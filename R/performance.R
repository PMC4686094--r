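# free parameters optimised for reward rate, per family; inverse
# temperatures are bounded at 50 via a scaled logistic transform since the
# simplex search is unconstrained
perf_family_spec <- function(family, task, lambda = NULL) {
  original <- task$variant == "original"
  rate <- list(to = plogis, init = function() qlogis(runif(1, 0.05, 0.95)))
  revp <- list(to = plogis, init = function() qlogis(runif(1, 0.005, 0.5)))
  temp <- list(to = function(z) 50 * plogis(z),
               init = function() qlogis(runif(1, 0.02, 0.6)))
  spec <- switch(family,
    q0 = list(pars = list(alpha = rate, T = temp),
              build = function(p) q_lambda_agent(p$alpha, p$T, lambda = 0)),
    q1 = list(pars = list(alpha = rate, T = temp),
              build = function(p) q_lambda_agent(p$alpha, p$T, lambda = 1)),
    q_lambda = {
      if (is.null(lambda)) stop("family 'q_lambda' needs a fixed lambda")
      list(pars = list(alpha = rate, T = temp),
           build = function(p) q_lambda_agent(p$alpha, p$T, lambda = lambda))
    },
    model_based = list(pars = list(alpha = rate, T = temp),
                       build = function(p) model_based_agent(p$alpha, p$T)),
    reward_as_cue = if (original) {
      list(pars = list(alpha = rate, T = temp, alpha2 = rate, T2 = temp),
           build = function(p) reward_as_cue_agent(p$alpha, p$T, p$alpha2, p$T2))
    } else {
      list(pars = list(alpha = rate, T = temp),
           build = function(p) reward_as_cue_agent(p$alpha, p$T))
    },
    latent_state = if (original) {
      list(pars = list(omega = revp, epsilon = rate, alpha = rate, T = temp),
           build = function(p) latent_state_agent(p$omega, p$epsilon,
                                                  alpha = p$alpha, T = p$T))
    } else {
      list(pars = list(omega = revp, epsilon = rate),
           build = function(p) latent_state_agent(p$omega, p$epsilon))
    },
    det_reward_as_cue = if (original) {
      list(pars = list(alpha2 = rate, T2 = temp),
           build = function(p) det_reward_as_cue_agent(p$alpha2, p$T2))
    } else {
      list(pars = list(), build = function(p) det_reward_as_cue_agent())
    },
    random = list(pars = list(), build = function(p) random_agent()),
    random_mf2 = list(pars = list(alpha = rate, T = temp),
                      build = function(p) random_mf2_agent(p$alpha, p$T)),
    stop("unknown performance family: ", family))
  spec$family <- family
  spec
}

#' Reward-rate objective
#'
#' Fraction of rewarded trials obtained by `agent` over one simulated
#' session. Deterministic in `(agent, task, seed)`: the same seed replays
#' the same stream of task and agent randomness, which is what makes
#' common-random-number optimisation possible.
#'
#' @param agent a `twostep_agent`.
#' @param task a [two_step_task()].
#' @param seed session seed.
#' @param n_trials session length.
#' @return Reward fraction in \[0, 1\].
#' @export
perf_objective <- function(agent, task, seed, n_trials = 10000L) {
  mean(run_session(agent, task, n_trials, seed)$outcome)
}

#' Optimise agent parameters for reward rate
#'
#' For each of `n_sessions` evaluation sessions, the family's parameters are
#' optimised by Nelder-Mead simplex search on the transformed parameter
#' space, with the random seed held fixed across objective evaluations
#' within an optimisation run (common random numbers) and `n_restarts`
#' randomised initial points per run. The best parameters found on the
#' optimisation seed are then re-evaluated on a fresh seed, and that value
#' is taken, guarding against overfitting to one random stream. Families
#' with no free parameters (the deterministic reward-as-cue policy on the
#' reduced task, and the random agent) are evaluated directly.
#'
#' @param family an agent family name (see [fit_ml()] plus
#'   `"det_reward_as_cue"`, `"random"`, `"random_mf2"`).
#' @param task a [two_step_task()].
#' @param n_restarts randomised restarts per optimisation run.
#' @param n_sessions number of evaluation sessions.
#' @param n_trials trials per session.
#' @param seed master seed (spawns optimisation and evaluation seeds).
#' @param lambda fixed eligibility trace for family `"q_lambda"`.
#' @param maxit maximum simplex iterations per restart.
#' @return A `twostep_perf` list: `family`, `mean` and `sem` of the reward
#'   fraction over evaluation sessions, `per_session` (data frame of
#'   optimised-seed and fresh-seed reward fractions plus fitted parameters),
#'   `n_sessions`, `n_trials`.
#' @export
optimise_performance <- function(family, task, n_restarts = 10L,
                                 n_sessions = 10L, n_trials = 10000L,
                                 seed = 1L, lambda = NULL, maxit = 300L) {
  spec <- perf_family_spec(family, task, lambda)
  set.seed(as.integer(seed))
  opt_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  eval_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  init_thetas <- lapply(seq_len(n_sessions * max(1L, n_restarts)), function(i)
    vapply(spec$pars, function(p) p$init(), numeric(1)))
  k <- length(spec$pars)
  rows <- lapply(seq_len(n_sessions), function(i) {
    if (k == 0L) {
      agent <- spec$build(list())
      perf_opt <- perf_objective(agent, task, opt_seeds[i], n_trials)
      theta_best <- numeric(0)
    } else {
      objective <- function(theta) {
        p <- spec_natural(spec, theta)
        -perf_objective(spec$build(p), task, opt_seeds[i], n_trials)
      }
      best <- NULL
      for (r in seq_len(n_restarts)) {
        theta0 <- init_thetas[[(i - 1L) * n_restarts + r]]
        opt <- optim(theta0, objective, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-5))
        if (is.null(best) || opt$value < best$value) best <- opt
      }
      theta_best <- best$par
      perf_opt <- -best$value
    }
    p <- spec_natural(spec, theta_best)
    perf_eval <- perf_objective(spec$build(p), task, eval_seeds[i], n_trials)
    c(list(session = i, perf_opt = perf_opt, perf = perf_eval), p)
  })
  per_session <- do.call(rbind, lapply(rows, as.data.frame))
  structure(list(
    family = family,
    mean = mean(per_session$perf),
    sem = sd(per_session$perf) / sqrt(n_sessions),
    per_session = per_session,
    n_sessions = n_sessions, n_trials = n_trials
  ), class = "twostep_perf")
}

#' Performance of the deterministic reward-as-cue policy
#'
#' Evaluates the fixed mapping "choose A after reward in state a or
#' non-reward in state b; choose B after reward in state b or non-reward in
#' state a". On the reduced task the policy has no free parameters and is
#' evaluated directly; on the original task its second-step learning
#' parameters are optimised first.
#'
#' @inheritParams optimise_performance
#' @return A `twostep_perf` (see [optimise_performance()]).
#' @export
det_reward_as_cue_performance <- function(task, n_sessions = 10L,
                                          n_trials = 10000L, seed = 1L,
                                          n_restarts = 10L) {
  optimise_performance("det_reward_as_cue", task, n_restarts = n_restarts,
                       n_sessions = n_sessions, n_trials = n_trials,
                       seed = seed)
}

#' @export
print.twostep_perf <- function(x, ...) {
  cat(sprintf(
    "Optimised performance, family %s: reward fraction %.3f +- %.3f (SEM, %d sessions x %d trials)\n",
    x$family, x$mean, x$sem, x$n_sessions, x$n_trials))
  invisible(x)
}
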