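#' Log-likelihood of recorded sessions under an agent
#'
#' Evaluates the summed log probability of the recorded choices under
#' `agent`, with the agent's internal state evolved on the recorded events
#' (not resampled ones). On the original task both first- and second-step
#' choices are modelled; on the reduced task only the first-step choice
#' exists. Evaluation uses the same compiled code path as simulation, so the
#' likelihood an agent assigns to a session it generated equals the sum of
#' the log choice probabilities recorded during generation.
#'
#' A recorded choice to which the agent assigns probability zero (possible
#' for the deterministic policies) yields `-Inf`, flagged by the
#' `"zero_prob"` attribute.
#'
#' @param agent a `twostep_agent`.
#' @param sessions a session or list of sessions.
#' @return Total log-likelihood, with attributes `n_obs` (number of modelled
#'   choices), `per_session` (per-session log-likelihoods) and `zero_prob`.
#' @examples
#' task <- two_step_task("reduced")
#' a <- q_lambda_agent(0.334, 3.22)
#' s <- run_session(a, task, 500, seed = 1)
#' session_log_likelihood(a, s)
#' attr(s, "loglik")  # identical: same code path
#' @export
session_log_likelihood <- function(agent, sessions) {
  sessions <- as_sessions(sessions)
  task <- attr(sessions[[1]], "task")
  par <- agent_par_vector(agent, task)
  per <- vapply(sessions, function(s) {
    engine_cpp(1L, agent$code, par, task_codes(task), 0L,
               session_events(s))$loglik
  }, numeric(1))
  n_obs <- sum(vapply(sessions, nrow, integer(1))) *
    (if (task$variant == "original") 2L else 1L)
  structure(sum(per), n_obs = n_obs, per_session = per,
            zero_prob = any(!is.finite(per)))
}

# replay a session, returning the agent's per-trial first-step choice
# probabilities on the recorded events
replay_choice_probs <- function(agent, session) {
  task <- attr(session, "task")
  engine_cpp(1L, agent$code, agent_par_vector(agent, task),
             task_codes(task), 0L, session_events(session))$p1A
}

# free-parameter specifications per fit family: transforms map the
# unconstrained optimisation space to natural parameters
fit_family_spec <- function(family, task, lambda = NULL) {
  original <- task$variant == "original"
  rate <- list(to = plogis, init = function() qlogis(runif(1, 0.05, 0.95)))
  revp <- list(to = plogis, init = function() qlogis(runif(1, 0.005, 0.5)))
  temp <- list(to = exp, init = function() log(runif(1, 0.5, 20)))
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
    stop("unknown fit family: ", family))
  spec$family <- family
  spec
}

spec_natural <- function(spec, theta) {
  p <- lapply(seq_along(spec$pars), function(i) spec$pars[[i]]$to(theta[i]))
  names(p) <- names(spec$pars)
  p
}

#' Maximum-likelihood fit of an agent family to sessions
#'
#' Optimises the family's free parameters over an unconstrained transformed
#' space (logistic transform for rates and probabilities, log transform for
#' inverse temperatures) by Nelder-Mead with `n_restarts` random starting
#' points, and reports the best restart. The eligibility trace of the
#' Q-lambda family is fixed per family (`q0`, `q1`, or `q_lambda` with a
#' given `lambda`), not estimated, so every reduced-task family has two free
#' parameters.
#'
#' @param family `"q0"`, `"q1"`, `"q_lambda"`, `"model_based"`,
#'   `"reward_as_cue"` or `"latent_state"`.
#' @param sessions a session or list of sessions.
#' @param n_restarts number of random restarts.
#' @param seed seed for the restart initial points.
#' @param lambda fixed eligibility trace for family `"q_lambda"`.
#' @param maxit maximum Nelder-Mead iterations per restart.
#' @param n_probe random candidate points evaluated per restart; the simplex
#'   starts from the best candidate. This guards against the plateaus that
#'   threshold-policy likelihoods (the latent-state agent) produce.
#' @return A `twostep_fit` list: `family`, `params` (fitted values on their
#'   natural scales), `loglik`, `n_obs`, `n_params`,
#'   `bic` (`n_params * log(n_obs) - 2 * loglik`), `restarts` (per-restart
#'   log-likelihoods and convergence codes) and `converged`.
#' @export
fit_ml <- function(family, sessions, n_restarts = 10L, seed = 1L,
                   lambda = NULL, maxit = 500L, n_probe = 15L) {
  sessions <- as_sessions(sessions)
  task <- attr(sessions[[1]], "task")
  spec <- fit_family_spec(family, task, lambda)
  events <- lapply(sessions, session_events)
  codes <- task_codes(task)
  negll <- function(theta) {
    p <- spec_natural(spec, theta)
    agent <- spec$build(p)
    par <- agent_par_vector(agent, task)
    ll <- sum(vapply(events, function(e)
      engine_cpp(1L, agent$code, par, codes, 0L, e)$loglik, numeric(1)))
    if (!is.finite(ll)) 1e12 else -ll
  }
  set.seed(as.integer(seed))
  restarts <- lapply(seq_len(n_restarts), function(r) {
    cands <- replicate(max(1L, n_probe),
                       vapply(spec$pars, function(p) p$init(), numeric(1)))
    cands <- matrix(cands, nrow = length(spec$pars))
    theta0 <- cands[, which.min(apply(cands, 2, negll))]
    opt <- optim(theta0, negll, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    list(theta = opt$par, loglik = -opt$value, convergence = opt$convergence)
  })
  lls <- vapply(restarts, `[[`, numeric(1), "loglik")
  conv <- vapply(restarts, `[[`, numeric(1), "convergence") == 0
  if (!any(is.finite(lls)))
    stop("all restarts failed to produce a finite likelihood for family ",
         family)
  best <- restarts[[which.max(lls)]]
  # The latent-state agent's threshold choice rule makes its likelihood a
  # step function of omega, with narrow ridges the simplex jumps across.
  # Polish the incumbent with dense coordinate-wise line searches at
  # shrinking spans before a final simplex pass.
  if (family == "latent_state") {
    theta <- best$theta
    fbest <- -best$loglik
    for (span in c(0.4, 0.06, 0.01)) {
      for (j in seq_along(theta)) {
        grid <- theta[j] + span * seq(-1, 1, length.out = 81L)
        vals <- vapply(grid, function(g) {
          th <- theta; th[j] <- g; negll(th)
        }, numeric(1))
        theta[j] <- grid[which.min(vals)]
        fbest <- min(vals)
      }
    }
    opt <- optim(theta, negll, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    if (opt$value < fbest) {
      theta <- opt$par
      fbest <- opt$value
    }
    if (-fbest > best$loglik)
      best <- list(theta = theta, loglik = -fbest,
                   convergence = best$convergence)
  }
  params <- spec_natural(spec, best$theta)
  n_obs <- sum(vapply(sessions, nrow, integer(1))) *
    (if (task$variant == "original") 2L else 1L)
  k <- length(spec$pars)
  structure(list(
    family = family,
    params = params,
    loglik = best$loglik,
    n_obs = n_obs,
    n_params = k,
    bic = k * log(n_obs) - 2 * best$loglik,
    restarts = data.frame(restart = seq_len(n_restarts), loglik = lls,
                          converged = conv),
    converged = conv[which.max(lls)],
    agent = spec$build(params)
  ), class = "twostep_fit")
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat("ML fit, family", x$family, "\n")
  cat("  params:", paste(names(x$params),
                         format(unlist(x$params), digits = 4),
                         sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  loglik %.2f on %d choices (%d params), BIC %.2f\n",
              x$loglik, x$n_obs, x$n_params, x$bic))
  if (!x$converged) cat("  warning: best restart did not converge\n")
  invisible(x)
}

#' Cross-fit likelihood matrix
#'
#' Fits every agent family to every labelled dataset and tabulates, per
#' (generator, fitter) cell, the mean per-session fitted log-likelihood with
#' its SEM across sessions, plus BIC, and paired t-tests between fitters of
#' the same dataset. Per-trial (geometric-mean) likelihoods are also
#' reported.
#'
#' @param datasets named list: each element a list of sessions simulated
#'   from one generating agent (the element name labels the generator).
#' @param families fit family names (see [fit_ml()]).
#' @param n_restarts restarts per fit.
#' @param seed seed for restart initial points.
#' @return A `twostep_crossfit` list with matrices `loglik` (generator x
#'   fitter, mean per-session log-likelihood), `sem`, `bic`,
#'   `per_trial_loglik`, the fitted objects in `fits`, and
#'   `pairwise_p[[generator]]` (paired t-tests between fitters).
#' @export
cross_fit_matrix <- function(datasets,
                             families = c("q0", "q1", "model_based",
                                          "reward_as_cue", "latent_state"),
                             n_restarts = 10L, seed = 1L) {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  gens <- names(datasets)
  loglik <- sem <- bic <- ptl <- matrix(
    NA_real_, length(gens), length(families),
    dimnames = list(generator = gens, fitter = families))
  fits <- list()
  per_session <- list()
  for (g in gens) {
    sess <- as_sessions(datasets[[g]])
    n_trials <- vapply(sess, nrow, integer(1))
    for (f in families) {
      fit <- fit_ml(f, sess, n_restarts = n_restarts, seed = seed)
      ll_per <- attr(session_log_likelihood(fit$agent, sess), "per_session")
      loglik[g, f] <- mean(ll_per)
      sem[g, f] <- sd(ll_per) / sqrt(length(ll_per))
      bic[g, f] <- fit$bic
      ptl[g, f] <- fit$loglik / fit$n_obs
      fits[[g]][[f]] <- fit
      per_session[[g]][[f]] <- ll_per
    }
  }
  pairwise_p <- lapply(per_session, function(ps) {
    m <- matrix(NA_real_, length(families), length(families),
                dimnames = list(families, families))
    for (i in seq_along(families))
      for (j in seq_along(families))
        if (i != j)
          m[i, j] <- stats::t.test(ps[[families[i]]], ps[[families[j]]],
                                   paired = TRUE)$p.value
    m
  })
  structure(list(loglik = loglik, sem = sem, bic = bic,
                 per_trial_loglik = ptl, fits = fits,
                 per_session = per_session, pairwise_p = pairwise_p),
            class = "twostep_crossfit")
}

#' @export
print.twostep_crossfit <- function(x, ...) {
  cat("Cross-fit mean per-session log-likelihood (generator x fitter):\n")
  print(round(x$loglik, 2))
  invisible(x)
}
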