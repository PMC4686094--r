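#' Agent constructors
#'
#' Each constructor returns a `twostep_agent` describing one behavioural
#' strategy. All agents expose choice probabilities at each step and a state
#' update applied at the end of each trial; the same compiled code path is
#' used for simulation and for likelihood evaluation on recorded events.
#'
#' * `q_lambda_agent()`: model-free Q-learning with eligibility trace
#'   `lambda`. `lambda = 1` updates the first-step value directly from the
#'   trial outcome; `lambda = 0` updates it from the second-step value.
#' * `model_based_agent()`: computes first-step action values afresh each
#'   trial as transition-weighted second-step state values (state value =
#'   single action value on the reduced task, max of the two action values on
#'   the original). `eta = NULL` uses the true transition matrix; a numeric
#'   `eta` learns it online by exponential moving average (initialised
#'   uniform at 0.5/0.5).
#' * `reward_as_cue_agent()`: treats the previous trial's (outcome,
#'   second-step state) pair as the decision state and learns separate
#'   first-step action values for each of the four cues, updated directly
#'   from the outcome. On trial 1 no cue exists: the choice is uniform and no
#'   first-step update is made. On the original task separate second-step
#'   learning rate/temperature apply.
#' * `latent_state_agent()`: believes the world is in one of two latent
#'   states (state a good, or state b good, with reward probabilities
#'   `p_good`/`p_bad`), performs a Bayesian update of the posterior after
#'   each trial allowing reversal probability `omega` between trials, and
#'   chooses the action favoured by the more probable state with probability
#'   `1 - epsilon`. `p_good`/`p_bad` default to 0.8/0.2 on the reduced task
#'   and 0.625/0.375 on the original (set at simulation/fit time if `NULL`).
#' * `det_reward_as_cue_agent()`: the deterministic reward-as-cue policy
#'   (choose A after reward in a or non-reward in b, B otherwise), used for
#'   performance evaluation.
#' * `random_agent()`: uniform choice at both steps.
#' * `random_mf2_agent()`: uniform at the first step, softmax Q-learning at
#'   the second step (original task only).
#'
#' A perseveration bias `perseveration` adds a transient bonus to the value
#' of the previously chosen first-step action inside the softmax only; it
#' never enters the value updates.
#'
#' @param alpha learning rate in \[0, 1\].
#' @param T softmax inverse temperature (>= 0).
#' @param lambda eligibility trace in \[0, 1\].
#' @param perseveration perseveration bias strength (>= 0).
#' @param eta transition learning rate in \[0, 1\], or `NULL` for the true
#'   transition matrix.
#' @param alpha2,T2 second-step learning rate and inverse temperature
#'   (original task); default to the first-step values.
#' @param omega per-trial latent-state reversal probability in \[0, 1\].
#' @param epsilon choice noise in \[0, 1\].
#' @param p_good,p_bad believed reward probabilities of the good and bad
#'   second-step state.
#' @return An object of class `twostep_agent`.
#' @examples
#' q_lambda_agent(alpha = 0.334, T = 3.22, lambda = 1)  # a Q(1) agent
#' model_based_agent(alpha = 0.5, T = 5)
#' latent_state_agent(omega = 0.0326, epsilon = 0.188)
#' @name agents
NULL

new_agent <- function(name, code, params) {
  structure(list(name = name, code = code, params = params),
            class = "twostep_agent")
}

check_unit <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(what, " must be a single value in [0, 1]")
  x
}
check_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(what, " must be a single non-negative value")
  x
}

#' @rdname agents
#' @export
q_lambda_agent <- function(alpha, T, lambda = 1, perseveration = 0) {
  check_unit(alpha, "alpha"); check_pos(T, "T")
  check_unit(lambda, "lambda"); check_pos(perseveration, "perseveration")
  new_agent("q_lambda", 0L, list(alpha = alpha, T = T, lambda = lambda,
                                 perseveration = perseveration))
}

#' @rdname agents
#' @export
model_based_agent <- function(alpha, T, eta = NULL, perseveration = 0) {
  check_unit(alpha, "alpha"); check_pos(T, "T")
  if (!is.null(eta)) check_unit(eta, "eta")
  check_pos(perseveration, "perseveration")
  new_agent("model_based", 1L, list(alpha = alpha, T = T, eta = eta,
                                    perseveration = perseveration))
}

#' @rdname agents
#' @export
reward_as_cue_agent <- function(alpha, T, alpha2 = alpha, T2 = T) {
  check_unit(alpha, "alpha"); check_pos(T, "T")
  check_unit(alpha2, "alpha2"); check_pos(T2, "T2")
  new_agent("reward_as_cue", 2L,
            list(alpha = alpha, T = T, alpha2 = alpha2, T2 = T2))
}

#' @rdname agents
#' @export
latent_state_agent <- function(omega, epsilon, p_good = NULL, p_bad = NULL,
                               alpha = 0.5, T = 5) {
  check_unit(omega, "omega"); check_unit(epsilon, "epsilon")
  if (!is.null(p_good)) check_unit(p_good, "p_good")
  if (!is.null(p_bad)) check_unit(p_bad, "p_bad")
  if (!is.null(p_good) && !is.null(p_bad) && p_good <= p_bad)
    stop("p_good must exceed p_bad")
  check_unit(alpha, "alpha"); check_pos(T, "T")
  new_agent("latent_state", 3L,
            list(omega = omega, epsilon = epsilon, p_good = p_good,
                 p_bad = p_bad, alpha = alpha, T = T))
}

#' @rdname agents
#' @export
det_reward_as_cue_agent <- function(alpha2 = 0.5, T2 = 5) {
  check_unit(alpha2, "alpha2"); check_pos(T2, "T2")
  new_agent("det_reward_as_cue", 4L, list(alpha2 = alpha2, T2 = T2))
}

#' @rdname agents
#' @export
random_agent <- function() new_agent("random", 5L, list())

#' @rdname agents
#' @export
random_mf2_agent <- function(alpha, T) {
  check_unit(alpha, "alpha"); check_pos(T, "T")
  new_agent("random_mf2", 6L, list(alpha = alpha, T = T))
}

#' Construct an agent by name
#'
#' String-addressable constructor for configuration and command-line use.
#'
#' @param name one of `"q_lambda"`, `"q0"`, `"q1"`, `"model_based"`,
#'   `"reward_as_cue"`, `"latent_state"`, `"det_reward_as_cue"`, `"random"`,
#'   `"random_mf2"`.
#' @param params named list of parameters passed to the constructor.
#' @return A `twostep_agent`.
#' @examples
#' make_agent("q1", list(alpha = 0.334, T = 3.22))
#' @export
make_agent <- function(name, params = list()) {
  switch(name,
    q_lambda = do.call(q_lambda_agent, params),
    q0 = do.call(q_lambda_agent, modifyList(params, list(lambda = 0))),
    q1 = do.call(q_lambda_agent, modifyList(params, list(lambda = 1))),
    model_based = do.call(model_based_agent, params),
    reward_as_cue = do.call(reward_as_cue_agent, params),
    latent_state = do.call(latent_state_agent, params),
    det_reward_as_cue = do.call(det_reward_as_cue_agent, params),
    random = random_agent(),
    random_mf2 = do.call(random_mf2_agent, params),
    stop("unknown agent name: ", name))
}

#' @export
print.twostep_agent <- function(x, ...) {
  ps <- x$params[!vapply(x$params, is.null, logical(1))]
  cat("Two-step agent:", x$name, "\n")
  if (length(ps))
    cat("  ", paste(names(ps), unlist(ps), sep = " = ", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# numeric parameter vector for the compiled engine; latent-state beliefs
# default per task variant when not given
agent_par_vector <- function(agent, task) {
  p <- agent$params
  switch(agent$name,
    q_lambda = c(p$alpha, p$T, p$lambda, p$perseveration),
    model_based = c(p$alpha, p$T, p$eta %||% -1, p$perseveration),
    reward_as_cue = c(p$alpha, p$T, p$alpha2, p$T2),
    latent_state = {
      original <- task$variant == "original"
      c(p$omega, p$epsilon,
        p$p_good %||% if (original) 0.625 else 0.8,
        p$p_bad %||% if (original) 0.375 else 0.2,
        p$alpha, p$T)
    },
    det_reward_as_cue = c(p$alpha2, p$T2),
    random = numeric(0),
    random_mf2 = c(p$alpha, p$T))
}

#' Softmax choice probabilities
#'
#' Overflow-safe softmax over action values at inverse temperature `T`, with
#' an optional additive per-action bias (used for the perseveration bonus,
#' which affects choice only and never the value updates).
#'
#' @param values numeric vector of action values (finite).
#' @param T inverse temperature (>= 0); `T = 0` gives uniform probabilities.
#' @param bias additive per-action bias, scalar or one value per action.
#' @return Probability vector summing to 1.
#' @examples
#' softmax_choice_probs(c(0.8, 0.2), T = 5)
#' @export
softmax_choice_probs <- function(values, T, bias = 0) {
  if (!all(is.finite(values))) stop("action values must be finite")
  check_pos(T, "T")
  z <- T * (values + bias)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Perseveration bonus
#'
#' Additive first-step bias of strength `p` on the action chosen on the
#' previous trial, zero elsewhere. Applied inside the softmax only.
#'
#' @param last_choice index of the previously chosen action, or `NA` on the
#'   first trial.
#' @param p bias strength (>= 0).
#' @param n_actions number of first-step actions.
#' @return Numeric bias vector.
#' @export
perseveration_bonus <- function(last_choice, p, n_actions = 2L) {
  check_pos(p, "p")
  b <- numeric(n_actions)
  if (!is.na(last_choice)) b[last_choice] <- p
  b
}

#' Q-lambda value update
#'
#' End-of-trial update for the Q-lambda family. The first-step value is
#' updated first, using the pre-update second-step value:
#' `Q1 <- (1 - alpha) Q1 + alpha (Q2 + lambda (r - Q2))`, then the
#' second-step value: `Q2 <- (1 - alpha) Q2 + alpha r`. Only chosen actions
#' change.
#'
#' @param values list with `q1` (length-2 numeric) and `q2` (2 x n matrix of
#'   second-step action values, states in rows).
#' @param choice1 first-step action index (1 = A, 2 = B).
#' @param second_state second-step state index (1 = a, 2 = b).
#' @param choice2 second-step action index.
#' @param outcome 0 or 1.
#' @param alpha learning rate.
#' @param lambda eligibility trace.
#' @return Updated `values` list.
#' @export
q_lambda_update <- function(values, choice1, second_state, choice2 = 1L,
                            outcome, alpha, lambda) {
  q2c <- values$q2[second_state, choice2]
  values$q1[choice1] <- (1 - alpha) * values$q1[choice1] +
    alpha * (q2c + lambda * (outcome - q2c))
  values$q2[second_state, choice2] <- (1 - alpha) * q2c + alpha * outcome
  values
}

#' Model-based first-step action values
#'
#' Transition-weighted second-step state values, recomputed at each trial
#' start: `Q1(i) = P(a|i) V(a) + P(b|i) V(b)`.
#'
#' @param v length-2 vector of second-step state values (state value is the
#'   single action value on the reduced task, the max of the two on the
#'   original).
#' @param t_hat length-2 vector `c(P(a|A), P(a|B))`; rows of the transition
#'   matrix are `(t_hat, 1 - t_hat)`.
#' @return Length-2 vector of first-step action values.
#' @examples
#' model_based_q1(c(0.8, 0.2), t_hat = c(0.8, 0.2))
#' @export
model_based_q1 <- function(v, t_hat) {
  stopifnot(length(v) == 2L, length(t_hat) == 2L,
            all(t_hat >= 0 & t_hat <= 1))
  c(t_hat[1] * v[1] + (1 - t_hat[1]) * v[2],
    t_hat[2] * v[1] + (1 - t_hat[2]) * v[2])
}

#' Online transition-probability update
#'
#' Exponential-moving-average update of the chosen action's transition
#' estimate towards the observed second-step state; the complementary entry
#' stays 1 minus the updated one, so rows remain stochastic.
#'
#' @param t_hat length-2 vector `c(P(a|A), P(a|B))`.
#' @param choice1 chosen first-step action index.
#' @param second_state observed second-step state index (1 = a, 2 = b).
#' @param eta transition learning rate in \[0, 1\].
#' @return Updated `t_hat`.
#' @export
transition_learning_update <- function(t_hat, choice1, second_state, eta) {
  check_unit(eta, "eta")
  x <- if (second_state == 1L) 1 else 0
  t_hat[choice1] <- (1 - eta) * t_hat[choice1] + eta * x
  t_hat
}

#' Latent-state Bayesian posterior update
#'
#' Two-hypothesis Bayes step on the trial outcome given the reached
#' second-step state (the transition itself is independent of the latent
#' state and cancels), followed by mixing for the possibility that the world
#' reversed between trials:
#' `posterior <- (1 - omega) posterior + omega (1 - posterior)`.
#'
#' @param posterior probability that state a is currently the good state.
#' @param second_state reached second-step state index (1 = a, 2 = b).
#' @param outcome 0 or 1.
#' @param p_good,p_bad believed reward probabilities.
#' @param omega per-trial reversal probability.
#' @return Updated posterior.
#' @examples
#' latent_state_update(0.5, second_state = 1, outcome = 1,
#'                     p_good = 0.8, p_bad = 0.2, omega = 0)
#' @export
latent_state_update <- function(posterior, second_state, outcome,
                                p_good, p_bad, omega) {
  check_unit(posterior, "posterior")
  la <- if (second_state == 1L) { if (outcome) p_good else 1 - p_good
        } else { if (outcome) p_bad else 1 - p_bad }
  lb <- if (second_state == 1L) { if (outcome) p_bad else 1 - p_bad
        } else { if (outcome) p_good else 1 - p_good }
  den <- posterior * la + (1 - posterior) * lb
  if (den > 0) posterior <- posterior * la / den
  (1 - omega) * posterior + omega * (1 - posterior)
}

#' Latent-state choice probabilities
#'
#' Probability `1 - epsilon` on the action with higher reward probability in
#' the more probable latent state, `epsilon` on the other; an exact
#' posterior tie gives 0.5 each.
#'
#' @param posterior probability that state a is the good state.
#' @param epsilon choice noise in \[0, 1\].
#' @return Length-2 vector `c(P(A), P(B))`.
#' @export
latent_state_choice_probs <- function(posterior, epsilon) {
  check_unit(posterior, "posterior"); check_unit(epsilon, "epsilon")
  pA <- if (posterior > 0.5) 1 - epsilon else if (posterior < 0.5) epsilon else 0.5
  c(pA, 1 - pA)
}
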