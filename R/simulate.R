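session_cols <- c("choice1", "transition", "second_state", "choice2",
                  "outcome", "rp_a1", "rp_b1", "rp_a2", "rp_b2",
                  "p1A", "p2_chosen", "q1A", "q1B", "posterior")

#' Simulate one session of an agent on a task
#'
#' Runs `n_trials` trials of `agent` on `task`, drawing all randomness from a
#' stream seeded with `seed`, so the session is fully reproducible. Reward
#' probabilities advance at the end of each trial, after the outcome draw.
#'
#' @param agent a `twostep_agent`.
#' @param task a [two_step_task()].
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed for the session's random stream.
#' @return A `twostep_session`: a data frame with one row per trial and
#'   columns `choice1` ("A"/"B"), `transition` ("common"/"rare"),
#'   `second_state` ("a"/"b"), `choice2` (second-step action, `NA` on the
#'   reduced task), `outcome` (0/1), the true reward probabilities in force
#'   on the trial (`rp_a1`, `rp_b1` and, on the original task, `rp_a2`,
#'   `rp_b2`), the agent's first-step probability of choosing A (`p1A`), the
#'   probability of the chosen second-step action (`p2_chosen`), the
#'   pre-choice first-step action values (`q1A`, `q1B`; value-based agents
#'   only) and the latent-state posterior (`posterior`; latent-state agent
#'   only). Agent, task, seed and the generated log-likelihood are stored as
#'   attributes.
#' @examples
#' task <- two_step_task("reduced")
#' s <- run_session(q_lambda_agent(0.334, 3.22), task, n_trials = 200, seed = 1)
#' head(s)
#' @export
run_session <- function(agent, task, n_trials, seed) {
  stopifnot(inherits(agent, "twostep_agent"), inherits(task, "twostep_task"),
            n_trials >= 1)
  seed <- as.integer(seed)
  set.seed(seed)
  res <- engine_cpp(0L, agent$code, agent_par_vector(agent, task),
                    task_codes(task), as.integer(n_trials))
  ev <- res$events
  colnames(ev) <- session_cols
  df <- as.data.frame(ev)
  df$choice1 <- c("A", "B")[df$choice1]
  df$transition <- ifelse(df$transition == 1, "common", "rare")
  df$second_state <- c("a", "b")[df$second_state]
  df$choice2 <- as.integer(df$choice2)
  df$outcome <- as.integer(df$outcome)
  structure(df,
            agent = agent, task = task, seed = seed,
            n_trials = as.integer(n_trials), loglik = res$loglik,
            class = c("twostep_session", "data.frame"))
}

#' Simulate a batch of sessions
#'
#' Runs `n_sessions` independent sessions. A master `seed` deterministically
#' spawns one seed per session; alternatively pass `seeds` explicitly
#' (duplicates are rejected).
#'
#' @param agent a `twostep_agent`.
#' @param task a [two_step_task()].
#' @param n_sessions number of sessions.
#' @param n_trials trials per session.
#' @param seed master seed used to spawn per-session seeds.
#' @param seeds optional explicit integer vector of per-session seeds.
#' @return A `twostep_sessions` list of [run_session()] results.
#' @export
run_batch <- function(agent, task, n_sessions = 10L, n_trials = 10000L,
                      seed = 1L, seeds = NULL) {
  if (is.null(seeds)) {
    set.seed(as.integer(seed))
    seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  }
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds)) stop("per-session seeds must be distinct")
  if (length(seeds) != n_sessions)
    stop("need exactly one seed per session")
  out <- lapply(seeds, function(s) run_session(agent, task, n_trials, s))
  structure(out, class = "twostep_sessions")
}

# accept a single session or a list of sessions everywhere downstream
as_sessions <- function(sessions) {
  if (inherits(sessions, "twostep_session")) return(list(sessions))
  if (!is.list(sessions) || !all(vapply(sessions, inherits, logical(1),
                                        "twostep_session")))
    stop("expected a twostep_session or a list of them")
  sessions
}

#' @export
print.twostep_session <- function(x, ...) {
  a <- attr(x, "agent"); tk <- attr(x, "task")
  cat(sprintf("Two-step session: %d trials, agent %s, %s task, seed %d\n",
              nrow(x), a$name, tk$variant, attr(x, "seed")))
  cat(sprintf("  reward fraction %.3f\n", mean(x$outcome)))
  invisible(x)
}

#' Reward fraction of sessions
#'
#' Mean fraction of rewarded trials, with the standard error of the mean
#' across sessions.
#'
#' @param sessions a session or list of sessions.
#' @return A list with `mean`, `sem` and `per_session`.
#' @export
reward_fraction <- function(sessions) {
  sessions <- as_sessions(sessions)
  per <- vapply(sessions, function(s) mean(s$outcome), numeric(1))
  list(mean = mean(per),
       sem = if (length(per) > 1) sd(per) / sqrt(length(per)) else NA_real_,
       per_session = per)
}

# events matrix (numeric, engine column order) from a session
session_events <- function(session) {
  m <- matrix(NA_real_, nrow(session), length(session_cols),
              dimnames = list(NULL, session_cols))
  m[, "choice1"] <- match(session$choice1, c("A", "B"))
  m[, "transition"] <- as.numeric(session$transition == "common")
  m[, "second_state"] <- match(session$second_state, c("a", "b"))
  m[, "choice2"] <- session$choice2
  m[, "outcome"] <- session$outcome
  for (cn in c("rp_a1", "rp_b1", "rp_a2", "rp_b2", "p1A", "p2_chosen",
               "q1A", "q1B", "posterior"))
    if (cn %in% names(session)) m[, cn] <- session[[cn]]
  m
}
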