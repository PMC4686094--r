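# common task configurations used across tests
reduced_task <- function(...) two_step_task("reduced", ...)
original_task <- function(...) two_step_task("original", ...)

# a hand-buildable session from explicit per-trial vectors (reduced task)
manual_session <- function(choice1, transition, outcome, task = reduced_task(),
                           rp_a1 = 0.8, rp_b1 = 0.2) {
  second_state <- ifelse((choice1 == "A") == (transition == "common"), "a", "b")
  n <- length(choice1)
  df <- data.frame(choice1 = choice1, transition = transition,
                   second_state = second_state, choice2 = NA_integer_,
                   outcome = as.integer(outcome),
                   rp_a1 = rep_len(rp_a1, n), rp_b1 = rep_len(rp_b1, n),
                   rp_a2 = NA_real_, rp_b2 = NA_real_,
                   p1A = NA_real_, p2_chosen = NA_real_,
                   q1A = NA_real_, q1B = NA_real_, posterior = NA_real_)
  structure(df, agent = q_lambda_agent(0.5, 1), task = task, seed = 0L,
            n_trials = n, class = c("twostep_session", "data.frame"))
}
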