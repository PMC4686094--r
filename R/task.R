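#' Define a two-step task
#'
#' Constructs the generative model of a two-step decision task. On each trial
#' a first-step choice between actions A and B leads, via a common or rare
#' transition, to second-step state a or b, where reward is delivered
#' stochastically. Two variants are supported:
#'
#' * `"original"`: common-transition probability 0.7, two actions in each
#'   second-step state, reward probabilities drifting as reflecting Gaussian
#'   random walks on \[0.25, 0.75\] with per-trial step SD 0.025.
#' * `"reduced"`: common-transition probability 0.8, a single action per
#'   second-step state, reward probabilities alternating between 0.8/0.2 and
#'   0.2/0.8 in states a/b every 50 trials.
#'
#' The reward process can be overridden on either variant: `"blocks"`
#' (alternating fixed blocks), `"random_walk"` (independent reflecting
#' Gaussian walks; on the reduced variant the default walk is on \[0, 1\] with
#' step SD 0.1), or `"fixed"` (static probabilities).
#'
#' @param variant `"reduced"` or `"original"`.
#' @param reward_process `"blocks"`, `"random_walk"` or `"fixed"`. Defaults to
#'   `"blocks"` for the reduced task and `"random_walk"` for the original.
#' @param p_common probability of a common transition. Defaults 0.8 (reduced)
#'   and 0.7 (original).
#' @param block_length trials per reward block (blocks process).
#' @param block_probs length-2 vector: reward probability in the good and bad
#'   second-step state during a block.
#' @param walk_bounds length-2 vector of reflecting bounds for the random
#'   walk. Defaults `c(0.25, 0.75)` (original) and `c(0, 1)` (reduced walk).
#' @param walk_sd per-trial Gaussian step standard deviation. Defaults 0.025
#'   (original) and 0.1 (reduced walk).
#' @param fixed_probs length-2 vector of static reward probabilities in
#'   states a and b (fixed process).
#' @return An object of class `twostep_task`.
#' @examples
#' two_step_task("reduced")
#' two_step_task("reduced", reward_process = "fixed", fixed_probs = c(0.5, 0.5))
#' two_step_task("original")
#' @export
two_step_task <- function(variant = c("reduced", "original"),
                          reward_process = NULL,
                          p_common = NULL,
                          block_length = 50L,
                          block_probs = c(0.8, 0.2),
                          walk_bounds = NULL,
                          walk_sd = NULL,
                          fixed_probs = c(0.8, 0.2)) {
  variant <- match.arg(variant)
  original <- variant == "original"
  reward_process <- match.arg(reward_process %||%
                                if (original) "random_walk" else "blocks",
                              c("blocks", "random_walk", "fixed"))
  p_common <- p_common %||% if (original) 0.7 else 0.8
  walk_bounds <- walk_bounds %||% if (original) c(0.25, 0.75) else c(0, 1)
  walk_sd <- walk_sd %||% if (original) 0.025 else 0.1

  stopifnot(is.numeric(p_common), length(p_common) == 1L,
            p_common >= 0, p_common <= 1,
            length(block_probs) == 2L, all(block_probs >= 0 & block_probs <= 1),
            length(fixed_probs) == 2L, all(fixed_probs >= 0 & fixed_probs <= 1),
            length(walk_bounds) == 2L, all(walk_bounds >= 0 & walk_bounds <= 1),
            is.numeric(walk_sd), walk_sd >= 0)
  if (walk_bounds[1] >= walk_bounds[2])
    stop("walk_bounds lower bound must be below the upper bound")
  block_length <- as.integer(block_length)
  if (block_length < 1L) stop("block_length must be >= 1")

  task <- structure(list(
    variant = variant,
    reward_process = reward_process,
    p_common = p_common,
    block_length = block_length,
    block_probs = block_probs,
    walk_bounds = walk_bounds,
    walk_sd = walk_sd,
    fixed_probs = fixed_probs,
    n_second_actions = if (original) 2L else 1L
  ), class = "twostep_task")
  task
}

#' @export
print.twostep_task <- function(x, ...) {
  cat("Two-step task (", x$variant, " variant)\n", sep = "")
  cat("  common transition probability:", x$p_common, "\n")
  cat("  second-step actions per state:", x$n_second_actions, "\n")
  desc <- switch(x$reward_process,
    blocks = sprintf("blocks of %d trials, reward probs %s/%s",
                     x$block_length, x$block_probs[1], x$block_probs[2]),
    random_walk = sprintf("reflecting Gaussian walk on [%s, %s], step sd %s",
                          x$walk_bounds[1], x$walk_bounds[2], x$walk_sd),
    fixed = sprintf("fixed reward probs %s/%s in states a/b",
                    x$fixed_probs[1], x$fixed_probs[2]))
  cat("  reward process:", desc, "\n")
  invisible(x)
}

# integer-coded task description for the compiled engine
task_codes <- function(task) {
  list(variant_code = if (task$variant == "original") 1L else 0L,
       p_common = task$p_common,
       process_code = match(task$reward_process,
                            c("blocks", "random_walk", "fixed")) - 1L,
       block_length = task$block_length,
       block_hi = task$block_probs[1], block_lo = task$block_probs[2],
       walk_lo = task$walk_bounds[1], walk_hi = task$walk_bounds[2],
       walk_sd = task$walk_sd,
       fixed_a = task$fixed_probs[1], fixed_b = task$fixed_probs[2],
       n_second_actions = task$n_second_actions)
}

#' Initialise the reward-probability state of a task
#'
#' Draws the initial per-trial reward probabilities: for the blocks process
#' the first block's good state is chosen at random; for the random-walk
#' process each walk starts uniformly within its bounds; for the fixed
#' process the configured probabilities are used.
#'
#' @param task a [two_step_task()].
#' @return A list with `trial_index`, `reward_probs` (2 states x actions
#'   matrix) and `block_phase` (trials since the last reversal).
#' @export
init_task_state <- function(task) {
  n2 <- task$n_second_actions
  rp <- matrix(NA_real_, 2L, n2, dimnames = list(c("a", "b"), NULL))
  if (task$reward_process == "blocks") {
    good <- if (runif(1) < 0.5) 1L else 2L
    rp[good, ] <- task$block_probs[1]
    rp[-good, ] <- task$block_probs[2]
  } else if (task$reward_process == "random_walk") {
    rp[] <- runif(2L * n2, task$walk_bounds[1], task$walk_bounds[2])
  } else {
    rp[1, ] <- task$fixed_probs[1]
    rp[2, ] <- task$fixed_probs[2]
  }
  list(trial_index = 0L, reward_probs = rp, block_phase = 0L)
}

#' Sample a first-step transition
#'
#' Draws the second-step state reached after a first-step choice. A common
#' transition (probability `p_common`) maps A to a and B to b; a rare
#' transition maps to the opposite state.
#'
#' @param choice1 `"A"` or `"B"`.
#' @param p_common probability of a common transition.
#' @return A list with `second_state` (`"a"` or `"b"`) and `transition`
#'   (`"common"` or `"rare"`).
#' @examples
#' set.seed(1)
#' sample_transition("A", p_common = 0.8)
#' @export
sample_transition <- function(choice1, p_common) {
  if (!is.character(choice1) || length(choice1) != 1L || !choice1 %in% c("A", "B"))
    stop('choice1 must be "A" or "B"')
  stopifnot(p_common >= 0, p_common <= 1)
  common <- runif(1) < p_common
  same <- c(A = "a", B = "b")[[choice1]]
  other <- setdiff(c("a", "b"), same)
  list(second_state = if (common) same else other,
       transition = if (common) "common" else "rare")
}

#' Sample a trial outcome
#'
#' Bernoulli reward draw using the reward probability currently in force for
#' the reached second-step state and chosen second-step action.
#'
#' @param task_state state from [init_task_state()] / [advance_reward_probs()].
#' @param second_state `"a"` or `"b"`.
#' @param choice2 second-step action index (1 on the reduced task).
#' @return 0 or 1.
#' @export
sample_outcome <- function(task_state, second_state, choice2 = 1L) {
  s <- match(second_state, c("a", "b"))
  if (is.na(s)) stop('second_state must be "a" or "b"')
  if (choice2 < 1L || choice2 > ncol(task_state$reward_probs))
    stop("choice2 out of range for this task variant")
  as.integer(runif(1) < task_state$reward_probs[s, choice2])
}

#' Advance the reward probabilities by one trial
#'
#' Applied at the end of each trial, after the outcome draw. Blocks flip the
#' good and bad state exactly every `block_length` trials; random walks take
#' independent Gaussian steps folded back into the bounds (reflection applied
#' repeatedly if a step overshoots both bounds); fixed probabilities never
#' change.
#'
#' @param task_state state from [init_task_state()].
#' @param task a [two_step_task()].
#' @return The updated task state.
#' @export
advance_reward_probs <- function(task_state, task) {
  task_state$trial_index <- task_state$trial_index + 1L
  if (task$reward_process == "blocks") {
    task_state$block_phase <- task_state$block_phase + 1L
    if (task_state$block_phase >= task$block_length) {
      task_state$reward_probs <- task_state$reward_probs[2:1, , drop = FALSE]
      rownames(task_state$reward_probs) <- c("a", "b")
      task_state$block_phase <- 0L
    }
  } else if (task$reward_process == "random_walk") {
    rp <- task_state$reward_probs
    step <- rnorm(length(rp), 0, task$walk_sd)
    task_state$reward_probs[] <- vapply(rp + step, fold_reflect_cpp,
                                        numeric(1),
                                        lo = task$walk_bounds[1],
                                        hi = task$walk_bounds[2])
  }
  task_state
}
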