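#' Reference agent parameter sets
#'
#' Parameter values that make the average behaviour of the different agent
#' families comparable: the model-based agent uses `alpha = 0.5, T = 5`, and
#' every other family's parameters are the maximum-likelihood fit of that
#' family to data simulated from the model-based agent on the same task
#' (reproducible with [fit_ml()]; see the package vignette).
#'
#' @param variant `"reduced"` or `"original"`.
#' @return Named list of agent constructors' argument lists, keyed by family.
#' @export
matched_agent_params <- function(variant = c("reduced", "original")) {
  variant <- match.arg(variant)
  if (variant == "reduced") {
    list(
      q0 = list(alpha = 0.501, T = 2.96),
      q1 = list(alpha = 0.334, T = 3.22),
      q_lambda_0.25 = list(alpha = 0.499, T = 3.48, lambda = 0.25),
      q_lambda_0.5 = list(alpha = 0.477, T = 3.57, lambda = 0.5),
      q_lambda_0.75 = list(alpha = 0.409, T = 3.42, lambda = 0.75),
      model_based = list(alpha = 0.5, T = 5),
      reward_as_cue = list(alpha = 0.00344, T = 4.46),
      latent_state = list(omega = 0.0326, epsilon = 0.188)
    )
  } else {
    list(
      q0 = list(alpha = 0.384, T = 4.09),
      q1 = list(alpha = 0.398, T = 2.72),
      model_based = list(alpha = 0.5, T = 5),
      reward_as_cue = list(alpha = 0.00184, T = 4.82,
                           alpha2 = 0.499, T2 = 4.98),
      latent_state = list(omega = 0.0882, epsilon = 0.368,
                          alpha = 0.509, T = 4.96)
    )
  }
}

matched_agent <- function(family, variant) {
  params <- matched_agent_params(variant)[[family]]
  if (is.null(params)) stop("no reference parameters for family ", family,
                            " on the ", variant, " task")
  name <- if (startsWith(family, "q_lambda")) "q_lambda" else family
  make_agent(name, params)
}

experiment_registry <- function() {
  list(
    stay_tables = list(
      description = "Stay-probability tables for Q(1) and model-based agents on both task variants",
      run = function(seed, n_sessions, n_trials, ...) {
        out <- list()
        for (variant in c("original", "reduced")) {
          task <- two_step_task(variant)
          for (fam in c("q1", "model_based")) {
            sess <- run_batch(matched_agent(fam, variant), task,
                              n_sessions, n_trials, seed = seed)
            out[[paste(variant, fam, "stay", sep = "_")]] <-
              as.data.frame(stay_table(sess))
          }
        }
        out
      }),
    confound_correction = list(
      description = "Q(1) reduced-task regression with and without the correct predictor, trial-start values, predictor correlations",
      run = function(seed, n_sessions, n_trials, ...) {
        task <- two_step_task("reduced")
        sess <- run_batch(matched_agent("q1", "reduced"), task,
                          n_sessions, n_trials, seed = seed)
        list(
          regression_4pred = as.data.frame(fit_choice_regression(sess)),
          regression_5pred = as.data.frame(fit_choice_regression(
            sess, c("outcome", "transition", "interaction", "correct_binary"))),
          trial_start_values = trial_start_value_table(sess),
          predictor_correlation = as.data.frame(predictor_correlation(sess)))
      }),
    reduced_task_grid = list(
      description = "Five agent families x four analyses on the reduced task",
      run = function(seed, n_sessions, n_trials, n_lags = 12L, ...) {
        task <- two_step_task("reduced")
        out <- list()
        for (fam in c("q1", "model_based", "q0", "reward_as_cue",
                      "latent_state")) {
          sess <- run_batch(matched_agent(fam, "reduced"), task,
                            n_sessions, n_trials, seed = seed)
          out[[paste0(fam, "_stay")]] <- as.data.frame(stay_table(sess))
          out[[paste0(fam, "_regression")]] <-
            as.data.frame(fit_choice_regression(sess))
          out[[paste0(fam, "_regression_corrected")]] <-
            as.data.frame(fit_choice_regression(
              sess, c("outcome", "transition", "interaction",
                      "correct_binary")))
          out[[paste0(fam, "_lagged")]] <-
            as.data.frame(fit_lagged_regression(sess, n_lags))
        }
        out
      }),
    performance_comparison = list(
      description = "Optimised reward fraction for all agent families on both task variants",
      run = function(seed, n_sessions, n_trials, n_restarts = 10L, ...) {
        out <- list()
        for (variant in c("original", "reduced")) {
          task <- two_step_task(variant)
          fams <- c("q1", "q0", "model_based", "latent_state",
                    "det_reward_as_cue", "random")
          rows <- lapply(fams, function(f) {
            pr <- optimise_performance(f, task, n_restarts = n_restarts,
                                       n_sessions = n_sessions,
                                       n_trials = n_trials, seed = seed)
            data.frame(family = f, mean = pr$mean, sem = pr$sem)
          })
          out[[paste0(variant, "_performance")]] <- do.call(rbind, rows)
        }
        out
      }),
    crossfit_matrix = list(
      description = "Cross-fit likelihood matrix on the reduced task",
      run = function(seed, n_sessions, n_trials, n_restarts = 10L, ...) {
        task <- two_step_task("reduced")
        gens <- c("q0", "q1", "model_based", "reward_as_cue", "latent_state")
        datasets <- lapply(gens, function(fam)
          run_batch(matched_agent(fam, "reduced"), task, n_sessions,
                    n_trials, seed = seed))
        names(datasets) <- gens
        cf <- cross_fit_matrix(datasets, n_restarts = n_restarts, seed = seed)
        list(loglik = as.data.frame(cf$loglik),
             sem = as.data.frame(cf$sem),
             per_trial_loglik = as.data.frame(cf$per_trial_loglik))
      }),
    walk_correction = list(
      description = "Q(1) on the reduced random-walk variant: binary vs continuous correct predictors",
      run = function(seed, n_sessions, n_trials, ...) {
        task <- two_step_task("reduced", reward_process = "random_walk")
        sess <- run_batch(matched_agent("q1", "reduced"), task,
                          n_sessions, n_trials, seed = seed)
        list(
          regression_binary = as.data.frame(fit_choice_regression(
            sess, c("outcome", "transition", "interaction", "correct_binary"))),
          regression_continuous = as.data.frame(fit_choice_regression(
            sess, c("outcome", "transition", "interaction",
                    "correct_continuous"))))
      })
  )
}

#' List available experiment recipes
#'
#' @return Data frame of experiment names and descriptions.
#' @export
list_experiments <- function() {
  reg <- experiment_registry()
  data.frame(name = names(reg),
             description = vapply(reg, `[[`, "", "description"),
             row.names = NULL)
}

#' Run a named experiment recipe
#'
#' Regenerates a figure/table-level result from a single call. Each recipe
#' simulates the sessions it needs, runs the analyses, and returns (and
#' optionally writes) plain tab-separated tables together with a provenance
#' manifest recording the recipe, seed and problem sizes.
#'
#' @param name an experiment name from [list_experiments()].
#' @param seed master seed.
#' @param n_sessions,n_trials simulation scale (defaults 10 x 10000).
#' @param out_dir optional directory; if given, every result table is
#'   written as `<name>_<table>.tsv` plus a `MANIFEST` file.
#' @param ... further recipe-specific settings (`n_lags`, `n_restarts`).
#' @return Named list of result data frames, invisibly if `out_dir` is set.
#' @export
run_experiment <- function(name, seed = 1L, n_sessions = 10L,
                           n_trials = 10000L, out_dir = NULL, ...) {
  reg <- experiment_registry()
  if (!name %in% names(reg))
    stop("unknown experiment '", name, "'; see list_experiments()")
  res <- reg[[name]]$run(seed = seed, n_sessions = n_sessions,
                         n_trials = n_trials, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tab in names(res))
      utils::write.table(res[[tab]],
                         file.path(out_dir, paste0(name, "_", tab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("experiment: %s", name),
                 sprintf("seed: %d", as.integer(seed)),
                 sprintf("n_sessions: %d", as.integer(n_sessions)),
                 sprintf("n_trials: %d", as.integer(n_trials)),
                 sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("tables: %s", paste(names(res), collapse = ", "))),
               file.path(out_dir, paste0(name, "_MANIFEST")))
    return(invisible(res))
  }
  res
}
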