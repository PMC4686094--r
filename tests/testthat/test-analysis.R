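test_that("stay table matches a hand count on a constructed session", {
  # 6 trials; trials 2..6 classified by trial 1..5's (transition, outcome)
  s <- manual_session(
    choice1 = c("A", "A", "B", "A", "B", "A"),
    transition = c("common", "rare", "common", "common", "rare", "common"),
    outcome = c(1, 0, 1, 0, 1, 1))
  st <- stay_table(s)
  pick <- function(tr, out) st$mean[st$transition == tr & st$outcome == out]
  expect_equal(pick("common", "rewarded"), mean(c(TRUE, FALSE)))   # t2 stays, t4 switches
  expect_equal(pick("rare", "non-rewarded"), 0)                    # t3 switches
  expect_equal(pick("common", "non-rewarded"), 0)                  # t5 switches
  expect_equal(pick("rare", "rewarded"), 0)                        # t6 switches
})

test_that("an always-staying agent has stay probability 1 in every cell", {
  task <- two_step_task("reduced")
  s <- run_session(q_lambda_agent(0.3, 5, 1, perseveration = 500), task,
                   400, seed = 1)
  st <- stay_table(s)
  expect_equal(st$mean, rep(1, 4))
})

test_that("design codings follow the stated predictor definitions", {
  s <- manual_session(
    choice1 = c("A", "B", "B"),
    transition = c("common", "rare", "common"),
    outcome = c(1, 0, 1),
    rp_a1 = 0.8, rp_b1 = 0.2)
  d <- build_design(s, c("outcome", "transition", "interaction",
                         "correct_binary", "correct_continuous",
                         "rewarded_common", "nonrewarded_rare"))
  X <- d$X
  # trial 1 was rewarded-common: outcome, transition, interaction all +0.5
  expect_equal(unname(X[1, c("outcome", "transition", "interaction")]),
               c(0.5, 0.5, 0.5))
  expect_equal(unname(X[1, "rewarded_common"]), 0.5)
  expect_equal(unname(X[1, "nonrewarded_rare"]), 0)
  # trial 2 was non-rewarded-rare: interaction +0.5 again, transition -0.5
  expect_equal(unname(X[2, c("outcome", "transition", "interaction")]),
               c(-0.5, -0.5, 0.5))
  expect_equal(unname(X[2, "nonrewarded_rare"]), 0.5)
  # correct predictors: probs (0.8, 0.2); choosing A is correct (+0.5, +0.6)
  expect_equal(unname(X[1, "correct_binary"]), 0.5)
  expect_equal(unname(X[1, "correct_continuous"]), 0.6)
  expect_equal(unname(X[2, "correct_binary"]), -0.5)  # previous choice was B
  expect_equal(unname(X[2, "correct_continuous"]), -0.6)
  # response: trial 2 switched (A -> B), trial 3 stayed
  expect_equal(d$y, c(FALSE, TRUE))
  # equal fixed probabilities make the continuous correct predictor vanish
  s2 <- manual_session(c("A", "B", "A"), rep("common", 3), c(1, 0, 1),
                       task = two_step_task("reduced",
                                            reward_process = "fixed",
                                            fixed_probs = c(0.5, 0.5)),
                       rp_a1 = 0.5, rp_b1 = 0.5)
  d2 <- build_design(s2, c("correct_continuous"))
  expect_true(all(d2$X[, "correct_continuous"] == 0))
})

test_that("choice regression recovers the coefficients of a known rule", {
  # sessions whose stay/switch decisions follow a known logistic rule of the
  # previous trial's events
  beta <- c(stay = 0.4, outcome = 1.2, transition = -0.3, interaction = 0.8)
  set.seed(3)
  make_session <- function(n) {
    choice1 <- character(n); transition <- character(n); outcome <- integer(n)
    choice1[1] <- "A"
    transition <- sample(c("common", "rare"), n, TRUE, c(0.8, 0.2))
    outcome <- rbinom(n, 1, 0.5)
    for (t in 2:n) {
      x <- c(1,
             ifelse(outcome[t - 1] == 1, 0.5, -0.5),
             ifelse(transition[t - 1] == "common", 0.5, -0.5),
             ifelse((transition[t - 1] == "common") == (outcome[t - 1] == 1),
                    0.5, -0.5))
      stay <- runif(1) < plogis(sum(beta * x))
      choice1[t] <- if (stay) choice1[t - 1] else setdiff(c("A", "B"),
                                                          choice1[t - 1])
    }
    manual_session(choice1, transition, outcome)
  }
  sessions <- lapply(1:5, function(i) make_session(4000))
  fit <- fit_choice_regression(sessions)
  expect_equal(fit$mean, unname(beta), tolerance = 0.15)
  for (j in seq_len(4))
    expect_lt(abs(fit$mean[j] - beta[j]), 3 * max(fit$sem[j], 0.02))
})

test_that("the saturated one-back model reproduces the stay table exactly", {
  task <- two_step_task("reduced")
  s <- run_session(q_lambda_agent(0.334, 3.22), task, 3000, seed = 5)
  d <- build_design(s, c("outcome", "transition", "interaction"))
  fit <- glm.fit(d$X, d$y, family = binomial())
  st <- stay_table(s)
  # fitted probability in each (transition, outcome) cell = empirical stay rate
  cell_x <- function(tr, out) c(1, ifelse(out == "rewarded", 0.5, -0.5),
                                ifelse(tr == "common", 0.5, -0.5),
                                ifelse((tr == "common") == (out == "rewarded"),
                                       0.5, -0.5))
  for (i in seq_len(nrow(st))) {
    pred <- plogis(sum(fit$coefficients *
                         cell_x(st$transition[i], st$outcome[i])))
    expect_equal(pred, st$mean[i], tolerance = 1e-8)
  }
})

test_that("adding the correct predictor never increases the deviance", {
  task <- two_step_task("reduced")
  for (seed in 1:3) {
    s <- run_session(q_lambda_agent(0.334, 3.22), task, 2000, seed = seed)
    d4 <- build_design(s, c("outcome", "transition", "interaction"))
    d5 <- build_design(s, c("outcome", "transition", "interaction",
                            "correct_binary"))
    dev4 <- glm.fit(d4$X, d4$y, family = binomial())$deviance
    dev5 <- glm.fit(d5$X, d5$y, family = binomial())$deviance
    expect_lte(dev5, dev4 + 1e-8)
  }
})

test_that("lagged regression: reward-as-cue influence is confined to lag 1", {
  task <- two_step_task("reduced")
  sess <- run_batch(reward_as_cue_agent(0.00344, 4.46), task, 6, 4000,
                    seed = 6)
  fit <- fit_lagged_regression(sess, n_lags = 4)
  lag1 <- fit[grepl("_lag1$", fit$predictor), ]
  later <- fit[grepl("_lag[234]$", fit$predictor), ]
  # strong, significant lag-1 loadings with the sign pattern of the policy
  expect_gt(lag1$mean[lag1$predictor == "rewarded_common_lag1"], 0.5)
  expect_lt(lag1$mean[lag1$predictor == "nonrewarded_common_lag1"], -0.5)
  expect_true(all(lag1$p < 0.01))
  # and the policy's full sign pattern: repeat after rewarded-common and
  # non-rewarded-rare, switch after the other two event types
  lag1_mean <- setNames(lag1$mean, lag1$predictor)
  expect_gt(lag1_mean[["rewarded_common_lag1"]], 0.5)
  expect_gt(lag1_mean[["nonrewarded_rare_lag1"]], 0.5)
  expect_lt(lag1_mean[["rewarded_rare_lag1"]], -0.5)
  # beyond lag 1 nothing is materially non-zero
  expect_lt(max(abs(later$mean)), 0.25 * min(abs(lag1$mean)))
})

test_that("trial-start value table exposes the value confound and its controls", {
  # alpha = 0: values never leave their initialisation
  task <- two_step_task("reduced")
  s <- run_session(q_lambda_agent(0, 3.22), task, 500, seed = 7)
  vt <- trial_start_value_table(s)
  expect_true(all(vt$q_chosen == 0.5 & vt$q_unchosen == 0.5))
  # blocks: chosen-minus-unchosen larger on common-rewarded / rare-non-rewarded
  sess <- run_batch(q_lambda_agent(0.334, 3.22), task, 6, 5000, seed = 8)
  vt <- trial_start_value_table(sess)
  dq <- vt$q_chosen - vt$q_unchosen
  names(dq) <- paste(vt$transition, vt$outcome)
  expect_gt(mean(dq[c("common rewarded", "rare non-rewarded")]),
            mean(dq[c("rare rewarded", "common non-rewarded")]))
  # equal fixed probabilities abolish the difference between the cell pairs
  fx <- two_step_task("reduced", reward_process = "fixed",
                      fixed_probs = c(0.5, 0.5))
  sess_fx <- run_batch(q_lambda_agent(0.334, 3.22), fx, 6, 5000, seed = 9)
  vtf <- trial_start_value_table(sess_fx)
  dqf <- vtf$q_chosen - vtf$q_unchosen
  names(dqf) <- paste(vtf$transition, vtf$outcome)
  gap <- mean(dqf[c("common rewarded", "rare non-rewarded")]) -
    mean(dqf[c("rare rewarded", "common non-rewarded")])
  expect_lt(abs(gap), 0.02)
  # a non-value-based agent is rejected
  ls <- run_session(latent_state_agent(0.03, 0.2), task, 200, seed = 10)
  expect_error(trial_start_value_table(ls), "value")
})

test_that("predictor correlations: identities, confound correlation, constants", {
  task <- two_step_task("reduced")
  sess <- run_batch(q_lambda_agent(0.334, 3.22), task, 4, 4000, seed = 11)
  cm <- suppressWarnings(predictor_correlation(
    sess, c("outcome", "transition", "interaction", "correct_binary",
            "rewarded_common")))
  # the interaction predictor correlates positively with the correct one
  expect_gt(cm["interaction", "correct_binary"], 0.1)
  expect_equal(diag(cm[c("outcome", "interaction"), c("outcome", "interaction")]),
               c(1, 1), ignore_attr = TRUE)
  # the constant stay predictor has undefined correlations, with a warning
  expect_warning(cm2 <- predictor_correlation(sess, c("stay", "outcome")),
                 "constant")
  expect_true(is.na(cm2["stay", "outcome"]))
})
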