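predictor_names <- c("stay", "outcome", "transition", "interaction",
                     "correct_binary", "correct_continuous",
                     "rewarded_common", "rewarded_rare",
                     "nonrewarded_common", "nonrewarded_rare")

#' Stay-probability table
#'
#' Fraction of trials on which the agent repeated its previous first-step
#' choice, tabulated by the previous trial's transition (common/rare) and
#' outcome (rewarded/non-rewarded). Cell means are computed per session and
#' aggregated with the standard error of the mean across sessions; a session
#' with an empty cell is excluded from that cell with a warning.
#'
#' @param sessions a session or list of sessions.
#' @return A data frame with columns `transition`, `outcome`, `mean`, `sem`,
#'   and the per-session cell values as attribute `"per_session"`.
#' @export
stay_table <- function(sessions) {
  sessions <- as_sessions(sessions)
  cells <- expand.grid(transition = c("common", "rare"),
                       outcome = c("rewarded", "non-rewarded"),
                       stringsAsFactors = FALSE)
  per <- sapply(sessions, function(s) {
    if (nrow(s) < 2) stop("stay_table needs at least 2 trials per session")
    stay <- s$choice1[-1] == s$choice1[-nrow(s)]
    tr <- s$transition[-nrow(s)]
    rw <- ifelse(s$outcome[-nrow(s)] == 1, "rewarded", "non-rewarded")
    vapply(seq_len(nrow(cells)), function(i) {
      sel <- tr == cells$transition[i] & rw == cells$outcome[i]
      if (!any(sel)) NA_real_ else mean(stay[sel])
    }, numeric(1))
  })
  per <- matrix(per, nrow = nrow(cells))
  if (anyNA(per))
    warning("empty stay-table cell(s) in some sessions; ",
            "those sessions excluded from the affected cell")
  cells$mean <- rowMeans(per, na.rm = TRUE)
  cells$sem <- apply(per, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  })
  structure(cells, per_session = per, class = c("stay_table", "data.frame"))
}

# per-trial predictor values evaluated at the lagged trial's events
lag_predictor <- function(session, name, idx) {
  outcome <- session$outcome[idx]
  common <- session$transition[idx] == "common"
  switch(name,
    stay = rep(1, length(idx)),
    outcome = ifelse(outcome == 1, 0.5, -0.5),
    transition = ifelse(common, 0.5, -0.5),
    interaction = ifelse(common == (outcome == 1), 0.5, -0.5),
    correct_binary = ,
    correct_continuous = {
      if (!all(c("rp_a1", "rp_b1") %in% names(session)) ||
          anyNA(session$rp_a1[idx]))
        stop("correct predictors require true reward probabilities in the session")
      original <- !is.null(attr(session, "task")) &&
        attr(session, "task")$variant == "original"
      pa <- if (original) pmax(session$rp_a1[idx], session$rp_a2[idx]) else session$rp_a1[idx]
      pb <- if (original) pmax(session$rp_b1[idx], session$rp_b2[idx]) else session$rp_b1[idx]
      chose_A <- session$choice1[idx] == "A"
      diffp <- ifelse(chose_A, pa - pb, pb - pa)
      if (name == "correct_binary") 0.5 * sign(diffp) else diffp
    },
    rewarded_common = ifelse(outcome == 1 & common, 0.5, 0),
    rewarded_rare = ifelse(outcome == 1 & !common, 0.5, 0),
    nonrewarded_common = ifelse(outcome == 0 & common, 0.5, 0),
    nonrewarded_rare = ifelse(outcome == 0 & !common, 0.5, 0),
    stop("unknown predictor: ", name))
}

#' Build a stay/switch regression design
#'
#' One-trial-back design for the logistic regression of choice. The response
#' is whether the first-step choice on trial t repeats the choice on trial
#' t-1 (stay vs switch); predictors are evaluated at trial t-1's events,
#' with the codings: `stay` +1 always; `outcome` +0.5 rewarded / -0.5
#' non-rewarded; `transition` +0.5 common / -0.5 rare; `interaction` +0.5
#' for rewarded-common and non-rewarded-rare trials, -0.5 otherwise;
#' `correct_binary` +0.5 when the previous choice led commonly to the state
#' with the higher reward probability (on the original task a state's reward
#' probability is the higher of its two action probabilities), -0.5 when to
#' the lower (0 at a tie); `correct_continuous` the signed difference in
#' state reward probabilities; and the four event indicators
#' `rewarded_common`, `rewarded_rare`, `nonrewarded_common`,
#' `nonrewarded_rare` coded +0.5 when the event occurred, 0 otherwise.
#'
#' @param session a `twostep_session`.
#' @param predictors character vector of predictor names (see above). The
#'   `stay` predictor is always included first.
#' @return A list with `X` (design matrix, one row per trial from trial 2)
#'   and `y` (logical stay response).
#' @export
build_design <- function(session, predictors = c("outcome", "transition",
                                                 "interaction")) {
  stopifnot(nrow(session) >= 2)
  predictors <- union("stay", predictors)
  bad <- setdiff(predictors, predictor_names)
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  idx <- seq_len(nrow(session) - 1L)      # trial t-1 for t = 2..n
  X <- vapply(predictors, function(p) lag_predictor(session, p, idx),
              numeric(length(idx)))
  colnames(X) <- predictors
  y <- session$choice1[-1] == session$choice1[-nrow(session)]
  list(X = X, y = y)
}

# penalised logistic Newton solver, used when plain ML separates
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100L, tol = 1e-10) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    g <- drop(crossprod(X, y - p)) - lambda * beta
    H <- crossprod(X * w, X) + diag(lambda, ncol(X))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

fit_logistic_session <- function(X, y, ridge = 1e-4) {
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  separated <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    anyNA(fit$coefficients)
  if (separated) {
    beta <- ridge_logistic(X, y, lambda = ridge)
    list(coef = beta, ridged = TRUE)
  } else {
    list(coef = fit$coefficients, ridged = FALSE)
  }
}

aggregate_loadings <- function(loadings, ridged) {
  n <- nrow(loadings)
  mean_ <- colMeans(loadings)
  sem <- apply(loadings, 2, sd) / sqrt(n)
  tstat <- mean_ / sem
  p <- 2 * pt(-abs(tstat), df = n - 1)
  res <- data.frame(predictor = colnames(loadings), mean = mean_, sem = sem,
                    t = tstat, p = p, row.names = NULL)
  structure(res, loadings = loadings, ridged = ridged,
            class = c("twostep_regression", "data.frame"))
}

#' One-trial-back logistic regression of choice
#'
#' Fits, per session, a maximum-likelihood logistic regression of stay vs
#' switch on the previous trial's events (design from [build_design()]), and
#' aggregates the predictor loadings across sessions with mean, SEM, and a
#' two-sided one-sample t-test against zero. Sessions whose plain ML fit
#' shows perfect separation are re-fit with a small ridge penalty
#' (reported via the `"ridged"` attribute).
#'
#' @param sessions a session or list of sessions.
#' @param predictors predictor names as in [build_design()].
#' @param ridge ridge penalty used only when separation is detected.
#' @return A `twostep_regression` data frame with columns `predictor`,
#'   `mean`, `sem`, `t`, `p`; per-session loadings in attribute
#'   `"loadings"`.
#' @examples
#' task <- two_step_task("reduced")
#' s <- run_batch(q_lambda_agent(0.334, 3.22), task, n_sessions = 3,
#'                n_trials = 500, seed = 1)
#' fit_choice_regression(s)
#' @export
fit_choice_regression <- function(sessions,
                                  predictors = c("outcome", "transition",
                                                 "interaction"),
                                  ridge = 1e-4) {
  sessions <- as_sessions(sessions)
  fits <- lapply(sessions, function(s) {
    d <- build_design(s, predictors)
    fit_logistic_session(d$X, d$y, ridge)
  })
  loadings <- do.call(rbind, lapply(fits, `[[`, "coef"))
  colnames(loadings) <- union("stay", predictors)
  aggregate_loadings(loadings, vapply(fits, `[[`, logical(1), "ridged"))
}

#' Lagged logistic regression of choice
#'
#' Regresses the identity of the first-step choice (A vs B) on the four
#' transition-outcome event types at lags 1 to `n_lags`. The predictor for
#' event e at lag k is the event's indicator coding (+0.5 when e occurred at
#' trial t-k, 0 otherwise) multiplied by the sign of the choice made at
#' trial t-k (A = +1, B = -1); an intercept absorbs overall side bias. A
#' positive loading therefore means that the event predicts repeating the
#' choice made k trials earlier. Trials without a full lag history are
#' dropped.
#'
#' @param sessions a session or list of sessions.
#' @param n_lags number of lags (>= 1).
#' @param ridge ridge penalty applied only on separation.
#' @return A `twostep_regression` data frame; predictors are named
#'   `<event>_lag<k>` plus `intercept`.
#' @export
fit_lagged_regression <- function(sessions, n_lags = 12L, ridge = 1e-4) {
  sessions <- as_sessions(sessions)
  events <- c("rewarded_common", "rewarded_rare",
              "nonrewarded_common", "nonrewarded_rare")
  fits <- lapply(sessions, function(s) {
    n <- nrow(s)
    if (n <= n_lags) stop("sessions must be longer than n_lags")
    t_idx <- (n_lags + 1L):n
    cols <- list(intercept = rep(1, length(t_idx)))
    for (k in seq_len(n_lags)) {
      src <- t_idx - k
      sgn <- ifelse(s$choice1[src] == "A", 1, -1)
      for (e in events)
        cols[[paste0(e, "_lag", k)]] <- lag_predictor(s, e, src) * sgn
    }
    X <- do.call(cbind, cols)
    y <- s$choice1[t_idx] == "A"
    fit_logistic_session(X, y, ridge)
  })
  loadings <- do.call(rbind, lapply(fits, `[[`, "coef"))
  aggregate_loadings(loadings, vapply(fits, `[[`, logical(1), "ridged"))
}

#' Trial-start action values by subsequent trial events
#'
#' Mean pre-choice first-step action value of the chosen and not-chosen
#' action, split by the current trial's transition and outcome. Available
#' only for agents that expose first-step action values (Q-lambda and
#' model-based agents).
#'
#' @param sessions a session or list of sessions carrying `q1A`/`q1B`.
#' @return A data frame with one row per transition x outcome cell and
#'   columns `q_chosen`, `q_unchosen` (cross-session means), `sem_chosen`,
#'   `sem_unchosen`.
#' @export
trial_start_value_table <- function(sessions) {
  sessions <- as_sessions(sessions)
  if (anyNA(sessions[[1]]$q1A))
    stop("sessions do not carry first-step action values (non-value-based agent)")
  cells <- expand.grid(transition = c("common", "rare"),
                       outcome = c("rewarded", "non-rewarded"),
                       stringsAsFactors = FALSE)
  per <- lapply(sessions, function(s) {
    qc <- ifelse(s$choice1 == "A", s$q1A, s$q1B)
    qu <- ifelse(s$choice1 == "A", s$q1B, s$q1A)
    rw <- ifelse(s$outcome == 1, "rewarded", "non-rewarded")
    t(vapply(seq_len(nrow(cells)), function(i) {
      sel <- s$transition == cells$transition[i] & rw == cells$outcome[i]
      c(mean(qc[sel]), mean(qu[sel]))
    }, numeric(2)))
  })
  qc_mat <- sapply(per, function(m) m[, 1])
  qu_mat <- sapply(per, function(m) m[, 2])
  n <- length(sessions)
  cells$q_chosen <- rowMeans(qc_mat)
  cells$q_unchosen <- rowMeans(qu_mat)
  cells$sem_chosen <- apply(qc_mat, 1, sd) / sqrt(n)
  cells$sem_unchosen <- apply(qu_mat, 1, sd) / sqrt(n)
  cells
}

#' Across-trial correlation between regression predictors
#'
#' Pearson correlation between predictor columns of the one-trial-back
#' design, either pooled over all sessions' trials or averaged over
#' per-session correlation matrices. Constant predictors (including `stay`)
#' have undefined correlations, reported as `NA` with a warning.
#'
#' @param sessions a session or list of sessions.
#' @param predictors predictor names as in [build_design()].
#' @param per_session if `TRUE`, average per-session correlation matrices
#'   instead of pooling trials.
#' @return A correlation matrix.
#' @export
predictor_correlation <- function(sessions,
                                  predictors = c("outcome", "transition",
                                                 "interaction",
                                                 "correct_binary"),
                                  per_session = FALSE) {
  sessions <- as_sessions(sessions)
  designs <- lapply(sessions, function(s)
    build_design(s, predictors)$X[, predictors, drop = FALSE])
  corr_of <- function(X) {
    const <- apply(X, 2, function(col) sd(col) == 0)
    cm <- suppressWarnings(cor(X))
    cm[const, ] <- NA_real_; cm[, const] <- NA_real_
    diag(cm)[!const] <- 1
    if (any(const))
      warning("constant predictor(s): ",
              paste(colnames(X)[const], collapse = ", "),
              "; correlation undefined")
    cm
  }
  if (per_session) {
    mats <- lapply(designs, corr_of)
    Reduce(`+`, mats) / length(mats)
  } else {
    corr_of(do.call(rbind, designs))
  }
}

#' @export
print.twostep_regression <- function(x, digits = 4, ...) {
  cat("Logistic regression of choice (", nrow(attr(x, "loadings")),
      " sessions)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  if (any(attr(x, "ridged")))
    cat("note:", sum(attr(x, "ridged")),
        "session fit(s) ridge-stabilised after separation\n")
  invisible(x)
}
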