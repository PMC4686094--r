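# Independent pure-R re-implementations used as oracles. These deliberately
# do not share code with the package's compiled engine: they replay recorded
# sessions trial by trial from the update equations written out directly.

oracle_softmax2 <- function(v0, v1, T) 1 / (1 + exp(-T * (v0 - v1)))

# log-likelihood of a session's recorded choices under each agent family,
# replaying the agent state on the recorded events
oracle_loglik <- function(agent, session) {
  task <- attr(session, "task")
  original <- task$variant == "original"
  p <- agent$params
  c1 <- match(session$choice1, c("A", "B"))
  s2 <- match(session$second_state, c("a", "b"))
  c2 <- session$choice2
  r <- session$outcome
  n <- nrow(session)
  q1 <- c(0.5, 0.5); q2 <- matrix(0.5, 2, 2)
  qrc <- matrix(0.5, 4, 2)
  post <- 0.5; cue <- NA; last <- NA
  ll <- 0
  for (t in seq_len(n)) {
    pA <- switch(agent$name,
      q_lambda = {
        b <- c(0, 0); if (!is.na(last)) b[last] <- p$perseveration
        oracle_softmax2(q1[1] + b[1], q1[2] + b[2], p$T)
      },
      model_based = {
        V <- if (original) apply(q2, 1, max) else q2[, 1]
        tA <- if (is.null(p$eta)) task$p_common else NA  # fixed-transition only
        qA <- tA * V[1] + (1 - tA) * V[2]
        qB <- (1 - tA) * V[1] + tA * V[2]
        b <- c(0, 0); if (!is.na(last)) b[last] <- p$perseveration
        oracle_softmax2(qA + b[1], qB + b[2], p$T)
      },
      reward_as_cue = if (is.na(cue)) 0.5 else
        oracle_softmax2(qrc[cue, 1], qrc[cue, 2], p$T),
      latent_state = {
        eps <- p$epsilon
        if (post > 0.5) 1 - eps else if (post < 0.5) eps else 0.5
      },
      stop("no oracle for agent ", agent$name))
    ll <- ll + log(if (c1[t] == 1) pA else 1 - pA)
    if (original) {
      Tsec <- if (agent$name == "reward_as_cue") p$T2 else p$T
      p2A <- oracle_softmax2(q2[s2[t], 1], q2[s2[t], 2], Tsec)
      ll <- ll + log(if (c2[t] == 1) p2A else 1 - p2A)
    }
    c2t <- if (original) c2[t] else 1
    if (agent$name == "q_lambda") {
      q2c <- q2[s2[t], c2t]
      q1[c1[t]] <- (1 - p$alpha) * q1[c1[t]] +
        p$alpha * (q2c + p$lambda * (r[t] - q2c))
      q2[s2[t], c2t] <- (1 - p$alpha) * q2c + p$alpha * r[t]
    } else if (agent$name == "model_based") {
      q2[s2[t], c2t] <- (1 - p$alpha) * q2[s2[t], c2t] + p$alpha * r[t]
    } else if (agent$name == "reward_as_cue") {
      if (!is.na(cue))
        qrc[cue, c1[t]] <- (1 - p$alpha) * qrc[cue, c1[t]] + p$alpha * r[t]
      if (original)
        q2[s2[t], c2t] <- (1 - p$alpha2) * q2[s2[t], c2t] + p$alpha2 * r[t]
      cue <- (if (r[t] == 1) 0 else 2) + s2[t]
    } else if (agent$name == "latent_state") {
      pg <- if (!is.null(p$p_good)) p$p_good else if (original) 0.625 else 0.8
      pb <- if (!is.null(p$p_bad)) p$p_bad else if (original) 0.375 else 0.2
      la <- if (s2[t] == 1) (if (r[t]) pg else 1 - pg) else (if (r[t]) pb else 1 - pb)
      lb <- if (s2[t] == 1) (if (r[t]) pb else 1 - pb) else (if (r[t]) pg else 1 - pg)
      post <- post * la / (post * la + (1 - post) * lb)
      post <- (1 - p$omega) * post + p$omega * (1 - post)
      if (original)
        q2[s2[t], c2t] <- (1 - p$alpha) * q2[s2[t], c2t] + p$alpha * r[t]
    }
    last <- c1[t]
  }
  ll
}

# stationary reward rate of the deterministic reward-as-cue policy on the
# reduced task with static reward probabilities, via its 4-state Markov
# chain over the (outcome, second-step state) cue
oracle_det_rc_reward_rate <- function(p_common = 0.8, rp = c(0.8, 0.2)) {
  # cue states 1..4: (r=1,a), (r=1,b), (r=0,a), (r=0,b); policy A,B,B,A
  act <- c(1, 2, 2, 1)
  P <- matrix(0, 4, 4)
  for (cue in 1:4) {
    a <- act[cue]
    for (s2 in 1:2) {
      ps <- if (s2 == a) p_common else 1 - p_common
      pr <- rp[s2]
      P[cue, (0 * 2) + s2] <- P[cue, s2] + ps * pr          # rewarded
      P[cue, (1 * 2) + s2] <- P[cue, 2 + s2] + ps * (1 - pr) # non-rewarded
    }
  }
  st <- Re(eigen(t(P))$vectors[, 1]); st <- st / sum(st)
  sum(st[1:2])  # stationary probability of being in a rewarded cue state
}

# fold a value into [lo, hi] by repeated reflection (independent of the
# package's compiled helper)
oracle_fold <- function(x, lo, hi) {
  while (x < lo || x > hi) x <- if (x < lo) 2 * lo - x else 2 * hi - x
  x
}
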