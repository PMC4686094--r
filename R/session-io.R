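#' Write and read session files
#'
#' Sessions are stored in a plain tab-separated text format: one file holds
#' any number of sessions, each introduced by commented metadata lines
#' (`# session`, `# agent`, `# params`, `# task`, `# seed`, `# n_trials`)
#' followed by a header line and one row per trial. Enumerations are spelled
#' out (`A`/`B`, `common`/`rare`, `a`/`b`) and numeric columns are written at
#' full precision, so a write/read round trip is lossless.
#'
#' `read_sessions()` validates the transition consistency invariant (a
#' common transition from A must reach state a, from B state b) and reports
#' malformed rows with their line numbers.
#'
#' @param sessions a session or list of sessions.
#' @param path file path.
#' @return `write_sessions()` returns `path` invisibly; `read_sessions()`
#'   returns a `twostep_sessions` list.
#' @examples
#' task <- two_step_task("reduced")
#' s <- run_batch(q_lambda_agent(0.5, 3), task, n_sessions = 2,
#'                n_trials = 50, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_sessions(s, f)
#' s2 <- read_sessions(f)
#' all.equal(as.data.frame(s[[1]]), as.data.frame(s2[[1]]))
#' @export
write_sessions <- function(sessions, path) {
  sessions <- as_sessions(sessions)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA"
      else if (is.numeric(v)) format(v, digits = 17)
      else as.character(v)
    }, character(1))
    out
  }
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    a <- attr(s, "agent"); tk <- attr(s, "task")
    ps <- a$params[!vapply(a$params, is.null, logical(1))]
    writeLines(c(
      sprintf("# session %d", i),
      sprintf("# agent %s", a$name),
      sprintf("# params %s", paste(names(ps), format(unlist(ps), digits = 17),
                                   sep = "=", collapse = ";")),
      sprintf("# task variant=%s;reward_process=%s;p_common=%s;block_length=%d;block_probs=%s,%s;walk_bounds=%s,%s;walk_sd=%s;fixed_probs=%s,%s",
              tk$variant, tk$reward_process, format(tk$p_common, digits = 17),
              tk$block_length,
              format(tk$block_probs[1], digits = 17),
              format(tk$block_probs[2], digits = 17),
              format(tk$walk_bounds[1], digits = 17),
              format(tk$walk_bounds[2], digits = 17),
              format(tk$walk_sd, digits = 17),
              format(tk$fixed_probs[1], digits = 17),
              format(tk$fixed_probs[2], digits = 17)),
      sprintf("# seed %d", attr(s, "seed")),
      sprintf("# n_trials %d", nrow(s)),
      paste(session_cols, collapse = "\t")), con)
    rows <- vapply(seq_len(nrow(s)), function(r)
      paste(fmt(as.list(s[r, session_cols])), collapse = "\t"), character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

parse_kv <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) p[2]), vapply(kv, `[`, "", 1))
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  lines <- readLines(path)
  starts <- grep("^# session ", lines)
  if (!length(starts)) stop("no '# session' blocks found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  sessions <- vector("list", length(starts))
  num <- function(x) suppressWarnings(as.numeric(x))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    offset <- starts[i] - 1L
    get_meta <- function(key) {
      ln <- grep(paste0("^# ", key, " "), block, value = TRUE)
      if (!length(ln)) stop("missing '# ", key, "' line in session block ", i)
      sub(paste0("^# ", key, " "), "", ln[1])
    }
    agent_name <- get_meta("agent")
    params <- lapply(parse_kv(get_meta("params")), num)
    tmeta <- parse_kv(get_meta("task"))
    pair <- function(key) num(strsplit(tmeta[[key]], ",", fixed = TRUE)[[1]])
    task <- two_step_task(tmeta$variant,
                          reward_process = tmeta$reward_process,
                          p_common = num(tmeta$p_common),
                          block_length = as.integer(tmeta$block_length),
                          block_probs = pair("block_probs"),
                          walk_bounds = pair("walk_bounds"),
                          walk_sd = num(tmeta$walk_sd),
                          fixed_probs = pair("fixed_probs"))
    agent <- make_agent(agent_name, params)
    hdr_i <- which(!startsWith(block, "#"))[1]
    hdr <- strsplit(block[hdr_i], "\t", fixed = TRUE)[[1]]
    if (!identical(hdr, session_cols))
      stop("unexpected header at line ", offset + hdr_i, " of ", path)
    data_lines <- block[(hdr_i + 1):length(block)]
    data_lines <- data_lines[nzchar(data_lines)]
    fields <- strsplit(data_lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != length(session_cols))
    if (length(bad))
      stop("malformed row(s) at line(s) ",
           paste(offset + hdr_i + bad, collapse = ", "), " of ", path)
    df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
    names(df) <- session_cols
    for (cn in setdiff(session_cols, c("choice1", "transition", "second_state")))
      df[[cn]] <- num(df[[cn]])
    df$choice2 <- as.integer(df$choice2)
    df$outcome <- as.integer(df$outcome)
    ok_lab <- df$choice1 %in% c("A", "B") &
      df$transition %in% c("common", "rare") &
      df$second_state %in% c("a", "b") & df$outcome %in% 0:1
    common_ok <- (df$transition == "common") ==
      ((df$choice1 == "A") == (df$second_state == "a"))
    bad <- which(!(ok_lab & common_ok))
    if (length(bad))
      stop("inconsistent trial record(s) at line(s) ",
           paste(offset + hdr_i + bad, collapse = ", "), " of ", path,
           " (labels or transition/second-state mismatch)")
    sessions[[i]] <- structure(df,
                               agent = agent, task = task,
                               seed = as.integer(get_meta("seed")),
                               n_trials = nrow(df),
                               class = c("twostep_session", "data.frame"))
  }
  structure(sessions, class = "twostep_sessions")
}
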