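#' Progressive-ratio criteria sequence
#'
#' Arithmetic sequence of response requirements: `start`, `start +
#' increment`, ... A PR3 schedule starting from the FR3 pre-training level
#' gives 3, 6, 9, ..., 21 after seven stages.
#'
#' @param start first requirement (>= 1).
#' @param increment step per completed stage (>= 1).
#' @param n_stages number of criteria to emit.
#' @return integer vector of length `n_stages`.
#' @export
pr_criteria <- function(start = 3, increment = 3, n_stages) {
  if (start < 1) stop("start must be >= 1")
  if (increment < 1) stop("increment must be >= 1")
  stopifnot(n_stages >= 1)
  as.integer(start + (seq_len(n_stages) - 1L) * increment)
}

#' Extract a progressive-ratio outcome for one mouse
#'
#' Walks the mouse's visits to the reward corners of a PR session in time
#' order. A stage is completed when a single visit contains at least the
#' current criterion's nose pokes on a reward-bottle side; nose pokes beyond
#' the criterion have no consequence, and consecutive completions must come
#' from distinct visits (the animal has to leave and re-enter). The
#' breakpoint is the highest completed criterion (0 if none). Visits to
#' reward corners between completions and after the last completion are
#' counted separately.
#'
#' By default one criterion counter covers both reward corners of the
#' session (`scope = "pair"`); `scope = "corner"` runs an independent
#' counter per corner and reports the best corner's outcome.
#'
#' @param table an `event_table`.
#' @param session a `session_spec` with a PR contingency.
#' @param mouse animal_id.
#' @param scope `"pair"` or `"corner"`.
#' @return object of class `pr_outcome`: list with `animal_id`,
#'   `breakpoint`, `completed` (criteria completed, in order),
#'   `visits_between` (reward-corner visits needed to reach each criterion,
#'   including the completing visit), `licks_after` (licks in each
#'   completing visit), `post_breakpoint_visits` and `n_visits`.
#' @export
extract_breakpoint <- function(table, session, mouse,
                               scope = c("pair", "corner")) {
  scope <- match.arg(scope)
  stopifnot(is_event_table(table), inherits(session, "session_spec"))
  if (session$contingency$type != "PR")
    stop("session ", session$index, " does not run a PR contingency")
  if (!mouse %in% roster(table)$animal_id)
    stop("unknown animal_id: ", mouse)
  rc <- reward_corners(session)
  w <- session_window(session)
  tt <- table[table$animal_id == mouse &
                table$t_start >= w[1] & table$t_start < w[2] &
                table$corner %in% rc, , drop = FALSE]
  if (scope == "corner") {
    outs <- lapply(rc, function(k)
      walk_pr(tt[tt$corner == k, , drop = FALSE], session, mouse))
    best <- which.max(vapply(outs, `[[`, 0, "breakpoint"))
    out <- outs[[best]]
    out$per_corner <- stats::setNames(outs, paste0("corner", rc))
    return(out)
  }
  walk_pr(tt, session, mouse)
}

walk_pr <- function(tt, session, mouse) {
  cont <- session$contingency
  crit <- cont$start
  completed <- integer(0)
  visits_between <- integer(0)
  licks_after <- integer(0)
  since_last <- 0L
  last_completion_row <- 0L
  n <- nrow(tt)
  for (i in seq_len(n)) {
    k <- as.character(tt$corner[i])
    kinds <- content_kind(session$contents[[k]])
    pokes <- c(tt$nosepokes_left[i], tt$nosepokes_right[i])
    pokes <- pokes[kinds != "water"]
    since_last <- since_last + 1L
    if (length(pokes) && max(pokes) >= crit) {
      completed <- c(completed, crit)
      visits_between <- c(visits_between, since_last)
      licks_after <- c(licks_after,
                       tt$licks_left[i] + tt$licks_right[i])
      since_last <- 0L
      last_completion_row <- i
      crit <- crit + cont$increment
    }
  }
  structure(list(animal_id = mouse,
                 breakpoint = if (length(completed))
                   completed[length(completed)] else 0L,
                 completed = completed,
                 visits_between = visits_between,
                 licks_after = licks_after,
                 post_breakpoint_visits = n - last_completion_row,
                 n_visits = n),
            class = "pr_outcome")
}

#' @export
print.pr_outcome <- function(x, ...) {
  cat(sprintf("<pr_outcome> %s: breakpoint %d (%d stages, %d visits, %d post-breakpoint)\n",
              x$animal_id, x$breakpoint, length(x$completed), x$n_visits,
              x$post_breakpoint_visits))
  invisible(x)
}

#' Progressive-ratio outcomes for a whole cohort
#'
#' @inheritParams extract_breakpoint
#' @return data.frame with one row per roster animal: `animal_id`,
#'   `breakpoint`, `stages_completed`, `post_breakpoint_visits`,
#'   `mean_visits_between`, `n_visits`.
#' @export
extract_breakpoints <- function(table, session, scope = "pair") {
  ids <- roster(table)$animal_id
  rows <- lapply(ids, function(id) {
    o <- extract_breakpoint(table, session, id, scope = scope)
    data.frame(animal_id = id, breakpoint = o$breakpoint,
               stages_completed = length(o$completed),
               post_breakpoint_visits = o$post_breakpoint_visits,
               mean_visits_between = if (length(o$visits_between))
                 mean(o$visits_between) else NA_real_,
               n_visits = o$n_visits, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Licks on risk versus safe bottles in a punishment session
#'
#' @param table an `event_table`.
#' @param session a `session_spec` with an FR-plus-risk contingency; its
#'   reward corners are the "risk" corners, the water corners are "safe".
#' @return data.frame with one row per roster animal: `animal_id`,
#'   `licks_risk`, `licks_safe`.
#' @export
risk_session_licks <- function(table, session) {
  stopifnot(is_event_table(table), inherits(session, "session_spec"))
  if (session$contingency$type != "FR_risk")
    stop("session ", session$index, " does not run a punishment-risk contingency")
  rc <- reward_corners(session)
  w <- session_window(session)
  tt <- table[table$t_start >= w[1] & table$t_start < w[2], , drop = FALSE]
  licks <- tt$licks_left + tt$licks_right
  ids <- roster(table)$animal_id
  out <- data.frame(animal_id = ids, licks_risk = 0L, licks_safe = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(tt)) {
    risk <- tapply(licks[tt$corner %in% rc],
                   factor(tt$animal_id[tt$corner %in% rc], levels = ids),
                   sum)
    safe <- tapply(licks[!tt$corner %in% rc],
                   factor(tt$animal_id[!tt$corner %in% rc], levels = ids),
                   sum)
    out$licks_risk <- as.integer(ifelse(is.na(risk), 0, risk))
    out$licks_safe <- as.integer(ifelse(is.na(safe), 0, safe))
  }
  out
}
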