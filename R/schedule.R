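#' Session specifications and cage schedules
#'
#' A `session_spec` describes one 24 h access interval: its half-open time
#' window in seconds since experiment start, the bottle contents of every
#' corner side, and the reinforcement contingency in force at the reward
#' corners. A `cage_schedule` is an ordered list of sessions.
#'
#' Water corners in non-free sessions implicitly run FR3 (the pre-training
#' contingency); this is stored as `water_contingency`.
#'
#' @param index session index, 1-based.
#' @param start,end window in seconds since experiment start, `[start, end)`.
#' @param contents named list `"1"`..`"4"`, each a character vector
#'   `c(left = , right = )` of content strings (see [content()]).
#' @param contingency a [contingency][contingency_free] applying to the
#'   reward corners.
#' @param water_contingency contingency at the water-only corners.
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(index, start, end, contents,
                         contingency = contingency_free(),
                         water_contingency = contingency_free()) {
  stopifnot(index >= 1, end > start, inherits(contingency, "contingency"))
  if (!identical(sort(names(contents)), c("1", "2", "3", "4")))
    stop("contents must be a named list for corners 1..4")
  for (k in names(contents)) {
    side <- contents[[k]]
    if (!identical(sort(names(side)), c("left", "right")))
      stop("corner ", k, " must name left and right contents")
    lapply(side, parse_content)  # validates
  }
  structure(list(index = as.integer(index), start = start, end = end,
                 contents = contents[c("1", "2", "3", "4")],
                 contingency = contingency,
                 water_contingency = water_contingency),
            class = "session_spec")
}

session_window <- function(s) c(s$start, s$end)

#' @rdname session_spec
#' @param s a `session_spec`.
#' @export
session_has_alcohol <- function(s) {
  any(vapply(s$contents, function(cs) any(is_alcohol(cs)), TRUE))
}

#' @rdname session_spec
#' @export
reward_corners <- function(s) {
  unname(which(vapply(s$contents,
                      function(cs) any(content_kind(cs) != "water"), TRUE)))
}

new_schedule <- function(sessions) {
  structure(sessions, class = "cage_schedule")
}

#' @export
`[.cage_schedule` <- function(x, i) new_schedule(unclass(x)[i])

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf("session %d  [%.0f, %.0f) s\n", x$index, x$start, x$end))
  for (k in 1:4)
    cat(sprintf("  corner %d: L=%s R=%s\n", k,
                x$contents[[k]]["left"], x$contents[[k]]["right"]))
  print(x$contingency)
  invisible(x)
}

#' @export
print.cage_schedule <- function(x, ...) {
  cat(sprintf("<cage_schedule> %d sessions, %d with alcohol\n", length(x),
              sum(vapply(x, session_has_alcohol, TRUE))))
  invisible(x)
}

corner_contents <- function(fill = "water") {
  stats::setNames(
    lapply(1:4, function(k) c(left = fill, right = fill)),
    as.character(1:4))
}

# reward-corner pairs alternate between odd {1,3} and even {2,4} sessions
alternating_corners <- function(k) if (k %% 2L == 1L) c(1L, 3L) else c(2L, 4L)

#' Build an intermittent two-bottle alcohol access schedule
#'
#' Three 24 h alcohol sessions per week (Monday, Wednesday and Friday,
#' starting at the bottle-exchange hour), with the alcohol corners
#' alternating between \{I, III\} on odd-numbered sessions and \{II, IV\} on
#' even-numbered ones. Ethanol concentration ramps 4% (session 1), 8%
#' (session 2), then 12% in all subsequent sessions. All other corners, and
#' all time outside access sessions, carry water. Time 0 is the first
#' exchange (Monday at `exchange_hour`).
#'
#' @param weeks number of weeks; each contributes 3 alcohol sessions.
#' @param exchange_hour clock hour (0-23) of the bottle exchange; 16 (4 pm)
#'   by default, 15 for cohorts exchanged at 3 pm.
#' @param access_mode `"free"` or `"FR3"` (three nose pokes within one visit
#'   open the gate).
#' @return a `cage_schedule` of `3 * weeks` sessions.
#' @examples
#' sched <- build_intermittent(weeks = 4)
#' length(sched)  # 12
#' @export
build_intermittent <- function(weeks, exchange_hour = 16,
                               access_mode = c("free", "FR3")) {
  access_mode <- match.arg(access_mode)
  stopifnot(weeks >= 0)
  if (exchange_hour < 0 || exchange_hour > 23)
    stop("exchange_hour must be within 0..23")
  cont <- if (access_mode == "free") contingency_free() else contingency_fr(3)
  day <- 86400
  sessions <- vector("list", 3L * weeks)
  for (k in seq_len(3L * weeks)) {
    wk <- (k - 1L) %/% 3L
    dow <- c(0L, 2L, 4L)[(k - 1L) %% 3L + 1L]  # Mon, Wed, Fri
    start <- (wk * 7L + dow) * day
    conc <- if (k == 1L) 4 else if (k == 2L) 8 else 12
    contents <- corner_contents()
    for (cc in alternating_corners(k)) {
      contents[[as.character(cc)]][] <- content("alcohol", conc)
    }
    sessions[[k]] <- session_spec(k, start, start + day, contents,
                                  contingency = cont,
                                  water_contingency = cont)
  }
  new_schedule(sessions)
}

#' Build the seven-session quinine adulteration sequence
#'
#' Seven consecutive 24 h sessions testing persistence of alcohol drinking
#' under bitter adulteration: (i) 12% alcohol and 0.02% saccharin in opposite
#' corners, (ii) saccharin + 0.01% quinine (both reward corners),
#' (iii) alcohol + 0.01% quinine, (iv) saccharin + 0.03% quinine,
#' (v) alcohol + 0.03% quinine, (vi) saccharin + 0.03% quinine,
#' (vii) alcohol + 0.03% quinine. Water fills the two remaining corners and
#' the reward-corner pair switches after every session.
#'
#' @param start_s experiment-time of the first session start, seconds.
#' @param access_mode `"free"` (the tested cohort) or `"FR3"`.
#' @return a `cage_schedule` of 7 sessions.
#' @export
build_quinine_sequence <- function(start_s = 0, access_mode = c("free", "FR3")) {
  access_mode <- match.arg(access_mode)
  cont <- if (access_mode == "free") contingency_free() else contingency_fr(3)
  alc <- function(q = NULL) content("alcohol", 12, quinine = q)
  sac <- function(q = NULL) content("saccharin", 0.02, quinine = q)
  items <- list(
    list(sac(), alc()),                   # (i) opposite corners
    list(sac(0.01), sac(0.01)),           # (ii)
    list(alc(0.01), alc(0.01)),           # (iii)
    list(sac(0.03), sac(0.03)),           # (iv)
    list(alc(0.03), alc(0.03)),           # (v)
    list(sac(0.03), sac(0.03)),           # (vi)
    list(alc(0.03), alc(0.03)))           # (vii)
  day <- 86400
  sessions <- vector("list", 7L)
  for (k in 1:7) {
    contents <- corner_contents()
    pair <- alternating_corners(k)
    contents[[as.character(pair[1])]][] <- items[[k]][[1]]
    contents[[as.character(pair[2])]][] <- items[[k]][[2]]
    start <- start_s + (k - 1L) * day
    sessions[[k]] <- session_spec(k, start, start + day, contents,
                                  contingency = cont,
                                  water_contingency = cont)
  }
  new_schedule(sessions)
}

#' Build a progressive-ratio test sequence
#'
#' Two designs are provided. The `"male"` variant is the five-session
#' sequence run on a male cohort after intermittent access: (i) 12% alcohol
#' and 0.02% saccharin in opposite corners (free choice), (ii) saccharin
#' under PR1 in both reward corners, (iii) alcohol under PR1, (iv) saccharin
#' under PR3, (v) alcohol under PR3. The `"female"` variant is the
#' three-session sequence run per cohort: (i) the cohort's reward under PR1
#' in two corners with FR3 water elsewhere, (ii) FR3 water in all corners,
#' (iii) the reward under PR3. The PR requirement starts at 3 (the FR3
#' pre-training level) and grows by the PR increment per completion; the
#' start is configurable because it is a design choice, not a measured value.
#'
#' @param variant `"male"` or `"female"` (unknown variants are an error).
#' @param reward reward content for the female variant: `"alcohol"`,
#'   `"saccharin"` or `"water"`.
#' @param start_s experiment-time of the first session start, seconds.
#' @param pr_start starting response requirement of the PR schedules.
#' @return a `cage_schedule`.
#' @export
build_pr_sequence <- function(variant = c("male", "female"),
                              reward = c("alcohol", "saccharin", "water"),
                              start_s = 0, pr_start = 3) {
  variant <- match.arg(variant)
  reward <- match.arg(reward)
  day <- 86400
  alc <- content("alcohol", 12)
  sac <- content("saccharin", 0.02)
  fr3 <- contingency_fr(3)
  sessions <- list()
  if (variant == "male") {
    plan <- list(
      list(c(sac, alc), contingency_free()),
      list(c(sac, sac), contingency_pr(pr_start, 1)),
      list(c(alc, alc), contingency_pr(pr_start, 1)),
      list(c(sac, sac), contingency_pr(pr_start, 3)),
      list(c(alc, alc), contingency_pr(pr_start, 3)))
    for (k in seq_along(plan)) {
      contents <- corner_contents()
      pair <- alternating_corners(k)
      contents[[as.character(pair[1])]][] <- plan[[k]][[1]][1]
      contents[[as.character(pair[2])]][] <- plan[[k]][[1]][2]
      start <- start_s + (k - 1L) * day
      sessions[[k]] <- session_spec(k, start, start + day, contents,
                                    contingency = plan[[k]][[2]],
                                    water_contingency = fr3)
    }
  } else {
    rw <- switch(reward, alcohol = alc, saccharin = sac, water = "water")
    plan <- list(
      list(rw, contingency_pr(pr_start, 1)),
      list(NULL, fr3),                     # FR3 water everywhere
      list(rw, contingency_pr(pr_start, 3)))
    for (k in seq_along(plan)) {
      contents <- corner_contents()
      if (!is.null(plan[[k]][[1]])) {
        for (cc in alternating_corners(k))
          contents[[as.character(cc)]][] <- plan[[k]][[1]]
      }
      start <- start_s + (k - 1L) * day
      sessions[[k]] <- session_spec(k, start, start + day, contents,
                                    contingency = plan[[k]][[2]],
                                    water_contingency = fr3)
    }
  }
  new_schedule(sessions)
}

#' Build a punishment-risk test sequence
#'
#' FR3 access paired with a 0.5 bar air puff. The `"male"` variant has three
#' sessions: session 1 with a 100% punishment risk delivered immediately on
#' FR3 completion (alcohol and saccharin in opposite corners), sessions 2-3
#' with a 25% risk delivered 2 s after completion. The `"female"` variant is
#' a single 25%-risk, 2 s-delay session with the cohort's reward in the two
#' reward corners. Water corners carry FR3 without punishment.
#'
#' @inheritParams build_pr_sequence
#' @return a `cage_schedule`.
#' @export
build_punishment_sequence <- function(variant = c("male", "female"),
                                      reward = c("alcohol", "saccharin",
                                                 "water"),
                                      start_s = 0) {
  variant <- match.arg(variant)
  reward <- match.arg(reward)
  day <- 86400
  alc <- content("alcohol", 12)
  sac <- content("saccharin", 0.02)
  fr3 <- contingency_fr(3)
  sessions <- list()
  if (variant == "male") {
    risks <- list(contingency_fr_risk(3, risk = 100, delay_s = 0),
                  contingency_fr_risk(3, risk = 25, delay_s = 2),
                  contingency_fr_risk(3, risk = 25, delay_s = 2))
    for (k in 1:3) {
      contents <- corner_contents()
      pair <- alternating_corners(k)
      contents[[as.character(pair[1])]][] <- sac
      contents[[as.character(pair[2])]][] <- alc
      start <- start_s + (k - 1L) * day
      sessions[[k]] <- session_spec(k, start, start + day, contents,
                                    contingency = risks[[k]],
                                    water_contingency = fr3)
    }
  } else {
    rw <- switch(reward, alcohol = alc, saccharin = sac, water = "water")
    contents <- corner_contents()
    for (cc in alternating_corners(1)) contents[[as.character(cc)]][] <- rw
    sessions[[1]] <- session_spec(1, start_s, start_s + day, contents,
                                  contingency = contingency_fr_risk(
                                    3, risk = 25, delay_s = 2),
                                  water_contingency = fr3)
  }
  new_schedule(sessions)
}

#' Look up bottle content at a time point
#'
#' Sessions are half-open `[start, end)`: at a bottle-exchange instant the
#' new session's contents apply. Outside all sessions the bottles carry
#' water (returned with a warning).
#'
#' @param sessions a `cage_schedule`.
#' @param corner corner 1..4.
#' @param side `"left"` or `"right"`.
#' @param t time in seconds since experiment start.
#' @return a content string.
#' @export
content_at <- function(sessions, corner, side = c("left", "right"), t) {
  side <- match.arg(side)
  stopifnot(corner %in% 1:4, length(t) == 1L)
  s <- locate_session(sessions, t)
  if (is.na(s)) {
    warning("t = ", t, " s lies outside all sessions; assuming water",
            call. = FALSE)
    return("water")
  }
  unname(sessions[[s]]$contents[[as.character(corner)]][side])
}

# index of the session whose [start, end) contains t, or NA
locate_session <- function(sessions, t) {
  for (i in seq_along(sessions)) {
    if (t >= sessions[[i]]$start && t < sessions[[i]]$end) return(i)
  }
  NA_integer_
}

#' Serialize / deserialize a schedule as JSON
#' @param sessions a `cage_schedule`.
#' @param path file path.
#' @return `read_schedule` returns a `cage_schedule`.
#' @export
write_schedule <- function(sessions, path) {
  ser <- lapply(sessions, function(s) {
    list(index = s$index, start = s$start, end = s$end,
         contents = lapply(s$contents, as.list),
         contingency = unclass(s$contingency),
         water_contingency = unclass(s$water_contingency))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  ser <- jsonlite::read_json(path)
  revive <- function(ct) {
    for (f in c("n", "start", "increment")) {
      if (!is.null(ct[[f]])) ct[[f]] <- as.integer(ct[[f]])
    }
    for (f in c("risk", "delay_s", "pressure_bar")) {
      if (!is.null(ct[[f]])) ct[[f]] <- as.numeric(ct[[f]])
    }
    structure(ct, class = "contingency")
  }
  sessions <- lapply(ser, function(s) {
    contents <- lapply(s$contents, function(cs)
      c(left = cs$left, right = cs$right))
    session_spec(s$index, s$start, s$end, contents,
                 contingency = revive(s$contingency),
                 water_contingency = revive(s$water_contingency))
  })
  new_schedule(sessions)
}
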