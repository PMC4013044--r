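#' Generative profile of one simulated mouse
#'
#' Collects every parameter the agent-based simulator needs for one animal:
#' a circadian activity curve (two truncated-Gaussian peaks inside the 12 h
#' dark phase over a light-phase floor), drinking preferences, bottle-side
#' bias, lick-burst size, operant persistence and outgoing follow edges.
#'
#' @param animal_id character tag, unique within a cohort.
#' @param sex `"M"` or `"F"` (annotation only).
#' @param weight_g body weight in grams (used for dose conversion).
#' @param p_alcohol probability in \[0, 1\] that a drinking attempt at an
#'   alcohol bottle is carried through; attempts at water bottles succeed
#'   with `1 - p_alcohol`, so the expected lick-based preference ratio of a
#'   mouse with uniform corner use equals `p_alcohol`.
#' @param p_saccharin analogous completion probability at saccharin bottles.
#' @param side_bias bottle-side bias in \[-1, 1\]; when both sides of a
#'   corner carry the same content the right side is chosen with probability
#'   `(1 + side_bias) / 2`.
#' @param activity list with `peak_h` (hours after dark onset of the two
#'   activity peaks), `width_h` (Gaussian SDs, hours), `amplitude` (peak
#'   visit rates, visits/hour) and `floor_frac` (light-phase rate as a
#'   fraction of the mean peak amplitude). All-zero amplitudes give a mouse
#'   that never visits.
#' @param licks_per_event list with `mean` and `dispersion` of the negative
#'   binomial lick count per drinking event (shifted to be >= 1).
#' @param persistence progressive-ratio criterion up to which the mouse
#'   keeps completing reliably; stages above it are rarely completed.
#' @param follow_edges list of [follow_edge()] objects.
#' @return an object of class `mouse_profile`.
#' @export
mouse_profile <- function(animal_id, sex = "F", weight_g = 26,
                          p_alcohol = 0.5, p_saccharin = 0.8,
                          side_bias = 0,
                          activity = list(peak_h = c(2, 10),
                                          width_h = c(2, 2),
                                          amplitude = c(12, 10),
                                          floor_frac = 0.05),
                          licks_per_event = list(mean = 30, dispersion = 5),
                          persistence = 21,
                          follow_edges = list()) {
  stopifnot(is.character(animal_id), nchar(animal_id) > 0,
            weight_g > 0,
            p_alcohol >= 0, p_alcohol <= 1,
            p_saccharin >= 0, p_saccharin <= 1,
            side_bias >= -1, side_bias <= 1,
            length(activity$peak_h) == length(activity$amplitude),
            all(activity$amplitude >= 0),
            licks_per_event$mean >= 1)
  for (e in follow_edges) stopifnot(inherits(e, "follow_edge"))
  structure(list(animal_id = animal_id, sex = sex, weight_g = weight_g,
                 p_alcohol = p_alcohol, p_saccharin = p_saccharin,
                 side_bias = side_bias, activity = activity,
                 licks_per_event = licks_per_event,
                 persistence = persistence, follow_edges = follow_edges),
            class = "mouse_profile")
}

#' Declare a follow relationship for the simulator
#'
#' After each visit by `target`, the owning mouse follows to the same corner
#' with probability `p_follow`, entering at a latency drawn uniformly from
#' `[latency_min, latency_max]` seconds. The support must lie inside the
#' 1-60 s window of the social pair filter, otherwise the injected edge
#' would be undetectable by construction.
#'
#' @param target animal_id of the mouse being followed.
#' @param p_follow follow probability in \[0, 1\].
#' @param latency_min,latency_max latency bounds in seconds.
#' @return an object of class `follow_edge`.
#' @export
follow_edge <- function(target, p_follow, latency_min = 2,
                        latency_max = 30) {
  stopifnot(p_follow >= 0, p_follow <= 1)
  if (latency_min < 1 || latency_max > 60 || latency_min > latency_max)
    stop("follow latency support must lie within [1, 60] s")
  structure(list(target = target, p_follow = p_follow,
                 latency_min = latency_min, latency_max = latency_max),
            class = "follow_edge")
}

#' Cohort configuration for the simulator
#'
#' @param profiles list of [mouse_profile()] objects (typical cohort sizes
#'   are 10 males or 14 females).
#' @param sessions a `cage_schedule` defining the simulated time span and
#'   the bottle contents/contingencies.
#' @param seed integer RNG seed; a fixed seed makes [simulate_cohort()]
#'   reproducible bit-for-bit.
#' @param visit_duration list with `meanlog` and `sdlog` of the log-normal
#'   visit duration in seconds. The default (median 20 s) puts the large
#'   majority of visits under one minute with a rare tail beyond 10 min.
#' @param p_attempt probability that a visit includes a drinking attempt.
#' @param suppression multiplier on the visit rate of a mouse to a corner
#'   where it has been punished (air puff); visits are thinned to this
#'   fraction from the first punishment onward.
#' @param dark_onset_h clock hours from experiment start to dark onset.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(profiles, sessions, seed = 1,
                          visit_duration = list(meanlog = log(20), sdlog = 1),
                          p_attempt = 0.6, suppression = 0.3,
                          dark_onset_h = 3) {
  stopifnot(length(profiles) >= 1, inherits(sessions, "cage_schedule"),
            suppression >= 0, suppression <= 1,
            p_attempt >= 0, p_attempt <= 1)
  for (p in profiles) stopifnot(inherits(p, "mouse_profile"))
  ids <- vapply(profiles, `[[`, "", "animal_id")
  if (anyDuplicated(ids)) stop("duplicate animal_id among profiles")
  for (p in profiles) {
    for (e in p$follow_edges) {
      if (!e$target %in% ids) stop("follow target not in cohort: ", e$target)
      if (e$target == p$animal_id) stop("a mouse cannot follow itself")
    }
  }
  structure(list(profiles = profiles, sessions = sessions,
                 seed = as.integer(seed), visit_duration = visit_duration,
                 p_attempt = p_attempt, suppression = suppression,
                 dark_onset_h = dark_onset_h),
            class = "cohort_config")
}

# visit rate (visits/hour) at hour-of-day hod for an activity spec
activity_rate <- function(act, hod, dark_onset_h) {
  amp <- act$amplitude
  if (!any(amp > 0)) return(rep(0, length(hod)))
  base <- act$floor_frac * mean(amp)
  hd <- (hod - dark_onset_h) %% 24  # hours since dark onset
  r <- rep(base, length(hod))
  dark <- hd < 12
  for (i in seq_along(amp)) {
    r[dark] <- r[dark] +
      amp[i] * exp(-0.5 * ((hd[dark] - act$peak_h[i]) / act$width_h[i])^2)
  }
  r
}

# log-normal draws for visit durations
draw_durations <- function(n, vd) stats::rlnorm(n, vd$meanlog, vd$sdlog)

# greedy non-overlap filter: keep a visit only if it starts after the
# previous kept visit has ended (a mouse is in one corner at a time)
drop_overlaps <- function(t_start, t_end) {
  n <- length(t_start)
  keep <- logical(n)
  last_end <- -Inf
  for (i in seq_len(n)) {
    if (t_start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- t_end[i]
    }
  }
  keep
}

# base visit skeleton (times, durations, corners) for one mouse
simulate_skeleton <- function(profile, t0, t1, vd, dark_onset_h) {
  hours <- seq(floor(t0 / 3600), ceiling(t1 / 3600) - 1)
  if (!length(hours)) return(empty_records())
  rate <- activity_rate(profile$activity, hours %% 24, dark_onset_h)
  n_h <- stats::rpois(length(hours), rate)
  if (sum(n_h) == 0) return(empty_records())
  t_start <- sort(rep(hours, n_h) * 3600 + stats::runif(sum(n_h), 0, 3600))
  t_start <- t_start[t_start >= t0 & t_start < t1]
  n <- length(t_start)
  if (!n) return(empty_records())
  dur <- draw_durations(n, vd)
  keep <- drop_overlaps(t_start, t_start + dur)
  t_start <- t_start[keep]; dur <- dur[keep]; n <- length(t_start)
  data.frame(animal_id = rep(profile$animal_id, n),
             corner = sample(1:4, n, replace = TRUE),
             t_start = t_start, t_end = t_start + dur,
             nosepokes_left = 0L, nosepokes_right = 0L,
             licks_left = 0L, licks_right = 0L,
             stringsAsFactors = FALSE)
}

# content-completion probability for one bottle content
content_pref <- function(profile, cont_str) {
  k <- parse_content(cont_str)$kind
  switch(k,
         alcohol = profile$p_alcohol,
         saccharin = profile$p_saccharin,
         water = 1 - profile$p_alcohol)
}

# shifted negative binomial lick burst (always >= 1)
draw_licks <- function(lp) {
  1L + stats::rnbinom(1L, mu = max(lp$mean - 1, 0.01), size = lp$dispersion)
}

#' Simulate a cohort event table
#'
#' Agent-based generator of corner-visit logs with the statistical structure
#' the downstream analyses assume. Visit times are drawn from each mouse's
#' inhomogeneous-rate circadian curve; corner choice is uniform except when
#' a follow edge fires (with probability `p_follow` after a target's visit
#' the follower schedules a visit to the same corner at a short latency);
#' at reward corners the bottle is chosen by content preference and side
#' bias; licks are emitted only when the session contingency is satisfied
#' (free access, or the FR/PR nose-poke criterion met within one visit);
#' under a punishment-risk contingency each completion is punished with the
#' stated probability and a punished mouse's subsequent visits to that
#' corner are thinned by the `suppression` factor.
#'
#' The output is deterministic for a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return an `event_table`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sessions <- config$sessions
  t0 <- min(vapply(sessions, `[[`, 0, "start"))
  t1 <- max(vapply(sessions, `[[`, 0, "end"))
  profiles <- config$profiles
  ids <- vapply(profiles, `[[`, "", "animal_id")

  skeletons <- lapply(profiles, simulate_skeleton, t0 = t0, t1 = t1,
                      vd = config$visit_duration,
                      dark_onset_h = config$dark_onset_h)
  names(skeletons) <- ids

  # follow edges: insert visits keyed on the target's *base* skeleton so
  # two mutual followers do not chain reactively
  extra <- list()
  for (p in profiles) {
    for (e in p$follow_edges) {
      lead <- skeletons[[e$target]]
      if (!nrow(lead)) next
      fire <- stats::runif(nrow(lead)) < e$p_follow
      m <- sum(fire)
      if (!m) next
      lat <- stats::runif(m, e$latency_min, e$latency_max)
      dur <- draw_durations(m, config$visit_duration)
      extra[[length(extra) + 1L]] <-
        data.frame(animal_id = rep(p$animal_id, m),
                   corner = lead$corner[fire],
                   t_start = lead$t_start[fire] + lat,
                   t_end = lead$t_start[fire] + lat + dur,
                   nosepokes_left = 0L, nosepokes_right = 0L,
                   licks_left = 0L, licks_right = 0L,
                   stringsAsFactors = FALSE)
    }
  }

  out <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    sk <- skeletons[[p$animal_id]]
    ex <- extra[vapply(extra, function(d) d$animal_id[1] == p$animal_id, TRUE)]
    if (length(ex)) {
      sk <- rbind(sk, do.call(rbind, ex))
      sk <- sk[order(sk$t_start), , drop = FALSE]
    }
    out[[i]] <- simulate_rewards(p, sk, sessions, config)
  }
  records <- do.call(rbind, out)
  rost <- data.frame(animal_id = ids,
                     sex = vapply(profiles, `[[`, "", "sex"),
                     weight_g = vapply(profiles, `[[`, 0, "weight_g"),
                     stringsAsFactors = FALSE)
  event_table(records, roster = rost, dark_onset_h = config$dark_onset_h,
              validate = FALSE)
}

# walk one mouse's visits chronologically, assigning nose pokes and licks
# according to the session contingency; stateful for PR criteria and
# punishment suppression
simulate_rewards <- function(profile, sk, sessions, config) {
  n <- nrow(sk)
  if (!n) return(sk)
  starts <- vapply(sessions, `[[`, 0, "start")
  ends <- vapply(sessions, `[[`, 0, "end")
  pr_state <- rep(NA_integer_, 4L)   # current PR criterion per corner
  pr_session <- rep(NA_integer_, 4L) # session the criterion belongs to
  suppressed <- rep(FALSE, 4L)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    cr <- sk$corner[i]
    if (suppressed[cr] && stats::runif(1) > config$suppression) {
      keep[i] <- FALSE
      next
    }
    si <- which(sk$t_start[i] >= starts & sk$t_start[i] < ends)
    if (!length(si)) next
    si <- si[1]
    ses <- sessions[[si]]
    cs <- ses$contents[[as.character(cr)]]
    is_reward_corner <- any(content_kind(cs) != "water")
    cont <- if (is_reward_corner) ses$contingency else ses$water_contingency

    if (stats::runif(1) >= config$p_attempt) {
      # exploratory visit: occasional stray nose pokes, no drinking
      pk <- stats::rpois(1L, 0.3)
      if (pk > 0) {
        side <- if (stats::runif(1) < 0.5) "left" else "right"
        col <- paste0("nosepokes_", side)
        sk[[col]][i] <- sk[[col]][i] + pk
      }
      next
    }

    # bottle choice: content preference first, then side bias on ties
    wl <- content_pref(profile, cs["left"])
    wr <- content_pref(profile, cs["right"])
    if (cs["left"] == cs["right"]) {
      pb <- (1 + profile$side_bias) / 2
      wl <- wl * (1 - pb); wr <- wr * pb
    }
    if (wl + wr <= 0) next
    side <- if (stats::runif(1) < wr / (wl + wr)) "right" else "left"
    drink <- stats::runif(1) < content_pref(profile, cs[side])
    if (!drink) next

    np_col <- paste0("nosepokes_", side)
    lk_col <- paste0("licks_", side)
    licks <- draw_licks(profile$licks_per_event)
    type <- cont$type
    if (type == "free") {
      sk[[np_col]][i] <- sk[[np_col]][i] + stats::rpois(1L, 1)
      sk[[lk_col]][i] <- sk[[lk_col]][i] + licks
    } else if (type == "FR") {
      sk[[np_col]][i] <- sk[[np_col]][i] + cont$n
      sk[[lk_col]][i] <- sk[[lk_col]][i] + licks
    } else if (type == "FR_risk") {
      sk[[np_col]][i] <- sk[[np_col]][i] + cont$n
      punished <- stats::runif(1) < cont$risk / 100
      if (!punished || cont$delay_s > 0) {
        # with a delayed puff the animal reaches the bottle before the hit
        sk[[lk_col]][i] <- sk[[lk_col]][i] + licks
      }
      if (punished) suppressed[cr] <- TRUE
    } else if (type == "PR") {
      if (is.na(pr_session[cr]) || pr_session[cr] != si) {
        pr_state[cr] <- cont$start
        pr_session[cr] <- si
      }
      crit <- pr_state[cr]
      p_complete <- if (crit <= profile$persistence) 0.9 else 0.05
      if (stats::runif(1) < p_complete) {
        sk[[np_col]][i] <- sk[[np_col]][i] + crit
        if (stats::runif(1) < 0.9)
          sk[[lk_col]][i] <- sk[[lk_col]][i] + licks
        pr_state[cr] <- crit + cont$increment
      } else {
        sk[[np_col]][i] <- sk[[np_col]][i] +
          min(crit - 1L, stats::rpois(1L, 2))
      }
    }
  }
  sk[keep, , drop = FALSE]
}

#' Inject a follower relationship into an existing event table
#'
#' For each visit of `leader`, with probability `p_follow` a visit by
#' `follower` to the same corner is inserted at the leader's entry time plus
#' a drawn latency. Latencies must lie within the 1-60 s social-analysis
#' window, so every inserted pair qualifies under the pair-count gap filter.
#' Intended as a fixture generator for testing social-inference recovery.
#'
#' @param table an `event_table`.
#' @param leader,follower animal ids (must differ and be in the roster).
#' @param p_follow follow probability in \[0, 1\].
#' @param latency numeric `c(min, max)` for a uniform latency in seconds, or
#'   a function `n -> n latencies`.
#' @param duration_s duration given to inserted visits.
#' @param seed optional seed for the insertion draws.
#' @return a re-sorted `event_table` with the inserted visits.
#' @export
inject_follower <- function(table, leader, follower, p_follow,
                            latency = c(2, 30), duration_s = 10,
                            seed = NULL) {
  stopifnot(is_event_table(table), p_follow >= 0, p_follow <= 1)
  ids <- roster(table)$animal_id
  if (!leader %in% ids) stop("unknown leader: ", leader)
  if (!follower %in% ids) stop("unknown follower: ", follower)
  if (leader == follower) stop("leader and follower must differ")
  if (!is.null(seed)) set.seed(seed)
  lead <- table[table$animal_id == leader, , drop = FALSE]
  fire <- stats::runif(nrow(lead)) < p_follow
  m <- sum(fire)
  if (m == 0) return(table)
  lat <- if (is.function(latency)) latency(m)
         else stats::runif(m, latency[1], latency[2])
  if (any(lat < 1 | lat > 60))
    stop("follow latency support must lie within [1, 60] s")
  ins <- data.frame(animal_id = rep(follower, m),
                    corner = lead$corner[fire],
                    t_start = lead$t_start[fire] + lat,
                    t_end = lead$t_start[fire] + lat + duration_s,
                    nosepokes_left = 0L, nosepokes_right = 0L,
                    licks_left = 0L, licks_right = 0L,
                    stringsAsFactors = FALSE)
  event_table(rbind(as.data.frame(table), ins), roster = roster(table),
              dark_onset_h = attr(table, "dark_onset_h"), validate = FALSE)
}
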