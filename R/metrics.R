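#' Two-bottle preference ratio
#'
#' `alcohol_licks / (alcohol_licks + water_licks)`. Undefined (returned as
#' `NA`) when both counts are zero: "no drinking" is distinguished from "no
#' preference".
#'
#' @param licks_alcohol,licks_water non-negative lick counts (vectorized).
#' @return ratio in \[0, 1\], `NA` where both counts are 0.
#' @examples
#' preference_ratio(509, 491)  # 0.509
#' @export
preference_ratio <- function(licks_alcohol, licks_water) {
  if (any(licks_alcohol < 0, na.rm = TRUE) ||
      any(licks_water < 0, na.rm = TRUE))
    stop("lick counts must be non-negative")
  tot <- licks_alcohol + licks_water
  ifelse(tot > 0, licks_alcohol / tot, NA_real_)
}

#' Bottle-side bias index
#'
#' `(right_licks - left_licks) / (right_licks + left_licks)`; -1 means all
#' licks on the left bottle, +1 all on the right. `NA` when both are zero.
#'
#' @param licks_left,licks_right non-negative lick counts (vectorized).
#' @return index in \[-1, 1\], `NA` where both counts are 0.
#' @export
side_bias <- function(licks_left, licks_right) {
  if (any(licks_left < 0, na.rm = TRUE) || any(licks_right < 0, na.rm = TRUE))
    stop("lick counts must be non-negative")
  tot <- licks_left + licks_right
  ifelse(tot > 0, (licks_right - licks_left) / tot, NA_real_)
}

#' Classify a side-bias index
#'
#' Strict thresholds: `strong_left` iff index < -0.6, `strong_right` iff
#' index > 0.6, otherwise `none` (so exactly -0.6 or 0.6 is `none`).
#'
#' @param index side-bias values in \[-1, 1\].
#' @param threshold magnitude above which a bias counts as strong.
#' @return factor with levels `strong_left`, `none`, `strong_right`.
#' @export
classify_bias <- function(index, threshold = 0.6) {
  stopifnot(all(abs(index) <= 1, na.rm = TRUE), threshold > 0)
  out <- rep("none", length(index))
  out[!is.na(index) & index < -threshold] <- "strong_left"
  out[!is.na(index) & index > threshold] <- "strong_right"
  out[is.na(index)] <- NA
  factor(out, levels = c("strong_left", "none", "strong_right"))
}

day_index <- function(t) floor(t / 86400) + 1L

#' Per-mouse daily activity summary
#'
#' Days are 24 h windows aligned to experiment start. A drinking episode is
#' a visit with at least one lick on either bottle; corner time is the sum
#' of visit durations.
#'
#' @param table an `event_table`.
#' @return data.frame with `animal_id`, `day`, `time_s`, `visits`,
#'   `episodes`, one row per mouse per day with any visit.
#' @export
daily_summary <- function(table) {
  stopifnot(is_event_table(table))
  if (!nrow(table)) {
    return(data.frame(animal_id = character(0), day = integer(0),
                      time_s = numeric(0), visits = integer(0),
                      episodes = integer(0), stringsAsFactors = FALSE))
  }
  d <- data.frame(animal_id = table$animal_id,
                  day = day_index(table$t_start),
                  dur = table$t_end - table$t_start,
                  drank = (table$licks_left + table$licks_right) > 0)
  agg <- stats::aggregate(cbind(time_s = dur, visits = 1, episodes = drank)
                          ~ animal_id + day, data = d, FUN = sum)
  agg$visits <- as.integer(agg$visits)
  agg$episodes <- as.integer(agg$episodes)
  agg[order(agg$animal_id, agg$day), c("animal_id", "day", "time_s",
                                       "visits", "episodes")]
}

#' Circadian activity profile
#'
#' Hourly visit counts per mouse, averaged over selected 24 h intervals
#' (days aligned to experiment start). Bin `h` covers the clock interval
#' `(h - 1, h]`: each value is the sum from the preceding hour, so a visit
#' at clock hour 13.5 lands in bin 14.
#'
#' @param table an `event_table`.
#' @param intervals integer day indices (1-based) to average over; `NULL`
#'   uses every day spanned by the table.
#' @return numeric matrix, one row per roster animal, 24 columns (mean
#'   visits per hour bin).
#' @export
circadian_profile <- function(table, intervals = NULL) {
  stopifnot(is_event_table(table))
  ids <- roster(table)$animal_id
  prof <- matrix(0, nrow = length(ids), ncol = 24,
                 dimnames = list(ids, paste0("h", 1:24)))
  if (is.null(intervals)) {
    intervals <- if (nrow(table)) {
      seq(min(day_index(table$t_start)), max(day_index(table$t_start)))
    } else integer(0)
  }
  if (!length(intervals)) return(prof)
  keep <- day_index(table$t_start) %in% intervals
  tt <- table[keep, , drop = FALSE]
  if (nrow(tt)) {
    hod <- (tt$t_start / 3600) %% 24
    bin <- ceiling(hod)
    bin[bin == 0] <- 24L
    tab <- table(factor(tt$animal_id, levels = ids),
                 factor(bin, levels = 1:24))
    prof <- prof + unclass(tab)
  }
  prof / length(intervals)
}

#' Visit-duration and revisit-interval distributions
#'
#' Log-binned histograms of (a) the durations of all corner visits and
#' (b) the intervals between two consecutive visits of the same animal to
#' the same corner (next `t_start` minus current `t_end`).
#'
#' @param table an `event_table`.
#' @param breaks histogram bin edges in seconds (log-spaced by default);
#'   values outside the range are clamped into the outermost bins.
#' @return list with components `durations` and `revisit_intervals`, each a
#'   list of `counts`, `breaks` and the raw `values`.
#' @export
duration_distributions <- function(table,
                                   breaks = 10^seq(-1, 5, by = 0.25)) {
  stopifnot(is_event_table(table))
  dur <- table$t_end - table$t_start
  gaps <- numeric(0)
  if (nrow(table)) {
    sp <- split(seq_len(nrow(table)),
                list(table$animal_id, table$corner), drop = TRUE)
    for (ix in sp) {
      if (length(ix) > 1) {
        ix <- ix[order(table$t_start[ix])]
        gaps <- c(gaps, table$t_start[ix][-1] -
                          table$t_end[ix][-length(ix)])
      }
    }
  }
  bin_counts <- function(v) {
    if (!length(v)) return(integer(length(breaks) - 1L))
    vc <- pmin(pmax(v, breaks[1]), breaks[length(breaks)])
    b <- findInterval(vc, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    tabulate(b, nbins = length(breaks) - 1L)
  }
  list(durations = list(counts = bin_counts(dur), breaks = breaks,
                        values = dur),
       revisit_intervals = list(counts = bin_counts(gaps), breaks = breaks,
                                values = sort(gaps)))
}

#' Ethanol intake and dose conversion
#'
#' Converts lick counts to consumed ethanol mass and body-weight-normalized
#' dose. One lick corresponds to `lick_volume_ul` microliters of fluid
#' (3 ul by default). Under the default `"v/v"` convention the ethanol mass
#' is `volume_ml * concentration/100 * density`; under `"w/v"` it is
#' `volume_ml * concentration/100` (grams per 100 ml of solution). An
#' already-known intake mass can be supplied directly via `intake_g`,
#' bypassing the lick conversion.
#'
#' @param licks lick count on the ethanol bottles.
#' @param concentration ethanol concentration in percent.
#' @param weight_g body weight in grams (> 0).
#' @param lick_volume_ul fluid volume per lick, microliters.
#' @param ethanol_density_g_per_ml ethanol density (v/v convention only).
#' @param intake_g optional ethanol mass in grams, overriding the lick
#'   conversion.
#' @param convention `"v/v"` (volume fraction times density, default) or
#'   `"w/v"` (mass per solution volume).
#' @return list with `intake_g` and `dose_g_per_kg`.
#' @examples
#' intake_dose(intake_g = 0.436, weight_g = 26)$dose_g_per_kg  # ~16.8
#' @export
intake_dose <- function(licks = NULL, concentration = 12, weight_g,
                        lick_volume_ul = 3,
                        ethanol_density_g_per_ml = 0.789,
                        intake_g = NULL,
                        convention = c("v/v", "w/v")) {
  convention <- match.arg(convention)
  if (any(weight_g <= 0)) stop("weight_g must be > 0")
  if (is.null(intake_g)) {
    if (is.null(licks)) stop("supply either licks or intake_g")
    if (any(licks < 0)) stop("licks must be non-negative")
    vol_ml <- licks * lick_volume_ul * 1e-3
    intake_g <- vol_ml * concentration / 100 *
      (if (convention == "v/v") ethanol_density_g_per_ml else 1)
  }
  list(intake_g = intake_g, dose_g_per_kg = intake_g / (weight_g / 1000))
}

#' Rough blood-ethanol estimate from lick rate
#'
#' Linear extrapolation through a single calibration point (300 licks over
#' one hour corresponds to about 0.1 permille w/v). An order-of-magnitude
#' estimate only; no pharmacokinetics are modeled.
#'
#' @param licks_in_window lick count on ethanol bottles within the window.
#' @param window_h window length in hours (> 0).
#' @param calib_licks_per_h,calib_permille the calibration point.
#' @return estimated blood ethanol concentration in permille (w/v).
#' @export
estimate_bec <- function(licks_in_window, window_h,
                         calib_licks_per_h = 300, calib_permille = 0.1) {
  if (any(window_h <= 0)) stop("window_h must be > 0")
  (licks_in_window / window_h) / calib_licks_per_h * calib_permille
}

#' Per-mouse, per-session metrics table
#'
#' Splits an event table by schedule session and computes, for every roster
#' animal and session: licks by bottle content (alcohol / saccharin /
#' water), visits, corner time, drinking episodes, preference ratio,
#' side-bias index, and ethanol intake and dose (from the roster weight).
#'
#' @param table an `event_table`.
#' @param sessions a `cage_schedule`.
#' @param lick_volume_ul,ethanol_density_g_per_ml,convention see
#'   [intake_dose()].
#' @return data.frame, one row per animal x session.
#' @export
session_metrics <- function(table, sessions, lick_volume_ul = 3,
                            ethanol_density_g_per_ml = 0.789,
                            convention = "v/v") {
  stopifnot(is_event_table(table))
  rost <- roster(table)
  rows <- list()
  for (si in seq_along(sessions)) {
    ses <- sessions[[si]]
    w <- session_window(ses)
    tt <- table[table$t_start >= w[1] & table$t_start < w[2], ,
                drop = FALSE]
    kinds <- vapply(ses$contents, content_kind, c("", ""))  # 2 x 4
    concs <- vapply(ses$contents,
                    function(cs) vapply(cs, function(s)
                      parse_content(s)$conc, 0), c(left = 0, right = 0))
    for (ai in seq_len(nrow(rost))) {
      id <- rost$animal_id[ai]
      tm <- tt[tt$animal_id == id, , drop = FALSE]
      lk <- c(alcohol = 0L, saccharin = 0L, water = 0L)
      lleft <- 0L; lright <- 0L
      alc_conc <- NA_real_
      if (nrow(tm)) {
        for (j in seq_len(nrow(tm))) {
          k <- as.character(tm$corner[j])
          for (sd in c("left", "right")) {
            n <- tm[[paste0("licks_", sd)]][j]
            if (n > 0) {
              kd <- kinds[sd, k]
              lk[kd] <- lk[kd] + n
              if (sd == "left") lleft <- lleft + n else lright <- lright + n
              if (kd == "alcohol") alc_conc <- concs[sd, k]
            }
          }
        }
      }
      if (is.na(rost$weight_g[ai])) {
        dose <- list(intake_g = NA_real_, dose_g_per_kg = NA_real_)
      } else {
        dose <- intake_dose(
          licks = unname(lk["alcohol"]),
          concentration = if (is.na(alc_conc)) 12 else alc_conc,
          weight_g = rost$weight_g[ai],
          lick_volume_ul = lick_volume_ul,
          ethanol_density_g_per_ml = ethanol_density_g_per_ml,
          convention = convention)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, session = ses$index,
        licks_alcohol = unname(lk["alcohol"]),
        licks_saccharin = unname(lk["saccharin"]),
        licks_water = unname(lk["water"]),
        visits = nrow(tm),
        time_s = sum(tm$t_end - tm$t_start),
        episodes = sum((tm$licks_left + tm$licks_right) > 0),
        preference = preference_ratio(unname(lk["alcohol"]),
                                      unname(lk["water"])),
        side_bias = side_bias(lleft, lright),
        intake_g = dose$intake_g,
        dose_g_per_kg = dose$dose_g_per_kg,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
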