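#' Canonical event tables
#'
#' An `event_table` is the package's central container: one row per corner
#' visit of one animal, ordered by visit start time, plus a cohort roster.
#' Times are float seconds since experiment start (the moment of the first
#' bottle exchange). Each corner owns two bottles ("left" and "right", bottle
#' indices `2k-1` and `2k` for corner `k`, numbered clockwise); per-visit
#' nose-poke and lick counts are recorded per side. Lick/nose-poke
#' micro-timestamps are not modeled: per-visit counts suffice for every
#' analysis implemented here.
#'
#' @param records data.frame with columns `animal_id`, `corner`, `t_start`,
#'   `t_end`, `nosepokes_left`, `nosepokes_right`, `licks_left`,
#'   `licks_right`.
#' @param roster data.frame with column `animal_id` and optional `sex` and
#'   `weight_g`; defaults to the animals present in `records`.
#' @param dark_onset_h clock hours from experiment start to the onset of the
#'   dark phase (12 h dark / 12 h light cycle assumed).
#' @param validate if `TRUE`, rows violating the invariants are dropped and
#'   reported via a warning; the dropped rows are kept in the `"rejected"`
#'   attribute.
#' @return an object of class `event_table` (a data.frame with attributes
#'   `roster`, `dark_onset_h` and `rejected`).
#' @seealso [read_events()], [write_events()], [slice_intervals()]
#' @export
event_table <- function(records = empty_records(), roster = NULL,
                        dark_onset_h = 3, validate = TRUE) {
  records <- as.data.frame(records)
  need <- event_columns()
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing event column(s): ", paste(miss, collapse = ", "))
  records <- records[need]
  records$animal_id <- as.character(records$animal_id)
  records$corner <- as.integer(records$corner)
  for (cl in c("t_start", "t_end"))
    records[[cl]] <- as.numeric(records[[cl]])
  for (cl in need[5:8]) records[[cl]] <- as.integer(records[[cl]])

  if (is.null(roster)) {
    ids <- unique(records$animal_id)
    roster <- data.frame(animal_id = ids,
                         sex = rep(NA_character_, length(ids)),
                         weight_g = rep(NA_real_, length(ids)),
                         stringsAsFactors = FALSE)
  }
  roster <- as.data.frame(roster)
  if (!"animal_id" %in% names(roster)) stop("roster must have animal_id")
  roster$animal_id <- as.character(roster$animal_id)
  if (!"sex" %in% names(roster)) roster$sex <- NA_character_
  if (!"weight_g" %in% names(roster)) roster$weight_g <- NA_real_
  if (anyDuplicated(roster$animal_id)) stop("duplicate animal_id in roster")
  if (nrow(records) && nrow(roster) < 1)
    stop("roster must contain at least one animal")

  rejected <- records[0, , drop = FALSE]
  rejected$reason <- character(0)
  if (validate && nrow(records)) {
    reason <- rep(NA_character_, nrow(records))
    bad_corner <- !(records$corner %in% 1:4)
    bad_time <- !is.finite(records$t_start) | !is.finite(records$t_end) |
      records$t_end < records$t_start
    counts <- as.matrix(records[need[5:8]])
    bad_count <- apply(is.na(counts) | counts < 0, 1L, any)
    unknown <- !(records$animal_id %in% roster$animal_id)
    reason[bad_count] <- "negative or missing count"
    reason[bad_time] <- "t_end < t_start or non-finite time"
    reason[bad_corner] <- "corner outside 1..4"
    reason[unknown] <- "animal_id not in roster"
    bad <- !is.na(reason)
    if (any(bad)) {
      rejected <- records[bad, , drop = FALSE]
      rejected$reason <- reason[bad]
      records <- records[!bad, , drop = FALSE]
      warning(sum(bad), " invalid event row(s) rejected", call. = FALSE)
    }
  } else if (nrow(records) && any(!(records$animal_id %in% roster$animal_id))) {
    stop("animal_id not in roster")
  }

  ord <- order(records$t_start, records$t_end, records$animal_id)
  if (is.unsorted(records$t_start)) records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  rownames(rejected) <- NULL
  structure(records,
            roster = roster,
            dark_onset_h = dark_onset_h,
            rejected = rejected,
            class = c("event_table", "data.frame"))
}

event_columns <- function() {
  c("animal_id", "corner", "t_start", "t_end",
    "nosepokes_left", "nosepokes_right", "licks_left", "licks_right")
}

empty_records <- function() {
  data.frame(animal_id = character(0), corner = integer(0),
             t_start = numeric(0), t_end = numeric(0),
             nosepokes_left = integer(0), nosepokes_right = integer(0),
             licks_left = integer(0), licks_right = integer(0),
             stringsAsFactors = FALSE)
}

#' @rdname event_table
#' @param x object to test or print.
#' @export
is_event_table <- function(x) inherits(x, "event_table")

#' Cohort roster of an event table
#' @param table an `event_table`.
#' @return data.frame with `animal_id`, `sex`, `weight_g`.
#' @export
roster <- function(table) attr(table, "roster")

#' Rows rejected during validation
#' @param table an `event_table`.
#' @return data.frame of rejected rows with a `reason` column.
#' @export
rejected_records <- function(table) attr(table, "rejected")

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d visits, %d animals, %.1f h span\n",
              nrow(x), nrow(roster(x)),
              if (nrow(x)) (max(x$t_end) - min(x$t_start)) / 3600 else 0))
  NextMethod()
}

#' Bottle index of a corner side
#'
#' Corner `k` owns bottles `2k - 1` (left) and `2k` (right), numbered
#' clockwise around the cage.
#'
#' @param corner corner 1..4.
#' @param side `"left"` or `"right"`.
#' @return integer bottle index 1..8.
#' @export
bottle_index <- function(corner, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(all(corner %in% 1:4))
  as.integer(2L * corner - (side == "left"))
}

#' Read an event table from the canonical TSV dialect
#'
#' The canonical dialect is tab-separated with a header row carrying exactly
#' the columns `animal_id, corner, t_start, t_end, nosepokes_left,
#' nosepokes_right, licks_left, licks_right` (one visit per row). Rows that
#' violate the invariants (negative counts, `t_end < t_start`, corner outside
#' 1..4, animal not in the roster) are rejected and reported with a warning,
#' not fatal: real cage logs contain glitches such as transponder loss.
#' Unsorted files are repaired (sorted by `t_start`) with a warning.
#'
#' @param path file to read.
#' @param roster optional roster data.frame or path to a roster TSV
#'   (`animal_id`, optional `sex`, `weight_g`).
#' @param dark_onset_h see [event_table()].
#' @return a validated `event_table`.
#' @export
read_events <- function(path, roster = NULL, dark_onset_h = 3) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.character(roster) && length(roster) == 1L)
    roster <- read_roster(roster)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(animal_id = "character"),
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(event_columns(), names(df))
  if (length(miss))
    stop("event file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) && is.unsorted(df$t_start))
    warning("event rows out of time order; repaired by sorting",
            call. = FALSE)
  event_table(df, roster = roster, dark_onset_h = dark_onset_h)
}

#' Write an event table in the canonical TSV dialect
#'
#' Numeric times are written with full precision so that
#' `read_events(write_events(x))` reproduces `x` exactly.
#'
#' @param table an `event_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  stopifnot(is_event_table(table))
  df <- as.data.frame(table)
  df$t_start <- formatC(df$t_start, digits = 17, format = "g")
  df$t_end <- formatC(df$t_end, digits = 17, format = "g")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a roster TSV
#' @param path roster file (`animal_id`, optional `sex`, `weight_g`).
#' @return data.frame roster.
#' @export
read_roster <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(animal_id = "character"),
                          encoding = "UTF-8")
  if (!"animal_id" %in% names(df)) stop("roster file must have animal_id")
  df
}

#' @rdname read_roster
#' @param roster roster data.frame.
#' @export
write_roster <- function(roster, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(roster, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict an event table to selected schedule sessions
#'
#' Keeps the records whose `t_start` lies inside the half-open window
#' `[start, end)` of a selected session. The half-open convention means a
#' visit starting exactly at a bottle-exchange instant belongs to the new
#' session, never to both.
#'
#' @param table an `event_table`.
#' @param sessions a `cage_schedule` (see [build_intermittent()]).
#' @param selector which sessions to keep: `"all"`, `"alcohol"`,
#'   `"last <k> alcohol"`, `"first <k> alcohol"`, or an integer vector of
#'   session indices.
#' @return an `event_table` containing only the matching records; the chosen
#'   session indices are stored in the `"sessions_selected"` attribute.
#' @export
slice_intervals <- function(table, sessions, selector = "all") {
  stopifnot(is_event_table(table))
  sel <- select_sessions(sessions, selector)
  if (!length(sel)) stop("selector matched no sessions")
  keep <- rep(FALSE, nrow(table))
  for (s in sel) {
    w <- session_window(sessions[[s]])
    keep <- keep | (table$t_start >= w[1] & table$t_start < w[2])
  }
  out <- event_table(as.data.frame(table)[keep, , drop = FALSE],
                     roster = roster(table),
                     dark_onset_h = attr(table, "dark_onset_h"),
                     validate = FALSE)
  attr(out, "sessions_selected") <- sel
  out
}

#' @rdname slice_intervals
#' @export
select_sessions <- function(sessions, selector = "all") {
  stopifnot(inherits(sessions, "cage_schedule"), length(sessions) >= 1)
  idx <- seq_along(sessions)
  if (is.numeric(selector)) {
    if (!all(selector %in% idx)) stop("session index out of range")
    return(as.integer(selector))
  }
  stopifnot(is.character(selector), length(selector) == 1L)
  sel <- trimws(tolower(selector))
  if (sel == "all") return(idx)
  alc <- idx[vapply(sessions, session_has_alcohol, TRUE)]
  if (sel == "alcohol") {
    if (!length(alc)) stop("no alcohol sessions in schedule")
    return(alc)
  }
  m <- regmatches(sel, regexec("^(last|first)\\s+(\\d+)\\s+alcohol$", sel))[[1]]
  if (!length(m)) stop("unrecognized selector: ", selector)
  k <- as.integer(m[3])
  if (length(alc) < k)
    stop("requested ", k, " alcohol sessions but schedule has ", length(alc))
  if (m[2] == "last") utils::tail(alc, k) else utils::head(alc, k)
}
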