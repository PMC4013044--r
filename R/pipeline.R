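#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate -> slice -> metrics -> operant -> social
#' on one configuration and writes all outputs plus a manifest into an
#' output directory. Outputs are written to a staging directory first and
#' moved into place only on success, so a failed run leaves no partial
#' output files behind. The manifest records package version, seeds and
#' every parameter, and deliberately contains no timestamps so that
#' re-running an identical configuration yields byte-identical outputs.
#'
#' @param config either a path to a JSON configuration file or a list with
#'   (a subset of) the fields:
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{integer master seed (default 1).}
#'     \item{events, roster}{paths to an existing event/roster TSV; if
#'       `events` is absent, `simulate` must be enabled.}
#'     \item{schedule}{path to a schedule JSON, or a list
#'       `list(design = "intermittent", weeks = 4, exchange_hour = 16,
#'       access_mode = "free")`.}
#'     \item{simulate}{`NULL`, or a list with `n_mice` (default 10),
#'       `p_alcohol` (scalar or per-mouse vector, default 0.5),
#'       `side_bias` (default 0) and optionally `amplitude`; profiles are
#'       built with [mouse_profile()] defaults otherwise.}
#'     \item{window}{session selector for the social analysis (default
#'       `"last 4 alcohol"`).}
#'     \item{social}{list with `n_perm` (100), `min_gap` (1), `max_gap`
#'       (60), `drop_repeats` (FALSE), `weak` (2), `strong` (3.5).}
#'     \item{constants}{list with `lick_volume_ul` (3),
#'       `ethanol_density_g_per_ml` (0.789).}
#'   }
#' @return the output directory path, invisibly; files written:
#'   `events.tsv` (if simulated), `roster.tsv`, `schedule.json`,
#'   `metrics.tsv`, `counts.tsv`, `normalized.tsv`, `scores.tsv`,
#'   `edges.tsv`, `nodes.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- pipeline_defaults(config)
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")

  sessions <- resolve_schedule(cfg$schedule)

  if (!is.null(cfg$events)) {
    table <- read_events(cfg$events, roster = cfg$roster)
    simulated <- FALSE
  } else if (!is.null(cfg$simulate)) {
    table <- simulate_from_config(cfg$simulate, sessions, cfg$seed)
    simulated <- TRUE
  } else {
    stop("config error: neither an events file nor a simulate block given")
  }

  staging <- file.path(cfg$out_dir, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE), add = TRUE)

  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(staging, name)
    writer(path)
    written <<- c(written, name)
  }

  if (simulated) emit("events.tsv", function(p) write_events(table, p))
  emit("roster.tsv", function(p) write_roster(roster(table), p))
  emit("schedule.json", function(p) write_schedule(sessions, p))

  metrics <- session_metrics(
    table, sessions,
    lick_volume_ul = cfg$constants$lick_volume_ul,
    ethanol_density_g_per_ml = cfg$constants$ethanol_density_g_per_ml)
  emit("metrics.tsv", function(p) write_tsv(metrics, p))

  window <- tryCatch(slice_intervals(table, sessions, cfg$window),
                     error = function(e)
                       stop("social stage: ", conditionMessage(e),
                            call. = FALSE))
  soc <- cfg$social
  scores <- permutation_scores(window, n_perm = soc$n_perm,
                               seed = cfg$seed + 1L,
                               min_gap = soc$min_gap,
                               max_gap = soc$max_gap,
                               drop_repeats = soc$drop_repeats)
  emit("counts.tsv", function(p) write_matrix(scores$observed, p))
  emit("normalized.tsv",
       function(p) write_matrix(normalize_by_first(scores$observed), p))
  emit("scores.tsv", function(p) write_matrix(scores$scores, p))

  edges <- classify_edges(scores, weak = soc$weak, strong = soc$strong)
  pref <- stats::aggregate(
    cbind(licks_alcohol, licks_water) ~ animal_id, data = metrics, FUN = sum)
  nodes <- merge(roster(table),
                 data.frame(animal_id = pref$animal_id,
                            preference = preference_ratio(
                              pref$licks_alcohol, pref$licks_water)),
                 by = "animal_id", all.x = TRUE)
  emit("edges.tsv", function(p)
    export_network(edges, nodes, p, file.path(staging, "nodes.tsv")))
  written <- c(written, "nodes.tsv")

  manifest <- list(
    package = "homecage",
    version = as.character(utils::packageVersion("homecage")),
    seed = cfg$seed,
    window = cfg$window,
    social = soc,
    constants = cfg$constants,
    simulated = simulated,
    events = if (simulated) "events.tsv" else cfg$events,
    n_animals = nrow(roster(table)),
    n_records = nrow(table),
    outputs = sort(unique(written)))
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, "manifest.json")

  for (f in unique(written)) {
    file.copy(file.path(staging, f), file.path(cfg$out_dir, f),
              overwrite = TRUE)
  }
  unlink(staging, recursive = TRUE)
  ok <- TRUE
  invisible(cfg$out_dir)
}

pipeline_defaults <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(
    out_dir = NULL, seed = 1L, events = NULL, roster = NULL,
    schedule = list(design = "intermittent", weeks = 4,
                    exchange_hour = 16, access_mode = "free"),
    simulate = NULL, window = "last 4 alcohol",
    social = list(n_perm = 100, min_gap = 1, max_gap = 60,
                  drop_repeats = FALSE, weak = 2, strong = 3.5),
    constants = list(lick_volume_ul = 3,
                     ethanol_density_g_per_ml = 0.789))
  cfg <- utils::modifyList(defaults, config)
  cfg$social <- utils::modifyList(defaults$social,
                                  as.list(cfg$social %||% list()))
  cfg$constants <- utils::modifyList(defaults$constants,
                                     as.list(cfg$constants %||% list()))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_schedule <- function(schedule) {
  if (inherits(schedule, "cage_schedule")) return(schedule)
  if (is.character(schedule) && length(schedule) == 1L)
    return(read_schedule(schedule))
  stopifnot(is.list(schedule))
  design <- schedule$design %||% "intermittent"
  switch(design,
    intermittent = build_intermittent(
      weeks = schedule$weeks %||% 4,
      exchange_hour = schedule$exchange_hour %||% 16,
      access_mode = schedule$access_mode %||% "free"),
    quinine = build_quinine_sequence(
      start_s = schedule$start_s %||% 0,
      access_mode = schedule$access_mode %||% "free"),
    pr = build_pr_sequence(variant = schedule$variant %||% "male",
                           reward = schedule$reward %||% "alcohol",
                           start_s = schedule$start_s %||% 0),
    punishment = build_punishment_sequence(
      variant = schedule$variant %||% "male",
      reward = schedule$reward %||% "alcohol",
      start_s = schedule$start_s %||% 0),
    stop("config error: unknown schedule design: ", design))
}

simulate_from_config <- function(sim, sessions, seed) {
  n <- sim$n_mice %||% 10
  p_alc <- rep_len(sim$p_alcohol %||% 0.5, n)
  bias <- rep_len(sim$side_bias %||% 0, n)
  amp <- sim$amplitude %||% c(12, 10)
  ids <- sprintf("m%02d", seq_len(n))
  profiles <- lapply(seq_len(n), function(i)
    mouse_profile(ids[i], p_alcohol = p_alc[i], side_bias = bias[i],
                  activity = list(peak_h = c(2, 10), width_h = c(2, 2),
                                  amplitude = amp, floor_frac = 0.05)))
  simulate_cohort(cohort_config(profiles, sessions, seed = seed))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

write_matrix <- function(m, path) {
  df <- as.data.frame(as.matrix(m))
  df <- cbind(second = rownames(m), df)
  write_tsv(df, path)
}
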