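#' Bottle content descriptors
#'
#' Bottle contents are encoded as compact strings: `"water"`,
#' `"alcohol:12"` (12% v/v ethanol), `"saccharin:0.02"` (0.02% w/v), with an
#' optional quinine adulterant suffix, e.g. `"alcohol:12+quinine:0.03"`.
#' These strings are what schedules store and what the simulator and the
#' metrics layer interpret.
#'
#' @param kind one of `"water"`, `"alcohol"`, `"saccharin"`.
#' @param conc concentration in percent (v/v for alcohol, w/v for saccharin);
#'   ignored for water.
#' @param quinine optional quinine concentration in % w/v.
#' @return a single content string.
#' @examples
#' content("alcohol", 12, quinine = 0.01)
#' @export
content <- function(kind = c("water", "alcohol", "saccharin"),
                    conc = NULL, quinine = NULL) {
  kind <- match.arg(kind)
  if (kind == "water") {
    if (!is.null(quinine)) stop("quinine-adulterated water is not modeled")
    return("water")
  }
  if (is.null(conc) || !is.numeric(conc) || conc <= 0)
    stop("a positive concentration is required for ", kind)
  s <- sprintf("%s:%g", kind, conc)
  if (!is.null(quinine)) {
    if (!is.numeric(quinine) || quinine <= 0) stop("quinine must be > 0")
    s <- sprintf("%s+quinine:%g", s, quinine)
  }
  s
}

#' Parse a content string
#'
#' @param x content string as produced by [content()].
#' @return list with elements `kind`, `conc` (NA for water) and `quinine`
#'   (NA when absent).
#' @export
parse_content <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, "+", fixed = TRUE)[[1]]
  main <- strsplit(parts[1], ":", fixed = TRUE)[[1]]
  kind <- main[1]
  if (!kind %in% c("water", "alcohol", "saccharin"))
    stop("unknown content kind: ", kind)
  conc <- if (length(main) > 1) as.numeric(main[2]) else NA_real_
  quin <- NA_real_
  if (length(parts) > 1) {
    q <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
    if (q[1] != "quinine") stop("unknown adulterant: ", q[1])
    quin <- as.numeric(q[2])
  }
  list(kind = kind, conc = conc, quinine = quin)
}

content_kind <- function(x) vapply(x, function(s) parse_content(s)$kind, "")

#' @rdname parse_content
#' @export
is_alcohol <- function(x) content_kind(x) == "alcohol"

#' Access contingencies
#'
#' Constructors for the reinforcement contingency attached to a session:
#' free access, fixed ratio (`n` nose pokes within one visit open the gate),
#' progressive ratio (the requirement starts at `start` and grows by
#' `increment` after every completion) and fixed ratio with a probabilistic
#' air-puff punishment.
#'
#' @param n fixed-ratio requirement (nose pokes per gate opening).
#' @param start,increment progressive-ratio starting requirement and step.
#' @param risk punishment probability in percent (e.g. 25).
#' @param delay_s seconds between criterion completion and the air puff;
#'   0 means immediate.
#' @param pressure_bar air-puff pressure in bar.
#' @return a list of class `"contingency"`.
#' @export
contingency_free <- function() {
  structure(list(type = "free"), class = "contingency")
}

#' @rdname contingency_free
#' @export
contingency_fr <- function(n = 3) {
  stopifnot(n >= 1)
  structure(list(type = "FR", n = as.integer(n)), class = "contingency")
}

#' @rdname contingency_free
#' @export
contingency_pr <- function(start = 3, increment = 3) {
  if (start < 1) stop("PR start must be >= 1")
  if (increment < 1) stop("PR increment must be >= 1")
  structure(list(type = "PR", start = as.integer(start),
                 increment = as.integer(increment)), class = "contingency")
}

#' @rdname contingency_free
#' @export
contingency_fr_risk <- function(n = 3, risk = 25, delay_s = 2,
                                pressure_bar = 0.5) {
  stopifnot(n >= 1, risk >= 0, risk <= 100, delay_s >= 0, pressure_bar > 0)
  structure(list(type = "FR_risk", n = as.integer(n), risk = risk,
                 delay_s = delay_s, pressure_bar = pressure_bar),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(switch(x$type,
    free = "free access",
    FR = sprintf("FR%d", x$n),
    PR = sprintf("PR(start=%d, +%d)", x$start, x$increment),
    FR_risk = sprintf("FR%d + %g%% risk (%g s delay, %g bar)",
                      x$n, x$risk, x$delay_s, x$pressure_bar)), "\n")
  invisible(x)
}
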