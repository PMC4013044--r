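# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (explicit loops, full enumeration) so they cannot share
# a bug with the vectorized implementations they check.

# adjacent-pair counter: explicit loop over positions
brute_pairs <- function(animal, t, animals, min_gap = 1, max_gap = 60,
                        drop_repeats = FALSE) {
  if (drop_repeats) {
    keep <- rep(TRUE, length(animal))
    for (i in seq_along(animal)[-1]) {
      if (animal[i] == animal[i - 1]) keep[i] <- FALSE
    }
    animal <- animal[keep]
    t <- t[keep]
  }
  m <- matrix(0L, length(animals), length(animals),
              dimnames = list(second = animals, first = animals))
  if (length(animal) >= 2) {
    for (i in seq_len(length(animal) - 1)) {
      gap <- t[i + 1] - t[i]
      if (gap >= min_gap && gap <= max_gap) {
        m[animal[i + 1], animal[i]] <- m[animal[i + 1], animal[i]] + 1L
      }
    }
  }
  m
}

# all permutations of 1..n as a list (n <= 8)
enum_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enum_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# exact permutation-null mean and SD of pair counts for one corner
# sequence: enumerate every label arrangement over the fixed time slots
exact_null <- function(animal, t, animals, min_gap = 1, max_gap = 60,
                       drop_repeats = FALSE) {
  perms <- enum_perms(length(animal))
  counts <- lapply(perms, function(p)
    brute_pairs(animal[p], t, animals, min_gap, max_gap, drop_repeats))
  arr <- simplify2array(counts)
  list(mean = apply(arr, c(1, 2), mean),
       sd = apply(arr, c(1, 2), stats::sd))
}

# small cohort helper for simulator-based tests
make_profiles <- function(n, ..., prefix = "m") {
  lapply(sprintf("%s%02d", prefix, seq_len(n)), mouse_profile, ...)
}

# a tiny hand-built event table
tiny_table <- function() {
  rec <- data.frame(
    animal_id = c("a", "b", "a"),
    corner = c(1L, 2L, 1L),
    t_start = c(0, 100, 250),
    t_end = c(30, 160, 280),
    nosepokes_left = c(3L, 0L, 1L),
    nosepokes_right = c(0L, 2L, 0L),
    licks_left = c(10L, 0L, 0L),
    licks_right = c(0L, 5L, 0L),
    stringsAsFactors = FALSE)
  event_table(rec, roster = data.frame(animal_id = c("a", "b"),
                                       sex = c("M", "F"),
                                       weight_g = c(26, 24)))
}
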