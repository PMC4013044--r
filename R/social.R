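#' Corner entry sequences
#'
#' Converts an event table into one entry sequence per corner: the ordered
#' (animal, entry time) pairs, entry time being the visit's `t_start`.
#' Sub-second duplicate entries by the same mouse at the same corner (chip
#' re-contact artifacts) are merged into the first entry; ties in entry
#' time are broken by stable input order.
#'
#' @param table an `event_table`.
#' @param merge_below gap in seconds under which consecutive same-animal
#'   entries at a corner are merged (default 1 s).
#' @return named list of 4 data.frames (`corner1`..`corner4`), each with
#'   columns `animal_id` and `t`.
#' @export
build_sequences <- function(table, merge_below = 1) {
  stopifnot(is_event_table(table))
  out <- vector("list", 4L)
  for (k in 1:4) {
    tt <- table[table$corner == k, c("animal_id", "t_start"), drop = FALSE]
    tt <- tt[order(tt$t_start), , drop = FALSE]
    names(tt) <- c("animal_id", "t")
    if (nrow(tt) > 1 && merge_below > 0) {
      same <- tt$animal_id[-1] == tt$animal_id[-nrow(tt)]
      close <- diff(tt$t) < merge_below
      tt <- tt[c(TRUE, !(same & close)), , drop = FALSE]
    }
    rownames(tt) <- NULL
    out[[k]] <- tt
  }
  names(out) <- paste0("corner", 1:4)
  out
}

# collapse consecutive same-animal runs to their first entry
collapse_repeats <- function(animal, t) {
  if (length(animal) < 2) return(list(animal = animal, t = t))
  keep <- c(TRUE, animal[-1] != animal[-length(animal)])
  list(animal = animal[keep], t = t[keep])
}

#' Count qualifying adjacent entry pairs
#'
#' Counts ordered adjacent pairs (first entrant, second entrant) in a
#' corner's entry sequence whose gap `t[i+1] - t[i]` lies within
#' `[min_gap, max_gap]` seconds (1 s to 1 minute by default; shorter gaps
#' are likely detector artifacts, longer ones are unlikely to reflect a
#' reaction to the first mouse). With `drop_repeats`, consecutive entries
#' by the same mouse are first collapsed to their initial entry, removing
#' all same-mouse pairs.
#'
#' The matrix follows the heat-map convention: the first mouse of the pair
#' indexes the column, the second mouse the row.
#'
#' @param seq a corner sequence (data.frame with `animal_id`, `t`).
#' @param animals character vector of all animal ids (matrix dimensions).
#' @param min_gap,max_gap inclusive gap bounds in seconds.
#' @param drop_repeats collapse same-mouse runs before counting.
#' @return integer matrix `animals x animals` (`[second, first]`), with
#'   attributes `n_pairs` (qualifying) and `n_total` (all adjacent pairs
#'   before the gap filter, after any collapsing).
#' @export
count_pairs <- function(seq, animals, min_gap = 1, max_gap = 60,
                        drop_repeats = FALSE) {
  if (min_gap > max_gap) stop("min_gap must not exceed max_gap")
  animal <- seq$animal_id
  t <- seq$t
  if (drop_repeats) {
    cr <- collapse_repeats(animal, t)
    animal <- cr$animal
    t <- cr$t
  }
  n <- length(animal)
  if (n < 2) {
    m <- matrix(0L, length(animals), length(animals),
                dimnames = list(second = animals, first = animals))
    attr(m, "n_pairs") <- 0L
    attr(m, "n_total") <- 0L
    return(m)
  }
  first <- animal[-n]
  second <- animal[-1]
  gap <- t[-1] - t[-n]
  ok <- gap >= min_gap & gap <= max_gap
  if (anyNA(match(animal, animals)))
    stop("sequence contains animals outside `animals`")
  tab <- table(factor(second[ok], levels = animals),
               factor(first[ok], levels = animals))
  m <- matrix(as.integer(tab), length(animals), length(animals),
              dimnames = list(second = animals, first = animals))
  attr(m, "n_pairs") <- sum(ok)
  attr(m, "n_total") <- n - 1L
  m
}

#' Pooled pair counts over all corners
#'
#' @param table an `event_table`.
#' @inheritParams count_pairs
#' @inheritParams build_sequences
#' @return integer matrix as in [count_pairs()], summed over the 4 corners.
#' @export
count_pairs_all <- function(table, min_gap = 1, max_gap = 60,
                            drop_repeats = FALSE, merge_below = 1) {
  seqs <- build_sequences(table, merge_below = merge_below)
  animals <- roster(table)$animal_id
  sum_pair_counts(lapply(seqs, count_pairs, animals = animals,
                         min_gap = min_gap, max_gap = max_gap,
                         drop_repeats = drop_repeats))
}

sum_pair_counts <- function(mats) {
  out <- Reduce(`+`, lapply(mats, function(m) {
    attributes(m)[c("n_pairs", "n_total")] <- NULL
    m
  }))
  attr(out, "n_pairs") <- sum(vapply(mats, attr, 0L, "n_pairs"))
  attr(out, "n_total") <- sum(vapply(mats, attr, 0L, "n_total"))
  out
}

#' Column-normalize a pair-count matrix
#'
#' Divides each column (pairs sharing the same first mouse) by its sum, so
#' each positive column sums to 1; all-zero columns stay zero and are
#' flagged.
#'
#' @param counts matrix from [count_pairs()] or [count_pairs_all()].
#' @return column-stochastic numeric matrix with attribute `zero_columns`
#'   (logical per column).
#' @export
normalize_by_first <- function(counts) {
  cs <- colSums(counts)
  zero <- cs == 0
  out <- sweep(counts, 2, ifelse(zero, 1, cs), "/")
  attributes(out)[c("n_pairs", "n_total")] <- NULL
  attr(out, "zero_columns") <- zero
  out
}

#' Permutation-null follow/avoid scores
#'
#' The observed pair-count matrix (pooled over corners) is compared against
#' a null in which each corner's sequence of animal labels is randomly
#' shuffled over that corner's fixed entry-time slots (so the same gap
#' filter applies to the null) `n_perm` times. Each cell's score is
#'
#'   `z(i -> j) = (observed - mean over permutations) / SD over permutations`
#'
#' with the first mouse `i` on the column and the second mouse `j` on the
#' row. Cells whose permutation SD is zero (no variation under the null)
#' receive the sentinel score 0 and are flagged. Scores are interpreted on
#' a standard-normal scale ([score_pvalue()]), which is approximate because
#' adjacent pair counts are neither exactly normal nor independent.
#'
#' @param x an `event_table`, or a list of corner sequences as returned by
#'   [build_sequences()].
#' @param n_perm number of label permutations (>= 2); 100 is the historical
#'   default, >= 1000 is recommended for stable tail behavior.
#' @param seed optional RNG seed for the permutations.
#' @param animals animal ids (required if `x` is a plain sequence list
#'   without a roster; defaults to the ids present).
#' @param permute_gaps `"respect"` keeps the entry-time slots (and the gap
#'   filter) in the null; `"ignore"` counts every adjacent pair of the
#'   shuffled sequence, dropping the gap structure from the null.
#' @inheritParams count_pairs
#' @inheritParams build_sequences
#' @return object of class `score_matrix`: list with `scores`, `observed`,
#'   `perm_mean`, `perm_sd`, `zero_sd` (logical matrix), `n_perm`, `seed`
#'   and the filter parameters.
#' @export
permutation_scores <- function(x, n_perm = 100, seed = NULL,
                               min_gap = 1, max_gap = 60,
                               drop_repeats = FALSE,
                               permute_gaps = c("respect", "ignore"),
                               animals = NULL, merge_below = 1) {
  permute_gaps <- match.arg(permute_gaps)
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (is_event_table(x)) {
    if (is.null(animals)) animals <- roster(x)$animal_id
    seqs <- build_sequences(x, merge_below = merge_below)
  } else {
    seqs <- x
    if (is.null(animals))
      animals <- sort(unique(unlist(lapply(seqs, `[[`, "animal_id"))))
  }
  if (!is.null(seed)) set.seed(seed)

  count1 <- function(sq, ignore_gaps = FALSE) {
    if (ignore_gaps)
      count_pairs(sq, animals, min_gap = -Inf, max_gap = Inf,
                  drop_repeats = drop_repeats)
    else
      count_pairs(sq, animals, min_gap = min_gap, max_gap = max_gap,
                  drop_repeats = drop_repeats)
  }
  obs <- sum_pair_counts(lapply(seqs, count1))
  if (attr(obs, "n_pairs") == 0L)
    warning("no qualifying pairs in the observed data", call. = FALSE)

  N <- length(animals)
  s1 <- matrix(0, N, N)
  s2 <- matrix(0, N, N)
  ignore <- permute_gaps == "ignore"
  for (b in seq_len(n_perm)) {
    perm <- matrix(0L, N, N)
    for (sq in seqs) {
      n <- nrow(sq)
      if (n < 2) next
      shuffled <- data.frame(animal_id = sq$animal_id[sample.int(n)],
                             t = sq$t, stringsAsFactors = FALSE)
      perm <- perm + count1(shuffled, ignore_gaps = ignore)
    }
    s1 <- s1 + perm
    s2 <- s2 + perm^2
  }
  mu <- s1 / n_perm
  sdv <- sqrt(pmax((s2 - n_perm * mu^2) / (n_perm - 1), 0))
  zero_sd <- sdv == 0
  z <- matrix(0, N, N, dimnames = dimnames(obs))
  z[!zero_sd] <- (obs[!zero_sd] - mu[!zero_sd]) / sdv[!zero_sd]
  dimnames(mu) <- dimnames(sdv) <- dimnames(zero_sd) <- dimnames(obs)
  structure(list(scores = z, observed = obs, perm_mean = mu, perm_sd = sdv,
                 zero_sd = zero_sd, n_perm = n_perm, seed = seed,
                 min_gap = min_gap, max_gap = max_gap,
                 drop_repeats = drop_repeats, permute_gaps = permute_gaps),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d animals, %d permutations, %d qualifying pairs\n",
              nrow(x$scores), x$n_perm, attr(x$observed, "n_pairs")))
  stats::printCoefmat(x$scores, digits = 3)
  invisible(x)
}

#' Two-sided normal-tail probability of a score
#'
#' `2 * P(Z > |z|)` for standard-normal `Z`: 0.0455 at `|z| = 2`, about
#' 0.00047 at `|z| = 3.5`. Approximate, since the permutation scores are
#' only approximately normal.
#'
#' @param z finite score(s).
#' @return two-sided tail probabilities.
#' @export
score_pvalue <- function(z) {
  if (any(!is.finite(z))) stop("scores must be finite")
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Classify follow/avoid edges from a score matrix
#'
#' Off-diagonal cells with score above `weak` become `follow` edges, below
#' `-weak` become `avoid` edges; magnitudes beyond `strong` are labeled
#' strong. Diagonal cells (a mouse re-entering a corner after itself) are
#' reported separately in the `"self"` attribute, since repeat entries
#' reflect individual exploration, not a social interaction.
#'
#' @param scores a `score_matrix` or a plain numeric matrix
#'   (`[second, first]`).
#' @param weak,strong positive score thresholds.
#' @return data.frame with `source` (first mouse), `target` (second mouse),
#'   `score`, `label` (`follow`/`avoid`) and `strength` (`weak`/`strong`);
#'   attribute `self` holds the diagonal report.
#' @export
classify_edges <- function(scores, weak = 2, strong = 3.5) {
  if (weak <= 0 || strong <= 0) stop("thresholds must be > 0")
  if (strong < weak) stop("strong threshold must be >= weak")
  z <- if (inherits(scores, "score_matrix")) scores$scores else scores
  animals <- colnames(z)
  if (is.null(animals)) animals <- as.character(seq_len(ncol(z)))
  hits <- which(abs(z) > weak, arr.ind = TRUE)
  offd <- hits[hits[, 1] != hits[, 2], , drop = FALSE]
  edges <- data.frame(
    source = animals[offd[, 2]],
    target = animals[offd[, 1]],
    score = z[offd],
    label = ifelse(z[offd] > 0, "follow", "avoid"),
    strength = ifelse(abs(z[offd]) > strong, "strong", "weak"),
    stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$score)), , drop = FALSE]
  rownames(edges) <- NULL
  dg <- diag(z)
  self <- data.frame(animal_id = animals,
                     score = dg,
                     label = ifelse(dg > weak, "repeat",
                                    ifelse(dg < -weak, "avoid_repeat",
                                           "none")),
                     stringsAsFactors = FALSE)
  attr(edges, "self") <- self
  edges
}

#' Export a follow/avoid network as TSV edge and node lists
#'
#' @param edges edge data.frame from [classify_edges()].
#' @param nodes node annotation data.frame with `animal_id` and optional
#'   `preference` and `weight_g`; every edge endpoint must appear in it.
#' @param edge_path,node_path output file paths.
#' @return invisibly, a list of the two paths.
#' @export
export_network <- function(edges, nodes, edge_path, node_path) {
  stopifnot(is.data.frame(edges), is.data.frame(nodes),
            "animal_id" %in% names(nodes))
  known <- nodes$animal_id
  missing <- setdiff(unique(c(edges$source, edges$target)), known)
  if (length(missing))
    stop("edge endpoints missing from node table: ",
         paste(missing, collapse = ", "))
  if (!"preference" %in% names(nodes)) nodes$preference <- NA_real_
  if (!"weight_g" %in% names(nodes)) nodes$weight_g <- NA_real_
  cols <- c("source", "target", "score", "label", "strength")
  utils::write.table(edges[intersect(cols, names(edges))], edge_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(nodes[c("animal_id", "preference", "weight_g")],
                     node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(list(edges = edge_path, nodes = node_path))
}

#' @rdname export_network
#' @return `read_network` returns a list with `edges` and `nodes`
#'   data.frames.
#' @export
read_network <- function(edge_path, node_path) {
  list(edges = utils::read.delim(edge_path, stringsAsFactors = FALSE,
                                 colClasses = c(source = "character",
                                                target = "character")),
       nodes = utils::read.delim(node_path, stringsAsFactors = FALSE,
                                 colClasses = c(animal_id = "character")))
}
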