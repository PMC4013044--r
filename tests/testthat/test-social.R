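test_that("build_sequences orders entries per corner and merges blips", {
  e <- event_table(roster = data.frame(animal_id = "a"))
  seqs <- build_sequences(e)
  expect_length(seqs, 4L)
  expect_true(all(vapply(seqs, nrow, 0L) == 0L))

  tab <- tiny_table()
  seqs2 <- build_sequences(tab)
  expect_equal(seqs2$corner1$animal_id, c("a", "a"))
  expect_equal(seqs2$corner2$animal_id, "b")

  # interleaved fixture equals a brute-force sort
  set.seed(3)
  n <- 60
  rec <- data.frame(animal_id = sample(c("a", "b", "c"), n, TRUE),
                    corner = sample(1:4, n, TRUE),
                    t_start = runif(n, 0, 5000))
  rec$t_end <- rec$t_start + 5
  rec[c("nosepokes_left", "nosepokes_right", "licks_left",
        "licks_right")] <- 0L
  tab3 <- event_table(rec)
  seqs3 <- build_sequences(tab3, merge_below = 0)
  for (k in 1:4) {
    sub <- rec[rec$corner == k, ]
    expect_equal(seqs3[[k]]$t, sort(sub$t_start))
    expect_equal(seqs3[[k]]$animal_id,
                 sub$animal_id[order(sub$t_start)])
  }

  # sub-second same-mouse re-entries collapse to the first contact
  blip <- data.frame(animal_id = c("a", "a", "b"), corner = 1L,
                     t_start = c(0, 0.4, 5), t_end = c(0.2, 0.6, 6),
                     nosepokes_left = 0L, nosepokes_right = 0L,
                     licks_left = 0L, licks_right = 0L)
  sq <- build_sequences(event_table(blip))$corner1
  expect_equal(nrow(sq), 2L)
  expect_equal(sq$t, c(0, 5))
})

test_that("count_pairs applies the 1-60 s gap filter", {
  animals <- c("a", "b")
  sq <- data.frame(animal_id = c("a", "b", "a", "b"),
                   t = c(0, 10, 25, 95))
  m <- count_pairs(sq, animals)
  # ab at gap 10, ba at gap 15; the final ab gap of 70 s is excluded
  expect_equal(m["b", "a"], 1L)
  expect_equal(m["a", "b"], 1L)
  expect_equal(sum(m), 2L)
  expect_equal(attr(m, "n_pairs"), 2L)
  expect_equal(attr(m, "n_total"), 3L)

  # singleton sequence -> all-zero matrix
  m1 <- count_pairs(data.frame(animal_id = "a", t = 0), animals)
  expect_equal(sum(m1), 0L)

  # repeats: aa dropped, ab kept with the first entry's timestamp
  sq2 <- data.frame(animal_id = c("a", "a", "b"), t = c(0, 5, 10))
  m2 <- count_pairs(sq2, animals, drop_repeats = TRUE)
  expect_equal(m2["a", "a"], 0L)
  expect_equal(m2["b", "a"], 1L)  # gap b - first a = 10 s, qualifies
  m2k <- count_pairs(sq2, animals, drop_repeats = FALSE)
  expect_equal(m2k["a", "a"], 1L)

  expect_error(count_pairs(sq, animals, min_gap = 10, max_gap = 2),
               "min_gap")
})

test_that("count_pairs equals the brute-force oracle on random sequences", {
  set.seed(11)
  animals <- letters[1:6]
  for (r in 1:200) {
    n <- sample(2:50, 1)
    ids <- sample(animals, n, replace = TRUE)
    # gaps straddling both filter edges
    t <- cumsum(runif(n, 0, 90))
    for (dr in c(FALSE, TRUE)) {
      got <- count_pairs(data.frame(animal_id = ids, t = t), animals,
                         drop_repeats = dr)
      want <- brute_pairs(ids, t, animals, drop_repeats = dr)
      expect_equal(as.vector(got), as.vector(want))
    }
  }
})

test_that("normalize_by_first makes positive columns stochastic", {
  m <- matrix(c(2, 1, 1, 0, 0, 0, 4, 0, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  nm <- normalize_by_first(m)
  expect_equal(nm[, 1], c(a = 0.5, b = 0.25, c = 0.25))
  expect_equal(attr(nm, "zero_columns"),
               c(a = FALSE, b = TRUE, c = FALSE))
  expect_equal(unname(colSums(nm)), c(1, 0, 1))

  z <- normalize_by_first(matrix(0, 2, 2))
  expect_true(all(z == 0) && all(attr(z, "zero_columns")))

  set.seed(2)
  r <- matrix(rpois(49, 3), 7, 7)
  nr <- normalize_by_first(r)
  pos <- colSums(r) > 0
  expect_true(all(abs(colSums(nr)[pos] - 1) < 1e-12))
})

test_that("degenerate sequences give sentinel zero scores", {
  # a single mouse only: every permutation is identical, SD is 0
  sq <- list(data.frame(animal_id = rep("a", 5), t = (0:4) * 10))
  sc <- permutation_scores(sq, n_perm = 50, seed = 1, animals = c("a", "b"))
  expect_true(all(sc$scores == 0))
  expect_true(sc$zero_sd["a", "a"])
  expect_equal(sc$observed["a", "a"], 4L)
  expect_error(permutation_scores(sq, n_perm = 1), "n_perm")
})

test_that("Monte-Carlo null matches exhaustive enumeration (short strings)", {
  animals <- c("a", "b")
  # 4 slots, all gaps qualifying: exact null over all 24 arrangements
  ids <- c("a", "a", "b", "b")
  t <- c(0, 10, 20, 30)
  ex <- exact_null(ids, t, animals)
  sc <- permutation_scores(list(data.frame(animal_id = ids, t = t)),
                           n_perm = 10000, seed = 5, animals = animals)
  se_mean <- ex$sd / sqrt(10000)
  expect_true(all(abs(sc$perm_mean - ex$mean) <=
                    3 * se_mean + 1e-12))
  # SD standard error ~ sd / sqrt(2 n)
  expect_true(all(abs(sc$perm_sd - ex$sd) <=
                    3 * ex$sd / sqrt(2 * 10000) + 0.02))

  # a gap-filtered case: middle gap fails the 60 s cut
  t2 <- c(0, 30, 120, 150)
  ex2 <- exact_null(ids, t2, animals)
  sc2 <- permutation_scores(list(data.frame(animal_id = ids, t = t2)),
                            n_perm = 10000, seed = 6, animals = animals)
  expect_true(all(abs(sc2$perm_mean - ex2$mean) <=
                    3 * ex2$sd / sqrt(10000) + 1e-12))
})

test_that("total pair count is permutation-invariant when all gaps qualify", {
  set.seed(8)
  ids <- sample(letters[1:4], 12, replace = TRUE)
  t <- cumsum(runif(12, 2, 50))  # every gap in [1, 60]
  obs <- count_pairs(data.frame(animal_id = ids, t = t), letters[1:4])
  for (r in 1:20) {
    p <- sample(length(ids))
    m <- count_pairs(data.frame(animal_id = ids[p], t = t), letters[1:4])
    expect_equal(sum(m), sum(obs))
    # the letter multiset is preserved by construction of the shuffle
    expect_equal(sort(ids[p]), sort(ids))
  }
})

test_that("score_pvalue reproduces the normal-tail calibration", {
  expect_equal(round(score_pvalue(2), 4), 0.0455)
  expect_equal(score_pvalue(0), 1)
  expect_lt(score_pvalue(3.5), 5e-4)
  expect_equal(round(score_pvalue(3.5), 6), 0.000465)
  expect_equal(score_pvalue(-2), score_pvalue(2))
  expect_error(score_pvalue(Inf), "finite")
})

test_that("classify_edges thresholds scores and sidelines the diagonal", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(nrow(classify_edges(z)), 0L)

  z["b", "a"] <- 2.1    # a followed by b
  z["c", "a"] <- -4.2   # c avoids entering after a
  z["a", "a"] <- 6      # repeat entries
  ed <- classify_edges(z)
  expect_equal(nrow(ed), 2L)
  strong <- ed[ed$strength == "strong", ]
  expect_equal(strong$source, "a")
  expect_equal(strong$target, "c")
  expect_equal(strong$label, "avoid")
  weak <- ed[ed$strength == "weak", ]
  expect_equal(weak$label, "follow")
  self <- attr(ed, "self")
  expect_equal(self$label[self$animal_id == "a"], "repeat")

  # brute-force threshold scan agreement on a random matrix
  set.seed(14)
  zr <- matrix(rnorm(36, sd = 2), 6, 6,
               dimnames = list(letters[1:6], letters[1:6]))
  ed2 <- classify_edges(zr)
  want <- sum(abs(zr) > 2) - sum(abs(diag(zr)) > 2)
  expect_equal(nrow(ed2), want)
  expect_error(classify_edges(zr, weak = -1), "> 0")
})

test_that("network export round-trips through TSV", {
  edges <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      score = c(3.7, -2.2),
                      label = c("follow", "avoid"),
                      strength = c("strong", "weak"),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(animal_id = c("a", "b", "c"),
                      preference = c(0.51, 0.4, 0.62),
                      weight_g = c(26, 24, 28), stringsAsFactors = FALSE)
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  export_network(edges, nodes, ep, np)
  back <- read_network(ep, np)
  expect_equal(back$edges, edges)
  expect_equal(back$nodes, nodes)

  # empty edge list -> header-only file
  export_network(edges[0, ], nodes, ep, np)
  expect_length(readLines(ep), 1L)

  expect_error(export_network(
    data.frame(source = "x", target = "a", score = 3, label = "follow",
               strength = "weak"), nodes, ep, np), "missing")
})

test_that("injected follower edges are recovered above the strong cut", {
  sched <- build_intermittent(1)
  sim <- simulate_cohort(cohort_config(make_profiles(6), sched[1],
                                       seed = 77))
  inj <- inject_follower(sim, "m03", "m05", p_follow = 0.8, seed = 78)
  sc <- permutation_scores(inj, n_perm = 100, seed = 79)
  expect_gt(sc$scores["m05", "m03"], 3.5)
  # and it lands in the edge list as a strong follow
  ed <- classify_edges(sc)
  hit <- ed[ed$source == "m03" & ed$target == "m05", ]
  expect_equal(hit$label, "follow")
  expect_equal(hit$strength, "strong")
})
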