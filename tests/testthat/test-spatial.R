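test_that("euclidean distance matches hand computations and metric axioms", {
  expect_equal(euclidean_dist(0, 0, 3, 4), 5)
  expect_equal(euclidean_dist(2, 7, 2, 7), 0)
  expect_equal(euclidean_dist(1, 1, 4, 5), 5)  # sqrt(9 + 16)
  set.seed(21)
  for (i in 1:50) {
    p <- matrix(runif(6, -100, 100), 3, 2)
    d12 <- euclidean_dist(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d21 <- euclidean_dist(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d13 <- euclidean_dist(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d23 <- euclidean_dist(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    expect_gte(d12, 0)
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-12)  # triangle inequality
  }
})

test_that("path length sums consecutive segments and bounds the chord", {
  expect_equal(path_length(c(0, 1, 3), c(0, 0, 0)), 3)
  expect_equal(path_length(5, 9), 0)
  expect_equal(path_length(c(0, 3, 3), c(0, 4, 4)), 5)  # zero-length leg
  set.seed(22)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
    pl <- path_length(x, y)
    expect_equal(pl, oracle_path_length(x, y), tolerance = 1e-12)
    expect_gte(pl + 1e-12, euclidean_dist(x[1], y[1], x[n], y[n]))
  }
})

make_anchor_records <- function() {
  # two trials; trial 1 context at (100,100) then target landing (103,104)
  tibble::tibble(
    participant = "P01", item = "item01",
    trial = c(1L, 1L, 1L, 2L, 2L),
    event_type = c("context", "target", "target", "response", "target"),
    t_onset_ms = c(0, 600, 800, 1200, 2000),
    duration_ms = 100,
    x_px = c(100, 103, 150, 30, 150),
    y_px = c(100, 104, 150, 40, 110),
    valid = TRUE
  )
}

test_that("anchor transitions use the correct preceding event per condition", {
  rec <- make_anchor_records()
  lay <- unit_layout()

  pre <- anchor_transitions(rec, lay, "pre_context")
  expect_equal(nrow(pre), 1)  # trial 2 has no context event
  expect_equal(pre$distance, 5)
  expect_equal(pre$landing_zone, "CFZ")
  expect_equal(attr(pre, "n_skipped"), 1)

  # post_context: anchors come from the previous trial's response screen;
  # trial 1 has no prior trial and trial 1 itself has no response event,
  # so no presentation is anchorable here
  post <- suppressMessages(anchor_transitions(rec, lay, "post_context"))
  expect_equal(nrow(post), 0)
  expect_equal(attr(post, "n_skipped"), 2)
})

test_that("post_context anchoring skips the first trial of a block", {
  rec <- tibble::tibble(
    participant = "P01", item = "item01",
    trial = c(1L, 1L, 2L, 2L),
    event_type = c("target", "response", "target", "response"),
    t_onset_ms = c(0, 500, 1000, 1500),
    duration_ms = 100,
    x_px = c(150, 100, 103, 90),
    y_px = c(150, 100, 104, 95),
    valid = TRUE
  )
  at <- suppressMessages(anchor_transitions(rec, unit_layout(), "post_context"))
  expect_equal(nrow(at), 1)
  expect_equal(at$trial, 2L)
  expect_equal(at$distance, 5)   # (100,100) -> (103,104)
  expect_equal(attr(at, "n_skipped"), 1)
})

test_that("stability aggregates duration over within-zone path", {
  # one CFZ visit: durations (200, 300, 500), consecutive distances (50, 50)
  seqs <- tibble::tibble(
    participant = "P01", item = "item01", trial = 1L, event_type = "target",
    segment = 1L, ord = 1:3, label = "CFZ",
    x_px = c(100, 150, 150), y_px = c(150, 150, 200),
    duration_ms = c(200, 300, 500)
  )
  st <- stability_table(seqs)
  expect_equal(st$total_duration, 1000)
  expect_equal(st$path_length, 100)
  expect_equal(st$stability, 10)

  # doubling durations doubles stability; scaling space divides it
  seqs2 <- seqs; seqs2$duration_ms <- seqs2$duration_ms * 2
  expect_equal(stability_table(seqs2)$stability, 20)
  seqs3 <- seqs; seqs3$x_px <- seqs3$x_px * 3; seqs3$y_px <- seqs3$y_px * 3
  expect_equal(stability_table(seqs3)$stability, 10 / 3)
})

test_that("cross-zone pairs count for neither zone; singletons are excluded", {
  seqs <- tibble::tibble(
    participant = "P01", item = "item01", trial = 1L, event_type = "target",
    segment = 1L, ord = 1:4,
    label = c("CFZ", "CFZ", "UFZ", "CFZ"),
    x_px = c(100, 160, 160, 160), y_px = c(150, 150, 50, 150),
    duration_ms = c(100, 100, 400, 100)
  )
  st <- suppressMessages(stability_table(seqs))
  # only the CFZ-CFZ pair contributes path; UFZ has duration but no path
  expect_equal(st$zone, "CFZ")
  expect_equal(st$path_length, 60)
  expect_equal(st$total_duration, 300)
  expect_equal(attr(st, "n_zero_path"), 1)
})

test_that("trial-level stability keeps condition for the event-order model", {
  ch <- small_cohort()
  st <- suppressMessages(stability_table(ch$seqs, "participant_aoi_event"))
  expect_true(all(c("participant", "condition", "trial", "zone",
                    "stability") %in% names(st)))
  expect_true(all(st$stability > 0))
  agg <- suppressMessages(stability_table(ch$seqs, "participant_aoi"))
  expect_false(anyDuplicated(agg[c("participant", "zone")]) > 0)
})

test_that("Kruskal-Wallis H matches the brute-force rank formula", {
  g <- list(UFZ = c(1, 2, 3), CFZ = c(4, 5, 6), LFZ = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, oracle_kruskal_h(g), tolerance = 1e-10)
  expect_equal(kw$effect_size, kw$statistic / 8)

  set.seed(33)
  for (i in 1:10) {
    g2 <- list(a = runif(sample(3:8, 1)), b = runif(sample(3:8, 1)),
               c = runif(sample(3:8, 1)))
    expect_equal(kruskal_wallis(g2)$statistic, oracle_kruskal_h(g2),
                 tolerance = 1e-10)
  }

  # identical groups: no rank separation
  same <- list(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4))
  expect_error(kruskal_wallis(same), NA)
  expect_equal(kruskal_wallis(list(a = 1:4, b = 1:4, c = 1:4))$statistic, 0,
               tolerance = 1e-10)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 non-empty")
})

test_that("epsilon-squared convention is consistent with reported arithmetic", {
  # chi-squared 11.06 at n = 149 gives epsilon-squared 0.075 (3 dp)
  expect_equal(round(11.06 / (149 - 1), 3), 0.075)
})

test_that("pairwise rank-sum tests apply the Holm step-down correctly", {
  expect_equal(oracle_holm(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "holm"),
               oracle_holm(c(0.01, 0.02, 0.04)))

  set.seed(44)
  g <- list(UFZ = rnorm(10, 0), CFZ = rnorm(12, 2), LFZ = rnorm(9, 0.5))
  pw <- pairwise_wilcoxon_holm(g)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, oracle_holm(pw$p_raw))
  expect_true(all(pw$p_adjusted >= pw$p_raw))
  o <- order(pw$p_raw)
  expect_true(all(diff(pw$p_adjusted[o]) >= -1e-12))  # monotone in raw order
  expect_true(all(abs(pw$effect_r) <= 1))

  # identical groups: adjusted p-values at their maximum
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  pw2 <- pairwise_wilcoxon_holm(same)
  expect_true(all(pw2$p_adjusted == 1))
  expect_true(all(pw2$z == 0))
})

test_that("anchor distances by landing zone feed the rank tests end-to-end", {
  ch <- small_cohort()
  at <- suppressMessages(anchor_transitions(
    suppressMessages(clean_fixations(ch$fx)), ch$cfg$face_layout,
    "pre_context"))
  expect_true(all(at$distance >= 0))
  groups <- split(at$distance, at$landing_zone)
  groups <- groups[names(groups) != "OUTSIDE"]
  kw <- kruskal_wallis(groups)
  expect_true(kw$p_raw > 0 && kw$p_raw <= 1)
  expect_true(kw$effect_size >= 0 && kw$effect_size <= 1)
})
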