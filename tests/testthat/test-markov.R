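test_that("transition counts match hand counts on tiny sequences", {
  s1 <- labels_to_seqs(list(c("UFZ", "CFZ", "CFZ", "LFZ")))
  m <- estimate_transitions(s1, 1)
  expect_equal(m$counts["UFZ", "CFZ"], 1)
  expect_equal(m$counts["CFZ", "CFZ"], 1)
  expect_equal(m$counts["CFZ", "LFZ"], 1)
  expect_equal(sum(m$counts), 3)
  expect_equal(m$prob["UFZ", "CFZ"], 1)
  expect_equal(m$prob["CFZ", "CFZ"], 0.5)
  expect_equal(m$prob["CFZ", "LFZ"], 0.5)

  s2 <- labels_to_seqs(list(rep("CFZ", 4)))
  m2 <- estimate_transitions(s2, 1)
  expect_equal(m2$prob["CFZ", "CFZ"], 1)
  expect_setequal(m2$unobserved, c("UFZ", "LFZ"))
  expect_true(all(is.na(m2$prob["UFZ", ])))

  s3 <- labels_to_seqs(list(c("UFZ", "CFZ", "LFZ", "CFZ")))
  m3 <- estimate_transitions(s3, 2)
  expect_equal(m3$prob["UFZ,CFZ", "LFZ"], 1)
  expect_equal(m3$prob["CFZ,LFZ", "CFZ"], 1)
  expect_equal(sum(m3$counts), 2)
})

test_that("transitions never cross sequence boundaries and counts conserve", {
  set.seed(99)
  states <- c("UFZ", "CFZ", "LFZ")
  for (rep_i in 1:20) {
    lens <- sample(1:8, 5, replace = TRUE)
    labs <- lapply(lens, function(n) sample(states, n, replace = TRUE))
    for (ord in 1:2) {
      usable <- sum(pmax(lens - ord, 0))
      if (usable == 0) next
      m <- estimate_transitions(labels_to_seqs(labs), ord)
      expect_equal(m$n_transitions, usable)
      expect_equal(unname(m$counts), unname(oracle_transition_counts(labs, ord)))
      rs <- rowSums(m$counts)
      expect_equal(unname(rowSums(m$prob[rs > 0, , drop = FALSE])),
                   rep(1, sum(rs > 0)), tolerance = 1e-12)
    }
  }
  expect_error(estimate_transitions(labels_to_seqs(list("CFZ")), 1),
               "no sequence")
})

test_that("row entropy follows the closed form with 0 log 0 = 0", {
  expect_equal(row_entropy(rep(1 / 3, 3))$H_norm, 1)
  expect_equal(row_entropy(c(1, 0, 0))$H_bits, 0)
  expect_equal(row_entropy(c(1, 0, 0))$H_norm, 0)
  e <- row_entropy(c(0.5, 0.5, 0))
  expect_equal(e$H_bits, 1)
  expect_equal(e$H_norm, 1 / log2(3))
  expect_error(row_entropy(c(-0.1, 0.6, 0.5)), "non-negative")
  expect_error(row_entropy(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("entropy bounds: H_norm is 1 iff uniform, 0 iff degenerate", {
  set.seed(5)
  for (i in 1:50) {
    p <- stats::rgamma(3, 1)
    p <- p / sum(p)
    h <- row_entropy(p)$H_norm
    expect_gte(h, 0)
    expect_lte(h, 1)
    if (max(p) < 1) expect_gt(h, 0)
  }
})

test_that("global entropy is the occupancy-weighted mean of row entropies", {
  # uniform rows: maximal uncertainty everywhere
  s <- labels_to_seqs(list(c("UFZ", "CFZ", "LFZ", "UFZ", "CFZ", "LFZ")))
  m <- s |> estimate_transitions(1)
  m$prob[] <- 1 / 3
  expect_equal(global_entropy(m)$global_H_norm, 1)

  # a single observed context carries weight 1
  m2 <- estimate_transitions(labels_to_seqs(list(rep("CFZ", 5))), 1)
  es2 <- global_entropy(m2)
  expect_equal(es2$global_H_bits, 0)
  expect_equal(es2$per_context$weight[match("CFZ", es2$per_context$context)], 1)

  # hand-checkable weighting: U->C, C->C, C->U gives weights (1/3, 2/3)
  m3 <- estimate_transitions(labels_to_seqs(list(c("UFZ", "CFZ", "CFZ", "UFZ"))), 1)
  es3 <- global_entropy(m3)
  expect_equal(es3$global_H_bits, (1 / 3) * 0 + (2 / 3) * 1)
})

test_that("analytic entropy of the reference chain matches a long simulation", {
  fm <- build_fixture_matrix(1)
  analytic <- global_entropy(fm)
  set.seed(31)
  lab <- sample_markov_sequence(fm, 50000)
  fitted <- global_entropy(estimate_transitions(tibble::tibble(label = lab), 1))
  expect_equal(fitted$global_H_norm, analytic$global_H_norm, tolerance = 0.02)
})

test_that("participant entropies exclude unusable participants with a log", {
  flat <- labels_to_seqs(list(rep("CFZ", 30)))
  pe <- participant_entropies(flat, 1)
  expect_equal(pe$H_norm, 0)

  mixed <- dplyr::bind_rows(
    tibble::tibble(participant = "P01", label = c("UFZ", "CFZ", "CFZ", "LFZ")),
    tibble::tibble(participant = "P02", label = "CFZ")  # single fixation
  )
  expect_message(pe2 <- participant_entropies(mixed, 1), "excluded")
  expect_equal(pe2$participant, "P01")
  expect_identical(attr(pe2, "excluded"), "P02")
  expect_error(participant_entropies(mixed[5, ], 1), "no participant")
})

test_that("cohort mean entropy recovers the generating chain's entropy", {
  cfg <- synth_config(n_participants = 8, n_items = 6, trials_per_item = 40,
                      seed = 77)
  fx <- generate_fixations(cfg)
  seqs <- build_sequences(suppressMessages(clean_fixations(fx)),
                          cfg$face_layout)
  pe <- participant_entropies(seqs, 1)
  expect_true(all(pe$n_transitions > 1500))
  analytic <- global_entropy(build_fixture_matrix(1))$global_H_norm
  expect_equal(mean(pe$H_norm), analytic, tolerance = 0.05)
})

test_that("order comparison handles degenerate and hand-checked cases", {
  expect_error(compare_orders(1:4 / 10, 1:4 / 10), "at least 5")

  h1 <- rep(0.4, 8)
  cmp0 <- compare_orders(h1, h1, n_boot = 200, seed = 1)
  expect_equal(cmp0$median_diff, 0)
  expect_equal(c(cmp0$ci_low, cmp0$ci_high), c(0, 0))

  cmp_c <- compare_orders(h1, h1 - 0.01, n_boot = 200, seed = 1)
  expect_equal(cmp_c$median_diff, 0.01)
  expect_equal(c(cmp_c$ci_low, cmp_c$ci_high), c(0.01, 0.01))

  d <- c(1, 2, 3, -1, 4, 5, 2)
  cmp <- compare_orders(d, rep(0, 7), n_boot = 100, seed = 2)
  expect_equal(cmp$wilcoxon_V, oracle_signed_rank_v(d))
  expect_true(cmp$ci_low <= cmp$median_diff && cmp$median_diff <= cmp$ci_high)
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
})

test_that("order comparison is invariant to participant ordering", {
  set.seed(8)
  h1 <- runif(12, 0.2, 0.5)
  h2 <- h1 - runif(12, 0, 0.05)
  a <- compare_orders(h1, h2, n_boot = 500, seed = 10)
  perm <- sample(12)
  b <- compare_orders(h1[perm], h2[perm], n_boot = 500, seed = 10)
  expect_equal(a$median_diff, b$median_diff)
  expect_equal(a$wilcoxon_V, b$wilcoxon_V)
  expect_equal(a$p_value, b$p_value)
  # fixed seed reproduces the bootstrap interval exactly
  a2 <- compare_orders(h1, h2, n_boot = 500, seed = 10)
  expect_identical(c(a$ci_low, a$ci_high), c(a2$ci_low, a2$ci_high))
})

test_that("conditioning on a longer history never increases plug-in entropy", {
  set.seed(12)
  states <- c("UFZ", "CFZ", "LFZ")
  for (i in 1:25) {
    labs <- lapply(1:6, function(j) sample(states, sample(5:30, 1), TRUE))
    seqs <- labels_to_seqs(labs)
    h2 <- global_entropy(estimate_transitions(seqs, 2))$global_H_bits
    h1 <- global_entropy(estimate_transitions(seqs, 1, skip = 1))$global_H_bits
    expect_lte(h2, h1 + 1e-12)
  }
})
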