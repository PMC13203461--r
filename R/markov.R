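#' Estimate a Markov transition model over facial zones
#'
#' Counts order-`k` transitions within each labelled fixation sequence
#' (never across participant, item, trial or event boundaries) and converts
#' them to conditional probabilities by row normalization — plain maximum
#' likelihood, no pseudocounts. Contexts never observed carry `NA`
#' probabilities and are flagged as unobserved.
#'
#' @param sequences A labelled sequence tibble from [build_sequences()], or
#'   any tibble with a `label` column over the three zones plus grouping
#'   keys among `participant`, `item`, `trial`, `condition`, `event_type`,
#'   `segment` (rows must be in temporal order within group).
#' @param order Markov order, 1 or 2.
#' @param skip Number of initial transitions to discard in each sequence.
#'   `skip = 1` with `order = 1` fits the first-order model on exactly the
#'   pairs contained in the triples used by the second-order model, the
#'   alignment under which conditioning on a longer history can never
#'   increase the plug-in conditional entropy.
#' @return An object of class `transition_model`: list with `order`,
#'   `states`, `counts` (contexts x destinations), `prob` (row-normalized,
#'   `NA` rows for unobserved contexts), `n_transitions`.
#' @examples
#' seqs <- tibble::tibble(participant = "P01", label = c("UFZ","CFZ","CFZ","LFZ"))
#' estimate_transitions(seqs, order = 1)$prob
#' @export
estimate_transitions <- function(sequences, order = 1L, skip = 0L) {
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2", call. = FALSE)
  states <- aoi_states()
  ctx <- context_labels(order, states)
  counts <- matrix(0L, length(ctx), 3L, dimnames = list(ctx, states))

  keys <- intersect(c("participant", "item", "trial", "condition",
                      "event_type", "segment"), names(sequences))
  idx <- match(sequences$label, states)
  if (anyNA(idx)) stop("labels must be among ", paste(states, collapse = ", "),
                       call. = FALSE)
  groups <- if (length(keys)) {
    split(idx, interaction(sequences[keys], drop = TRUE, lex.order = TRUE))
  } else list(idx)

  for (g in groups) {
    if (length(g) <= order + skip) next
    emb <- stats::embed(g, order + 1L)  # columns: x_t, x_{t-1}, ..., x_{t-order}
    if (skip > 0L) emb <- emb[-seq_len(min(skip, nrow(emb))), , drop = FALSE]
    if (!nrow(emb)) next
    ctx_idx <- context_index(emb[, (order + 1L):2L, drop = FALSE])
    flat <- (ctx_idx - 1L) * 3L + emb[, 1L]
    tab <- tabulate(flat, nbins = length(ctx) * 3L)
    counts <- counts + matrix(tab, nrow = length(ctx), byrow = TRUE)
  }

  total <- sum(counts)
  if (total == 0) {
    stop("no sequence longer than the model order; cannot estimate transitions",
         call. = FALSE)
  }
  rs <- rowSums(counts)
  prob <- counts / ifelse(rs > 0, rs, NA_real_)
  out <- list(order = order, states = states, counts = counts, prob = prob,
              n_transitions = total, unobserved = rownames(counts)[rs == 0])
  class(out) <- "transition_model"
  out
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Order-%d transition model: %d transitions\n", x$order,
              x$n_transitions))
  print(round(x$prob, 3))
  if (length(x$unobserved)) {
    cat("unobserved context(s):", paste(x$unobserved, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Shannon entropy of a transition row
#'
#' Entropy in bits of a conditional distribution over the three facial
#' zones, with the convention `0 * log2(0) = 0`, and its normalized form
#' (entropy divided by `log2` of the number of destinations), which ranges
#' from 0 (fully predictable) to 1 (uniform).
#'
#' @param p Numeric probability vector summing to 1.
#' @return List with `H_bits` and `H_norm`.
#' @examples
#' row_entropy(c(0.5, 0.5, 0))  # H_bits = 1, H_norm = 1 / log2(3)
#' @export
row_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1", call. = FALSE)
  nz <- p[p > 0]
  h <- -sum(nz * log2(nz))
  list(H_bits = h, H_norm = h / log2(length(p)))
}

#' Per-context and global transition entropy
#'
#' Computes state-wise entropy for every observed conditioning context of a
#' transition model and aggregates to a global value as the weighted mean of
#' per-context entropies, weighted by empirical context occupancy (each
#' context's share of all observed transitions). Unobserved contexts get
#' weight zero. The normalization constant is `log2(3)` — the number of
#' possible destinations — regardless of model order.
#'
#' @param model A `transition_model` from [estimate_transitions()], or a
#'   `fixture_matrix`, in which case occupancy weights are taken from the
#'   chain's stationary distribution (the infinite-data limit).
#' @return An object of class `entropy_summary`: list with `order`,
#'   `per_context` (tibble: context, weight, H_bits, H_norm),
#'   `global_H_bits`, `global_H_norm`.
#' @export
global_entropy <- function(model) {
  P <- model$prob
  if (inherits(model, "fixture_matrix")) {
    w <- if (model$order == 1L) {
      stationary_distribution(P)
    } else {
      stationary_distribution(pair_chain_matrix(P, model$states))
    }
  } else {
    rs <- rowSums(model$counts)
    if (sum(rs) == 0) stop("model has no observed context", call. = FALSE)
    w <- rs / sum(rs)
  }
  hb <- vapply(seq_len(nrow(P)), function(i) {
    if (is.na(P[i, 1]) || w[i] == 0) return(NA_real_)
    row_entropy(P[i, ])$H_bits
  }, 0)
  obs <- !is.na(hb)
  gH <- sum(w[obs] * hb[obs]) / sum(w[obs])
  out <- list(
    order = model$order,
    per_context = tibble::tibble(
      context = rownames(P), weight = as.numeric(w),
      H_bits = hb, H_norm = hb / log2(3)),
    global_H_bits = gH,
    global_H_norm = gH / log2(3)
  )
  class(out) <- "entropy_summary"
  out
}

#' @export
print.entropy_summary <- function(x, ...) {
  cat(sprintf("Order-%d transition entropy\n", x$order))
  print(as.data.frame(x$per_context), digits = 3)
  cat(sprintf("global: H_bits = %.3f, H_norm = %.3f\n",
              x$global_H_bits, x$global_H_norm))
  invisible(x)
}

#' Per-participant global normalized entropy
#'
#' Fits a transition model and computes the global normalized entropy
#' separately for each participant. Participants contributing no usable
#' transition at the requested order are excluded with a message.
#'
#' @inheritParams estimate_transitions
#' @return Tibble with columns `participant`, `n_transitions`, `H_bits`,
#'   `H_norm`; attribute `excluded` lists dropped participants.
#' @export
participant_entropies <- function(sequences, order = 1L, skip = 0L) {
  parts <- unique(sequences$participant)
  rows <- list()
  excluded <- character()
  for (p in parts) {
    sub <- sequences[sequences$participant == p, , drop = FALSE]
    m <- tryCatch(estimate_transitions(sub, order = order, skip = skip),
                  error = function(e) NULL)
    if (is.null(m)) {
      excluded <- c(excluded, p)
      next
    }
    es <- global_entropy(m)
    rows[[p]] <- tibble::tibble(participant = p, n_transitions = m$n_transitions,
                                H_bits = es$global_H_bits,
                                H_norm = es$global_H_norm)
  }
  if (!length(rows)) stop("no participant has usable sequences", call. = FALSE)
  if (length(excluded)) {
    message("participant_entropies: excluded ", length(excluded),
            " participant(s) with no usable sequence: ",
            paste(excluded, collapse = ", "))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  out
}

#' Compare first- and second-order entropy across participants
#'
#' Paired comparison of per-participant global normalized entropies from the
#' first- and second-order models: the median difference `H1 - H2`, a
#' percentile bootstrap 95% interval obtained by resampling participants
#' with replacement, and a two-sided Wilcoxon signed-rank test on the paired
#' differences (zeros dropped, exact or normal approximation as chosen by
#' [stats::wilcox.test()]).
#'
#' @param h1,h2 Paired numeric vectors of per-participant global normalized
#'   entropies (same participants, same order).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed for the bootstrap (restores the RNG
#'   state on exit).
#' @return An object of class `order_comparison`: list with `median_diff`,
#'   `ci_low`, `ci_high`, `wilcoxon_V`, `p_value`, `n`, `n_boot`, `seed`,
#'   and the per-participant differences `d`.
#' @export
compare_orders <- function(h1, h2, n_boot = 10000L, seed = NULL) {
  if (length(h1) != length(h2)) stop("`h1` and `h2` must be paired vectors",
                                     call. = FALSE)
  n <- length(h1)
  if (n < 5) stop("need at least 5 participants for resampling inference",
                  call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  d <- h1 - h2
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boot_med <- apply(matrix(d[idx], nrow = n), 2, stats::median)
  ci <- stats::quantile(boot_med, c(0.025, 0.975), names = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(h1, h2, paired = TRUE))
  out <- list(median_diff = stats::median(d),
              ci_low = ci[1], ci_high = ci[2],
              wilcoxon_V = unname(wt$statistic), p_value = wt$p.value,
              n = n, n_boot = n_boot, seed = seed, d = d)
  class(out) <- "order_comparison"
  out
}

#' @export
print.order_comparison <- function(x, ...) {
  cat(sprintf(
    "Entropy difference H1 - H2 (n = %d participants)\n  median = %.4f, 95%% bootstrap CI [%.4f, %.4f] (B = %d)\n  Wilcoxon signed-rank V = %.1f, p = %.4g\n",
    x$n, x$median_diff, x$ci_low, x$ci_high, x$n_boot, x$wilcoxon_V, x$p_value))
  invisible(x)
}
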