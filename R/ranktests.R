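#' Kruskal-Wallis test across facial zones with epsilon-squared
#'
#' Rank-based comparison of a metric (e.g. anchor distance or stability)
#' across the facial zones, via [stats::kruskal.test()] (tie-corrected H,
#' chi-squared approximation), plus the epsilon-squared effect size
#' `H / (n - 1)`.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return A one-row tibble: `test`, `statistic` (H), `df`, `p_raw`,
#'   `effect_size` (epsilon-squared), `n`, and `groups` (comma-separated
#'   labels).
#' @examples
#' kruskal_wallis(list(UFZ = c(1, 2, 3), CFZ = c(4, 5, 6), LFZ = c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  n <- length(values)
  if (n < 5) stop("need at least 5 observations in total", call. = FALSE)
  kt <- stats::kruskal.test(values, g)
  tibble::tibble(
    test = "kruskal_wallis",
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_raw = kt$p.value,
    effect_size = unname(kt$statistic) / (n - 1),
    n = n,
    groups = paste(names(groups), collapse = ",")
  )
}

#' Pairwise rank-sum comparisons with Holm correction
#'
#' All pairwise two-sided Wilcoxon rank-sum tests between independent
#' groups (normal approximation with continuity correction), Holm step-down
#' adjusted p-values across the family, and the effect size
#' `r = |Z| / sqrt(n1 + n2)` with Z recovered from the two-sided p-value.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return Tibble with one row per pair: `group1`, `group2`, `n1`, `n2`,
#'   `statistic` (rank-sum W), `z`, `p_raw`, `p_adjusted`, `effect_r`.
#' @export
pairwise_wilcoxon_holm <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    z <- stats::qnorm(wt$p.value / 2, lower.tail = FALSE)
    tibble::tibble(
      group1 = pr[1], group2 = pr[2],
      n1 = length(a), n2 = length(b),
      statistic = unname(wt$statistic), z = z,
      p_raw = wt$p.value,
      effect_r = z / sqrt(length(a) + length(b))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "holm")
  out[, c("group1", "group2", "n1", "n2", "statistic", "z", "p_raw",
          "p_adjusted", "effect_r")]
}
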