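#' Rank spatial units by dwell time per participant
#'
#' For each participant, accumulates fixation duration per spatial unit —
#' either the three facial zones or a uniform grid over the face box — and
#' ranks the units by dwell (mid-ranks for ties, rank 1 = least dwell).
#' Participants with zero total dwell are excluded with a message.
#'
#' @param sequences A labelled sequence tibble from [build_sequences()].
#' @param units `"three_zones"` (default) or `"grid"`.
#' @param grid_dims For `units = "grid"`, `c(rows, cols)` of the grid laid
#'   over the bounding box of the zones.
#' @param layout Required for `units = "grid"`: the AOI layout whose
#'   bounding box defines the grid extent (the first item's box is used).
#' @return Numeric matrix of ranks, participants in rows, units in columns.
#' @export
dwell_ranks <- function(sequences, units = c("three_zones", "grid"),
                        grid_dims = c(2, 2), layout = NULL) {
  units <- match.arg(units)
  fx <- sequences
  if (units == "three_zones") {
    fx$unit <- factor(fx$label, levels = aoi_states())
  } else {
    if (is.null(layout)) stop("`layout` is required for grid units", call. = FALSE)
    lz <- layout[layout$item == layout$item[1], ]
    xb <- seq(min(lz$x_min), max(lz$x_max), length.out = grid_dims[2] + 1)
    yb <- seq(min(lz$y_min), max(lz$y_max), length.out = grid_dims[1] + 1)
    ri <- cut(fx$y_px, yb, include.lowest = TRUE, labels = FALSE)
    ci <- cut(fx$x_px, xb, include.lowest = TRUE, labels = FALSE)
    keep <- !is.na(ri) & !is.na(ci)
    fx <- fx[keep, , drop = FALSE]
    cells <- paste0("r", rep(seq_len(grid_dims[1]), each = grid_dims[2]),
                    "c", rep(seq_len(grid_dims[2]), grid_dims[1]))
    fx$unit <- factor(paste0("r", ri[keep], "c", ci[keep]), levels = cells)
  }
  dwell <- tapply(fx$duration_ms, list(fx$participant, fx$unit), sum,
                  default = 0)
  total <- rowSums(dwell)
  if (any(total == 0)) {
    message("dwell_ranks: excluded ", sum(total == 0),
            " participant(s) with zero dwell")
    dwell <- dwell[total > 0, , drop = FALSE]
  }
  if (nrow(dwell) < 2) stop("need at least 2 participants with dwell",
                            call. = FALSE)
  t(apply(dwell, 1, rank))
}

#' Kendall's coefficient of concordance
#'
#' Agreement among participants' rankings of spatial units by dwell:
#' `W = 12 S / (m^2 (n^3 - n))` with `S` the sum of squared deviations of
#' the unit rank sums from their mean, `m` participants and `n` units. No
#' tie correction is applied (ties enter through mid-ranks).
#'
#' @param rank_matrix Numeric matrix of ranks, participants in rows, units
#'   in columns (as from [dwell_ranks()]).
#' @return An object of class `concordance_result`: list with `W`, `S`,
#'   `m`, `n`, `rank_sums`, `rank_matrix`.
#' @examples
#' kendall_w(rbind(c(1, 2, 3), c(1, 2, 3)))  # W = 1
#' @export
kendall_w <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  m <- nrow(rank_matrix)
  n <- ncol(rank_matrix)
  if (m < 2 || n < 2) stop("need at least 2 participants and 2 units",
                           call. = FALSE)
  R <- colSums(rank_matrix)
  S <- sum((R - mean(R))^2)
  W <- 12 * S / (m^2 * (n^3 - n))
  out <- list(W = W, S = S, m = m, n = n, rank_sums = R,
              rank_matrix = rank_matrix)
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Kendall's W = %.3f (m = %d participants, n = %d units, S = %.1f)\n",
              x$W, x$m, x$n, x$S))
  invisible(x)
}
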