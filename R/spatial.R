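#' Euclidean distance between fixation points
#'
#' @param x1,y1,x2,y2 Numeric vectors of screen coordinates in pixels.
#' @return Numeric vector of distances `sqrt((x2-x1)^2 + (y2-y1)^2)`.
#' @examples
#' euclidean_dist(0, 0, 3, 4)  # 5
#' @export
euclidean_dist <- function(x1, y1, x2, y2) {
  sqrt((x2 - x1)^2 + (y2 - y1)^2)
}

#' Path length of an ordered fixation sequence
#'
#' Sum of Euclidean distances between consecutive fixation points; 0 for a
#' single point.
#'
#' @param x,y Numeric vectors of coordinates in temporal order.
#' @return Scalar path length in pixels.
#' @examples
#' path_length(c(0, 1, 3), c(0, 0, 0))  # 3
#' @export
path_length <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (length(x) == 1L) return(0)
  sum(euclidean_dist(x[-length(x)], y[-length(y)], x[-1], y[-1]))
}

#' Anchor-based cross-event repositioning distances
#'
#' For every target-face presentation, computes the Euclidean distance
#' between the last fixation of the preceding event — the spatial anchor —
#' and the first fixation on the target face, together with the facial zone
#' the landing fixation falls in. Under the `pre_context` condition the
#' preceding event is the context image of the same trial; under
#' `post_context` it is the response screen of the previous trial (so the
#' first trial of a block has no anchor). Presentations lacking either an
#' anchor fixation or a target fixation are skipped and counted.
#'
#' @param fixations A cleaned fixation tibble (with `event_type` among
#'   context / target / response). When a `condition` column is present it is
#'   filtered to the requested condition.
#' @param layout An AOI layout covering the items present.
#' @param condition `"pre_context"` or `"post_context"`.
#' @return Tibble with one row per usable presentation: `participant`,
#'   `item`, `trial`, `condition`, `anchor_x`, `anchor_y`, `landing_x`,
#'   `landing_y`, `distance`, `landing_zone`. Attribute `n_skipped` counts
#'   skipped presentations.
#' @export
anchor_transitions <- function(fixations, layout,
                               condition = c("pre_context", "post_context")) {
  condition <- match.arg(condition)
  validate_aoi_layout(layout)
  fx <- fixations
  if ("condition" %in% names(fx)) {
    fx <- fx[fx$condition == condition, , drop = FALSE]
  }
  anchor_event <- if (condition == "pre_context") "context" else "response"
  anchor_trial_offset <- if (condition == "pre_context") 0L else 1L

  targets <- fx[fx$event_type == "target", , drop = FALSE]
  anchors <- fx[fx$event_type == anchor_event, , drop = FALSE]
  # first target fixation / last anchor fixation per participant x trial
  first_t <- dplyr::slice_min(dplyr::group_by(targets, .data$participant,
                                              .data$trial),
                              .data$t_onset_ms, n = 1, with_ties = FALSE)
  last_a <- dplyr::slice_max(dplyr::group_by(anchors, .data$participant,
                                             .data$trial),
                             .data$t_onset_ms, n = 1, with_ties = FALSE)
  first_t <- dplyr::ungroup(first_t)
  last_a <- dplyr::ungroup(last_a)
  last_a$trial_of_target <- last_a$trial + anchor_trial_offset

  joined <- dplyr::inner_join(
    first_t,
    last_a[, c("participant", "trial_of_target", "x_px", "y_px")],
    by = c("participant", "trial" = "trial_of_target"),
    suffix = c("", "_anchor"))
  n_skipped <- nrow(first_t) - nrow(joined)
  if (n_skipped > 0) {
    message(sprintf("anchor_transitions: skipped %d presentation(s) without a usable anchor",
                    n_skipped))
  }
  lz <- character(nrow(joined))
  for (it in unique(joined$item)) {
    sel <- joined$item == it
    lz[sel] <- assign_aoi(joined$x_px[sel], joined$y_px[sel], layout, it)
  }
  out <- tibble::tibble(
    participant = joined$participant, item = joined$item,
    trial = joined$trial, condition = condition,
    anchor_x = joined$x_px_anchor, anchor_y = joined$y_px_anchor,
    landing_x = joined$x_px, landing_y = joined$y_px,
    distance = euclidean_dist(joined$x_px_anchor, joined$y_px_anchor,
                              joined$x_px, joined$y_px),
    landing_zone = lz
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Gaze stability per facial zone
#'
#' For each participant (optionally per trial) and facial zone, computes the
#' total fixation duration, the within-zone path length — the sum of
#' consecutive-fixation distances over pairs whose two fixations both lie in
#' the zone, accumulated across that group's sequences — and the gaze
#' stability index, total duration divided by path length (ms per pixel).
#' Pairs spanning two zones contribute to neither. Groups with zero path
#' length (e.g. a zone visited only by isolated single fixations) are
#' excluded and counted.
#'
#' @param sequences A labelled sequence tibble from [build_sequences()]
#'   (target-face fixations).
#' @param level `"participant_aoi"` for participant x zone aggregates (the
#'   grain of the zone-effect mixed model) or `"participant_aoi_event"` for
#'   trial-level rows carrying the `condition` column (the grain of the
#'   event-order model).
#' @return Tibble with grouping columns, `total_duration`, `path_length`,
#'   `stability`; attribute `n_zero_path` counts excluded groups.
#' @export
stability_table <- function(sequences,
                            level = c("participant_aoi", "participant_aoi_event")) {
  level <- match.arg(level)
  fx <- sequences
  seq_keys <- intersect(c("participant", "item", "trial", "condition",
                          "event_type", "segment"), names(fx))
  grp <- interaction(fx[seq_keys], drop = TRUE, lex.order = TRUE)
  # consecutive within-sequence pairs, attributed to a zone only when both
  # endpoints share it
  n <- nrow(fx)
  gi <- as.integer(grp)
  same_seq <- c(gi[-n] == gi[-1], FALSE)
  seg_d <- c(euclidean_dist(fx$x_px[-n], fx$y_px[-n],
                            fx$x_px[-1], fx$y_px[-1]), NA_real_)
  same_zone <- c(fx$label[-n] == fx$label[-1], FALSE)
  pair_ok <- same_seq & same_zone

  agg_keys <- if (level == "participant_aoi") "participant"
              else intersect(c("participant", "condition", "trial"), names(fx))
  fx$.path <- ifelse(pair_ok, seg_d, 0)
  dur <- dplyr::summarise(
    dplyr::group_by(fx, dplyr::across(dplyr::all_of(c(agg_keys, "label")))),
    total_duration = sum(.data$duration_ms),
    path_length = sum(.data$.path),
    .groups = "drop")
  dur <- dplyr::rename(dur, zone = "label")
  zero <- dur$path_length <= 0
  n_zero <- sum(zero)
  if (n_zero > 0) {
    message(sprintf("stability_table: excluded %d group(s) with zero within-zone path length",
                    n_zero))
  }
  out <- dur[!zero, , drop = FALSE]
  out$stability <- out$total_duration / out$path_length
  attr(out, "n_zero_path") <- n_zero
  out
}
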