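canonical_columns <- function() {
  c("participant", "item", "trial", "event_type", "t_onset_ms",
    "duration_ms", "x_px", "y_px")
}

#' Read a fixation export
#'
#' Reads a delimited fixation table (tab- or comma-separated, with header)
#' into a typed tibble. Vendor column names are mapped to the canonical
#' fields through a dialect: a named character vector whose names are the
#' canonical fields (`participant`, `item`, `trial`, `event_type`,
#' `t_onset_ms`, `duration_ms`, `x_px`, `y_px`, optionally `valid` and
#' `condition`) and whose values are the column names found in the file.
#' Numeric fields that fail to parse (e.g. the literal string `"NA"`) are
#' marked missing but retained, so that [clean_fixations()] can count them.
#'
#' @param path Path to the file. Files ending in `.csv` are read as
#'   comma-separated, anything else as tab-separated.
#' @param dialect Optional named character vector mapping canonical field
#'   names to the file's column names; omit for files already using the
#'   canonical names (such as [write_fixations()] output).
#' @return A tibble with the canonical columns plus `valid` (defaulting to
#'   `TRUE` when absent from the file) and, when present, `condition`.
#' @export
read_fixations <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (!is.null(dialect)) {
    found <- intersect(dialect, names(raw))
    ren <- dialect[dialect %in% found]
    names(raw)[match(ren, names(raw))] <- names(ren)
  }
  missing_cols <- setdiff(canonical_columns(), names(raw))
  if (length(missing_cols)) {
    stop("fixation file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    participant = as.character(raw$participant),
    item = as.character(raw$item),
    trial = suppressWarnings(as.integer(raw$trial)),
    event_type = as.character(raw$event_type),
    t_onset_ms = num(raw$t_onset_ms),
    duration_ms = num(raw$duration_ms),
    x_px = num(raw$x_px),
    y_px = num(raw$y_px)
  )
  out$valid <- if ("valid" %in% names(raw)) {
    toupper(raw$valid) %in% c("TRUE", "T", "1", "YES")
  } else TRUE
  if ("condition" %in% names(raw)) out$condition <- as.character(raw$condition)
  out
}

#' Clean a fixation table
#'
#' Removes records flagged invalid and records with missing coordinates,
#' onset or duration (or negative duration), then restores temporal order
#' within each participant x item x trial x event group. The number of
#' dropped records is reported via `message()` and attached as the
#' `n_removed` attribute.
#'
#' @param fixations A fixation tibble from [read_fixations()] or
#'   [generate_fixations()].
#' @return The cleaned tibble, ordered by participant, trial, event and
#'   onset, with attribute `n_removed`.
#' @export
clean_fixations <- function(fixations) {
  keep <- fixations$valid &
    !is.na(fixations$x_px) & !is.na(fixations$y_px) &
    !is.na(fixations$t_onset_ms) &
    !is.na(fixations$duration_ms) & fixations$duration_ms >= 0
  n_removed <- sum(!keep)
  out <- fixations[keep, , drop = FALSE]
  if (n_removed > 0) {
    message(sprintf("clean_fixations: removed %d of %d records", n_removed,
                    length(keep)))
  }
  if (nrow(out) == 0) warning("no fixations remain after cleaning", call. = FALSE)
  out <- dplyr::arrange(out, .data$participant, .data$trial, .data$item,
                        .data$event_type, .data$t_onset_ms)
  attr(out, "n_removed") <- n_removed
  out
}

#' Assign points to facial zones
#'
#' Point-in-rectangle test against one item's AOI layout, using the
#' half-open convention `[min, max)` on both axes: a point on the shared
#' boundary of two stacked zones belongs to the lower zone, whose top edge
#' is closed. Points in no zone map to `"OUTSIDE"`.
#'
#' @param x,y Numeric vectors of screen coordinates in pixels (origin
#'   top-left, y increasing downward).
#' @param layout An AOI layout tibble restricted to a single item (three
#'   rows), or a multi-item layout together with `item`.
#' @param item Item identifier selecting the layout block when `layout`
#'   covers several items.
#' @return Character vector over `UFZ`, `CFZ`, `LFZ`, `OUTSIDE`.
#' @examples
#' lay <- default_face_layout("item01")
#' assign_aoi(960, 540, lay, "item01")
#' @export
assign_aoi <- function(x, y, layout, item = NULL) {
  if (!is.null(item)) layout <- layout[layout$item == item, ]
  if (length(unique(layout$item)) != 1L || nrow(layout) != 3L) {
    stop("`layout` must contain exactly one item's three zones; ",
         "pass `item` to select one", call. = FALSE)
  }
  out <- rep("OUTSIDE", length(x))
  for (i in seq_len(nrow(layout))) {
    hit <- x >= layout$x_min[i] & x < layout$x_max[i] &
      y >= layout$y_min[i] & y < layout$y_max[i]
    out[hit] <- layout$zone[i]
  }
  out
}

#' Build zone-labelled fixation sequences
#'
#' Segments cleaned fixations by participant, item, trial and event, labels
#' each fixation with its facial zone via [assign_aoi()], and returns the
#' scanpath sequences in long form. Fixations falling outside all zones are
#' by default dropped with the sequence stitched across the gap; with
#' `break_at_outside = TRUE` they instead split the sequence into segments
#' (so no transition is counted across the gap). Repeated same-zone
#' fixations are retained as distinct elements.
#'
#' @param fixations A cleaned fixation tibble.
#' @param layout An AOI layout covering every item present.
#' @param events Which event types to keep (default: target-face fixations,
#'   the only ones with facial AOIs).
#' @param break_at_outside Split sequences at out-of-zone fixations instead
#'   of stitching across them.
#' @return A tibble with one row per retained fixation: the grouping keys,
#'   `segment` (sequence segment within the group), `ord` (temporal rank
#'   within segment), `label`, and the fixation's `x_px`, `y_px`,
#'   `duration_ms`. Attribute `n_outside` counts out-of-zone fixations.
#' @export
build_sequences <- function(fixations, layout, events = "target",
                            break_at_outside = FALSE) {
  validate_aoi_layout(layout)
  fx <- fixations[fixations$event_type %in% events, , drop = FALSE]
  missing_items <- setdiff(unique(fx$item), unique(layout$item))
  if (length(missing_items)) {
    stop("no AOI layout for item(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  fx <- dplyr::arrange(fx, .data$participant, .data$trial, .data$item,
                       .data$event_type, .data$t_onset_ms)
  fx$label <- NA_character_
  for (it in unique(fx$item)) {
    sel <- fx$item == it
    fx$label[sel] <- assign_aoi(fx$x_px[sel], fx$y_px[sel], layout, it)
  }
  n_outside <- sum(fx$label == "OUTSIDE")

  keys <- c("participant", "item", "trial",
            intersect("condition", names(fx)), "event_type")
  grp <- interaction(fx[keys], drop = TRUE, lex.order = TRUE)
  if (break_at_outside) {
    out_flag <- fx$label == "OUTSIDE"
    seg <- stats::ave(as.integer(out_flag), grp, FUN = cumsum)
    fx$segment <- seg + 1L
    fx <- fx[!out_flag, , drop = FALSE]
  } else {
    fx$segment <- 1L
    fx <- fx[fx$label != "OUTSIDE", , drop = FALSE]
  }
  if (nrow(fx) == 0) {
    warning("no in-zone fixations for the requested events", call. = FALSE)
    return(structure(fx[0, ], n_outside = n_outside))
  }
  grp2 <- interaction(fx[c(keys, "segment")], drop = TRUE, lex.order = TRUE)
  fx$ord <- stats::ave(seq_len(nrow(fx)), grp2, FUN = seq_along)
  out <- fx[, c(keys, "segment", "ord", "label", "x_px", "y_px", "duration_ms")]
  attr(out, "n_outside") <- n_outside
  out
}
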