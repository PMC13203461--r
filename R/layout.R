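#' Default three-band facial AOI layout
#'
#' Constructs an AOI layout in which each item's face occupies a centred box
#' on the screen, split into three horizontal bands: the upper facial zone
#' (forehead to supraorbital ridge), the central zone (supraorbital ridge to
#' subnasale) and the lower zone (subnasale to chin). Coordinates are screen
#' pixels with the origin at the top-left and y increasing downward.
#'
#' @param items Character vector of item identifiers; the same face box is
#'   used for every item.
#' @param screen Screen size in pixels, `c(width, height)`.
#' @param face_box Face box size in pixels, `c(width, height)`, centred on the
#'   screen.
#' @param band_props Proportions of the face-box height taken by the upper,
#'   central and lower bands (must sum to 1).
#' @return A tibble with columns `item`, `zone`, `x_min`, `y_min`, `x_max`,
#'   `y_max`; one row per item x zone. Rectangles use the half-open
#'   convention `[min, max)`.
#' @examples
#' default_face_layout("item01")
#' @export
default_face_layout <- function(items = "item01",
                                screen = c(1920, 1080),
                                face_box = c(600, 800),
                                band_props = c(0.30, 0.40, 0.30)) {
  stopifnot(length(screen) == 2, length(face_box) == 2,
            length(band_props) == 3, abs(sum(band_props) - 1) < 1e-9)
  x0 <- (screen[1] - face_box[1]) / 2
  y0 <- (screen[2] - face_box[2]) / 2
  cuts <- y0 + cumsum(c(0, band_props)) * face_box[2]
  one <- tibble::tibble(
    zone  = aoi_states(),
    x_min = x0, y_min = cuts[1:3],
    x_max = x0 + face_box[1], y_max = cuts[2:4]
  )
  out <- tidyr::crossing(item = as.character(items), one)
  validate_aoi_layout(out)
  out
}

#' Validate an AOI layout table
#'
#' Checks that a layout has the required columns, that within each item the
#' three zones are pairwise non-overlapping, and that they are stacked
#' vertically in the order upper, central, lower (y increasing downward).
#'
#' @param layout A layout tibble as produced by [default_face_layout()] or
#'   [read_aoi_layout()].
#' @return Invisibly `layout`; errors when the layout is malformed.
#' @export
validate_aoi_layout <- function(layout) {
  need <- c("item", "zone", "x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(layout))
  if (length(miss)) {
    stop("layout is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (it in unique(layout$item)) {
    lz <- layout[layout$item == it, ]
    if (!setequal(lz$zone, aoi_states())) {
      stop(sprintf("item '%s' must define exactly the zones %s", it,
                   paste(aoi_states(), collapse = ", ")), call. = FALSE)
    }
    lz <- lz[match(aoi_states(), lz$zone), ]
    if (any(lz$x_max <= lz$x_min) || any(lz$y_max <= lz$y_min)) {
      stop(sprintf("item '%s' has a degenerate rectangle", it), call. = FALSE)
    }
    if (lz$y_max[1] > lz$y_min[2] + 1e-9 || lz$y_max[2] > lz$y_min[3] + 1e-9) {
      stop(sprintf("item '%s': zones must be stacked UFZ above CFZ above LFZ",
                   it), call. = FALSE)
    }
  }
  invisible(layout)
}

#' Read and write AOI layouts as structured text
#'
#' Layouts are stored as YAML: one block per item, each zone a rectangle
#' `[x_min, y_min, x_max, y_max]` in screen pixels.
#'
#' @param layout A validated layout tibble.
#' @param path File path.
#' @return `read_aoi_layout()` returns a layout tibble; `write_aoi_layout()`
#'   invisibly returns `path`.
#' @export
write_aoi_layout <- function(layout, path) {
  validate_aoi_layout(layout)
  items <- split(layout, layout$item)
  obj <- lapply(items, function(lz) {
    zs <- lapply(seq_len(nrow(lz)), function(i)
      as.numeric(lz[i, c("x_min", "y_min", "x_max", "y_max")]))
    stats::setNames(zs, lz$zone)
  })
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_aoi_layout
#' @export
read_aoi_layout <- function(path) {
  obj <- yaml::read_yaml(path)
  rows <- lapply(names(obj), function(it) {
    zl <- obj[[it]]
    tibble::tibble(
      item = it, zone = names(zl),
      x_min = unname(vapply(zl, function(r) r[[1]], 0)),
      y_min = unname(vapply(zl, function(r) r[[2]], 0)),
      x_max = unname(vapply(zl, function(r) r[[3]], 0)),
      y_max = unname(vapply(zl, function(r) r[[4]], 0))
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_aoi_layout(out)
  out
}
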