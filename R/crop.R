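# column of a (possibly oblique) separating line at image row i:
# the line is {p : rotated column of p == index} in the frame rotated by
# line$angle about line$center
line_column_at_row <- function(line, i) {
  a <- line$angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  line$center[2L] + (line$index - line$center[2L] - sa * (i - line$center[1L])) / ca
}

# signed rotated-frame coordinates of a pixel grid under a line's frame
rotated_col_grid <- function(line, rows, cols) {
  a <- line$angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  di <- rows - line$center[1L]
  dj <- cols - line$center[2L]
  line$center[2L] + outer(sa * di, ca * dj, `+`)
}

rotated_row_grid <- function(line, rows, cols) {
  a <- line$angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  di <- rows - line$center[1L]
  dj <- cols - line$center[2L]
  line$center[1L] + outer(ca * di, -sa * dj, `+`)
}

#' Crop a single tooth and mask pixels beyond its separating lines
#'
#' Cuts the axis-aligned bounding box spanned by the two (possibly
#' oblique) interdental separating lines out of a tooth-row image, and
#' zeroes every pixel on the far side of the left line, the far side of
#' the right line, or beyond the row separating line, by half-plane
#' tests against each line in its own rotated frame. Pixels inside all
#' half-planes are left untouched. Masking out neighboring-tooth
#' fragments that fall inside the bounding box prevents them from
#' confusing the downstream classifier.
#'
#' `left` and/or `right` may be `NULL`, meaning the image edge (the
#' outermost teeth); `row_sep` may be `NULL` when the row image was
#' already cut at the row separating line (the usual pipeline case).
#'
#' @param row_img Grayscale image of one tooth row.
#' @param left,right Column [separator_line()]s bounding the tooth, or
#'   `NULL` for the image edge. `left` must lie strictly left of `right`.
#' @param row_sep Optional row [separator_line()] in this image's frame.
#' @param row `"upper"` or `"lower"`: which side of `row_sep` the tooth
#'   row lies on.
#' @return An object of class `"tooth_crop"`: a list with `image` (the
#'   masked crop), `bbox` (`c(top, left, bottom, right)`, 1-based
#'   inclusive, in `row_img` coordinates), `left_line`, `right_line`,
#'   `row`, and `mask_fraction` (fraction of bounding-box pixels zeroed
#'   by masking, in `[0, 1)`).
#' @export
crop_and_mask <- function(row_img, left = NULL, right = NULL,
                          row_sep = NULL, row = c("upper", "lower")) {
  row <- match.arg(row)
  h <- nrow(row_img); w <- ncol(row_img)
  edge_rows <- c(1, h)
  bb_left <- if (is.null(left)) 1L else
    max(1L, floor(min(line_column_at_row(left, edge_rows))))
  bb_right <- if (is.null(right)) w else
    min(w, ceiling(max(line_column_at_row(right, edge_rows))))
  if (!is.null(left) && !is.null(right) && left$index >= right$index)
    stop("left separating line must lie strictly left of the right one",
         call. = FALSE)
  if (bb_right <= bb_left)
    stop("degenerate crop: bounding box has no area", call. = FALSE)

  rows <- seq_len(h); cols <- seq(bb_left, bb_right)
  crop <- row_img[, cols, drop = FALSE]
  keep <- matrix(TRUE, h, length(cols))
  if (!is.null(left))
    keep <- keep & (rotated_col_grid(left, rows, cols) >= left$index)
  if (!is.null(right))
    keep <- keep & (rotated_col_grid(right, rows, cols) <= right$index)
  if (!is.null(row_sep)) {
    rr <- rotated_row_grid(row_sep, rows, cols)
    keep <- keep & if (row == "upper") rr < row_sep$index else rr >= row_sep$index
  }
  crop[!keep] <- 0
  structure(list(image = crop,
                 bbox = c(top = 1L, left = bb_left, bottom = h, right = bb_right),
                 left_line = left, right_line = right, row = row,
                 mask_fraction = mean(!keep)),
            class = "tooth_crop")
}

#' @export
print.tooth_crop <- function(x, ...) {
  cat(sprintf("Tooth crop (%s row): %d x %d, cols %d..%d, %.1f%% masked\n",
              x$row, nrow(x$image), ncol(x$image),
              x$bbox[["left"]], x$bbox[["right"]], 100 * x$mask_fraction))
  invisible(x)
}

#' Slice a tooth crop into left and right halves
#'
#' Caries and restorations are judged per tooth side, so each masked
#' single-tooth crop is cut at its middle column into a left and a right
#' half image. For odd widths the left half receives the extra column.
#' Sides are labeled in the source image's orientation.
#'
#' @param crop A `"tooth_crop"` from [crop_and_mask()].
#' @param bitewing_id Provenance: identifier of the source bitewing.
#' @param tooth Provenance: tooth ordinal within its row (left to right).
#' @return A list of two objects of class `"half_tooth"`, sides
#'   `"left"` and `"right"`; each has `image`, `side`, `bitewing_id`,
#'   `row` and `tooth`.
#' @export
split_halves <- function(crop, bitewing_id = "bitewing", tooth = NA_integer_) {
  stopifnot(inherits(crop, "tooth_crop"))
  w <- ncol(crop$image)
  if (w < 2L) stop("tooth crop must be at least 2 columns wide", call. = FALSE)
  mid <- ceiling(w / 2)
  mk <- function(img, side)
    structure(list(image = img, side = side, bitewing_id = bitewing_id,
                   row = crop$row, tooth = tooth),
              class = "half_tooth")
  list(mk(crop$image[, seq_len(mid), drop = FALSE], "left"),
       mk(crop$image[, seq(mid + 1L, w), drop = FALSE], "right"))
}

#' @export
print.half_tooth <- function(x, ...) {
  cat(sprintf("Half-tooth image: %s %s tooth %s, %s side, %d x %d\n",
              x$bitewing_id, x$row, x$tooth, x$side,
              nrow(x$image), ncol(x$image)))
  invisible(x)
}
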