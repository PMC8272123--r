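#' Separating lines
#'
#' A separating line is the minimizer `(angle, index)` of a projection
#' profile over a rotation sweep: in the frame obtained by rotating the
#' image by `angle` degrees ([rotate_image()]), the line is row `index`
#' (axis `"row"`) or column `index` (axis `"column"`). `score` is the
#' minimized projection value and `center` the `(row, col)` rotation
#' center of the frame the search ran in, which is needed to evaluate
#' the line as an oblique half-plane in the unrotated frame
#' ([crop_and_mask()]). Indices are 1-based, following R convention.
#'
#' @param angle Degrees.
#' @param index 1-based row or column index in the rotated frame.
#' @param score Minimized projection value (non-negative).
#' @param axis `"row"` or `"column"`.
#' @param center Length-2 numeric `(row, col)` rotation center.
#' @return An object of class `"separator_line"`.
#' @export
separator_line <- function(angle, index, score, axis = c("row", "column"),
                           center) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(angle), length(angle) == 1L,
            is.numeric(index), length(index) == 1L, index >= 1,
            is.numeric(score), length(score) == 1L, score >= 0,
            length(center) == 2L)
  structure(list(angle = angle, index = as.integer(index), score = score,
                 axis = axis, center = as.numeric(center)),
            class = "separator_line")
}

#' @export
print.separator_line <- function(x, ...) {
  cat(sprintf("Separating line: %s %d at angle %+.1f deg (score %.0f)\n",
              x$axis, x$index, x$angle, x$score))
  invisible(x)
}

# angles of an inclusive sweep -range..range by step, ordered so that the
# first strict minimum encountered realizes the tie-break:
# smaller |angle| first, then smaller angle
sweep_angles <- function(angle_range, step) {
  a <- seq(-angle_range, angle_range, by = step)
  if (max(a) < angle_range) a <- c(a, angle_range)
  a[order(abs(a), a)]
}

# in-band minimum of a profile restricted to the foreground extent,
# ties resolved toward the index nearest `center_index`, then smallest
band_minimum <- function(profile, band, center_index) {
  vals <- profile[band]
  m <- min(vals)
  cand <- band[vals == m]
  cand <- cand[order(abs(cand - center_index), cand)]
  list(index = cand[1L], score = m, band_mean = mean(vals))
}

# rows (margin = "row") or columns with any foreground, as a full range
content_band <- function(bin, axis) {
  p <- if (axis == "row") rowSums(bin) else colSums(bin)
  nz <- which(p > 0)
  if (length(nz) == 0L) return(NULL)
  seq(nz[1L], nz[length(nz)])
}

#' Row separating line by rotation-optimized horizontal projection
#'
#' Sweeps rotation angles over an inclusive grid
#' `-angle_range .. +angle_range` (degrees, spacing `step`), rotates the
#' binary image at each angle (nearest-neighbor, zero fill), computes
#' the horizontal projection restricted to the rows intersecting the
#' rotated foreground's bounding box, and returns the global minimizer
#' `(angle, row)`. The band restriction keeps zero-filled border rows
#' introduced by the rotation from trivially minimizing the projection.
#' Ties are broken toward smaller `|angle|`, then smaller angle, then
#' the row nearest the image center, then the smaller row.
#'
#' @param bin Binary bitewing image (`{0, 255}`) with nonzero mass.
#' @param angle_range Half-width of the sweep in degrees (default 15;
#'   clinical bitewing tilt is small).
#' @param step Sweep spacing in degrees (default 1).
#' @return A `"separator_line"` with axis `"row"`.
#' @export
find_row_separator <- function(bin, angle_range = 15, step = 1) {
  if (sum(bin) == 0) stop("image has no foreground content", call. = FALSE)
  h <- nrow(bin); w <- ncol(bin)
  center <- c((h + 1) / 2, (w + 1) / 2)
  best <- NULL
  for (a in sweep_angles(angle_range, step)) {
    rot <- rotate_image(bin, a, "nearest")
    band <- content_band(rot, "row")
    if (is.null(band)) next
    hit <- band_minimum(rowSums(rot), band, center[1L])
    if (is.null(best) || hit$score < best$score) {
      best <- hit; best$angle <- a
    }
  }
  separator_line(best$angle, best$index, best$score, "row", center)
}

#' Split a bitewing into upper and lower tooth rows
#'
#' Rotates the source image (bilinear) and its binary companion
#' (nearest-neighbor) by the separator's angle and cuts at its row:
#' the upper output holds rows above the separating line, the lower
#' output holds the separator row and everything below.
#'
#' @param src Grayscale bitewing.
#' @param bin Its binarization (same extent).
#' @param sep Row separating line from [find_row_separator()].
#' @return A list with `upper`, `lower`, `upper_bin`, `lower_bin`,
#'   and the applied `angle` and cut `index`.
#' @export
split_rows <- function(src, bin, sep) {
  stopifnot(inherits(sep, "separator_line"), sep$axis == "row",
            identical(dim(src), dim(bin)))
  h <- nrow(src)
  if (sep$index <= 1L || sep$index > h)
    stop("degenerate split: separator leaves an empty side", call. = FALSE)
  src_r <- rotate_image(src, sep$angle, "bilinear")
  bin_r <- rotate_image(bin, sep$angle, "nearest")
  up <- seq_len(sep$index - 1L)
  lo <- seq(sep$index, h)
  list(upper = src_r[up, , drop = FALSE], lower = src_r[lo, , drop = FALSE],
       upper_bin = bin_r[up, , drop = FALSE],
       lower_bin = bin_r[lo, , drop = FALSE],
       angle = sep$angle, index = sep$index)
}

#' Interdental separating lines by recursive vertical-projection search
#'
#' The rotation-optimized vertical projection yields one separating
#' line per search; to separate an unknown number of teeth the search
#' is applied by recursive bisection. On each column segment the global
#' minimizer `(angle, column)` is found exactly as in
#' [find_row_separator()] but over columns; the cut is accepted when its
#' score is at most `valley_ceiling` times the mean in-band column mass
#' (at the minimizing angle) and both resulting sides are at least
#' `min_tooth_width` columns wide. Accepted cuts recurse on each side;
#' an unsplittable segment is a single tooth. Lines are returned sorted
#' left to right.
#'
#' Each returned line's `center` is the center of the column segment it
#' was found on, so the line can be re-evaluated as an oblique
#' half-plane in the row image's frame.
#'
#' @param row_bin Binary image of one tooth row, nonzero mass.
#' @inheritParams find_row_separator
#' @param min_tooth_width Minimum admissible tooth width in pixels
#'   (default 8% of the row image width).
#' @param valley_ceiling Valley acceptance ceiling as a fraction of the
#'   mean in-band column mass (default 0.15).
#' @return A list of `"separator_line"` objects (possibly empty) with
#'   axis `"column"`, sorted by index.
#' @export
find_tooth_separators <- function(row_bin, angle_range = 15, step = 1,
                                  min_tooth_width = max(2L, round(0.08 * ncol(row_bin))),
                                  valley_ceiling = 0.15) {
  if (sum(row_bin) == 0) stop("image has no foreground content", call. = FALSE)
  h <- nrow(row_bin)
  angles <- sweep_angles(angle_range, step)

  bisect <- function(c0, c1) {
    width <- c1 - c0 + 1L
    if (width < 2L * min_tooth_width) return(list())
    sub <- row_bin[, c0:c1, drop = FALSE]
    if (sum(sub) == 0) return(list())
    sub_center <- c((h + 1) / 2, (width + 1) / 2)
    best <- NULL
    for (a in angles) {
      rot <- rotate_image(sub, a, "nearest")
      band <- content_band(rot, "column")
      if (is.null(band)) next
      hit <- band_minimum(colSums(rot), band, sub_center[2L])
      if (is.null(best) || hit$score < best$score) {
        best <- hit; best$angle <- a
      }
    }
    if (is.null(best)) return(list())
    x <- best$index
    if (best$score > valley_ceiling * best$band_mean ||
        (x - 1L) < min_tooth_width || (width - x) < min_tooth_width)
      return(list())
    abs_index <- c0 - 1L + x
    line <- separator_line(best$angle, abs_index, best$score, "column",
                           c(sub_center[1L], c0 - 1 + sub_center[2L]))
    c(bisect(c0, abs_index - 1L), list(line), bisect(abs_index + 1L, c1))
  }

  lines <- bisect(1L, ncol(row_bin))
  lines[order(vapply(lines, `[[`, integer(1), "index"))]
}
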