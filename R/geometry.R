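#' Rotate an image about its center
#'
#' Rotates image content by `angle` degrees about the image center,
#' keeping the original extent and filling uncovered pixels with 0.
#' The rotation acts in (row, column) coordinates: a content point at
#' offset `(di, dj)` from the center moves to
#' `(cos a * di - sin a * dj, sin a * di + cos a * dj)`.
#' With rows drawn top-to-bottom this is a clockwise rotation on screen
#' for positive `angle`; the sign convention only matters in that
#' [rotated_coords()] and the synthetic generator use the same one, so
#' an image generated with rotation `+r` is levelled by rotating `-r`.
#'
#' Nearest-neighbor resampling preserves the `{0, 255}` alphabet of
#' binary images and is used throughout the projection searches;
#' bilinear resampling is used for grayscale crops.
#'
#' @param img Intensity matrix.
#' @param angle Rotation angle in degrees.
#' @param method `"nearest"` or `"bilinear"`.
#' @return Matrix with the same dimensions as `img`.
#' @export
rotate_image <- function(img, angle, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (angle == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  dqi <- matrix(seq_len(h) - ci, h, w)
  dqj <- matrix(seq_len(w) - cj, h, w, byrow = TRUE)
  # inverse map: source coordinates for each output pixel
  si <- ci + ca * dqi + sa * dqj
  sj <- cj - sa * dqi + ca * dqj
  out <- matrix(0, h, w)
  if (method == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= h & rj >= 1 & rj <= w
    out[ok] <- img[cbind(ri[ok], rj[ok])]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0;   fj <- sj - j0
    ok <- i0 >= 1 & i0 + 1 <= h & j0 >= 1 & j0 + 1 <= w
    i0 <- i0[ok]; j0 <- j0[ok]; fi <- fi[ok]; fj <- fj[ok]
    out[ok] <-
      img[cbind(i0,     j0)]     * (1 - fi) * (1 - fj) +
      img[cbind(i0 + 1, j0)]     * fi       * (1 - fj) +
      img[cbind(i0,     j0 + 1)] * (1 - fi) * fj +
      img[cbind(i0 + 1, j0 + 1)] * fi       * fj
    # convex combination: clamp float overshoot to the input range
    out[out < min(img, 0)] <- min(img, 0)
    out[out > max(img)] <- max(img)
  }
  out
}

#' Forward-rotated coordinates of pixel positions
#'
#' Returns where content at rows `i`, columns `j` of an image lands
#' after [rotate_image()] by `angle` degrees about `center` (defaults
#' to the image center implied by `dim`). Used for half-plane masking
#' against oblique separating lines and for mapping generator ground
#' truth into the rotated frame.
#'
#' @param i,j Numeric vectors of row/column positions (recycled).
#' @param angle Degrees.
#' @param center Length-2 numeric `(row, col)` rotation center.
#' @return A list with numeric vectors `i` and `j` of rotated positions.
#' @export
rotated_coords <- function(i, j, angle, center) {
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  di <- i - center[1L]; dj <- j - center[2L]
  list(i = center[1L] + ca * di - sa * dj,
       j = center[2L] + sa * di + ca * dj)
}

#' Resize an image by bilinear interpolation
#'
#' @param img Intensity matrix.
#' @param rows,cols Target extent.
#' @return `rows` x `cols` matrix, clipped to `[0, 255]`.
#' @export
resize_bilinear <- function(img, rows, cols) {
  if (nrow(img) < 1L || ncol(img) < 1L || rows < 1L || cols < 1L)
    stop("cannot resize an empty image", call. = FALSE)
  if (nrow(img) == rows && ncol(img) == cols) return(img)
  if (nrow(img) == 1L) img <- img[c(1L, 1L), , drop = FALSE]
  if (ncol(img) == 1L) img <- img[, c(1L, 1L), drop = FALSE]
  out <- EBImage::resize(EBImage::Image(t(img)), w = cols, h = rows,
                         filter = "bilinear")
  clip255(t(EBImage::imageData(out)))
}

#' Translate an image with zero fill
#'
#' @param img Intensity matrix.
#' @param di,dj Integer shifts (positive moves content down / right).
#' @return Matrix of the same size.
#' @export
translate_image <- function(img, di, dj) {
  h <- nrow(img); w <- ncol(img)
  di <- as.integer(round(di)); dj <- as.integer(round(dj))
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - di; src_c <- seq_len(w) - dj
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
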