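#' Radiograph images
#'
#' Throughout the package a radiograph is an ordinary numeric matrix of
#' 8-bit intensities: `pixels[i, j]` is the intensity of row `i`, column
#' `j`, with values in `[0, 255]` (0 = radiolucent background, 255 =
#' maximally radiopaque). `as_radiograph()` validates and coerces an
#' object to this form; most pipeline functions call it on entry.
#'
#' A valid radiograph has at least 2 rows and 2 columns and only finite
#' intensities within `[0, 255]`.
#'
#' @param x A numeric matrix (or an object coercible to one, e.g. an
#'   integer matrix).
#' @return A numeric matrix of intensities in `[0, 255]`.
#' @examples
#' img <- as_radiograph(matrix(c(0, 255, 128, 64), 2, 2))
#' @export
as_radiograph <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("a radiograph must be a numeric matrix", call. = FALSE)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("a radiograph must be at least 2 x 2 pixels", call. = FALSE)
  if (!all(is.finite(x)))
    stop("radiograph intensities must be finite", call. = FALSE)
  if (min(x) < 0 || max(x) > 255)
    stop("radiograph intensities must lie in [0, 255]", call. = FALSE)
  x
}

#' @rdname as_radiograph
#' @export
is_binary_image <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x == 0 | x == 255)
}

#' Read and write grayscale radiographs
#'
#' `read_radiograph()` loads an 8-bit PNG or TIFF file as an intensity
#' matrix in `[0, 255]`; color inputs are converted to grayscale by the
#' Rec. 601 luminance weights (0.299 R + 0.587 G + 0.114 B).
#' `write_radiograph()` writes a matrix as an 8-bit grayscale PNG.
#'
#' @param path File path. Format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`).
#' @param img Intensity matrix in `[0, 255]`.
#' @return `read_radiograph()` returns an intensity matrix;
#'   `write_radiograph()` returns `path` invisibly.
#' @export
read_radiograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    a <- if (nc >= 3L) {
      0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    } else {
      a[, , 1L]
    }
  }
  as_radiograph(round(a * 255))
}

#' @rdname read_radiograph
#' @export
write_radiograph <- function(img, path) {
  img <- clip255(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

# clip into [0, 255] without rescaling
clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
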