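#' Frequency-domain high-pass transfer grids
#'
#' Builds the transfer function \eqn{H(u,v)} evaluated on a
#' `height` x `width` grid with the zero frequency at the center
#' (the fftshift convention). `D(u,v)` is the Euclidean distance, in
#' index units, from the spectrum center.
#'
#' * `gaussian`: \eqn{H = 1 - \exp(-D^2 / (2 D_0^2))} (the standard
#'   Gaussian high-pass). Setting `denominator = "as_printed"` uses
#'   \eqn{2 D_0} in place of \eqn{2 D_0^2}, a dimensionally anomalous
#'   variant kept available for comparison.
#' * `ideal`: \eqn{H = 0} for \eqn{D \le D_0} and 1 elsewhere (a sharp
#'   cut at the cutoff frequency).
#'
#' @param height,width Grid extent (each at least 2).
#' @param cutoff Positive cutoff frequency \eqn{D_0}, in cycles from the
#'   spectrum center.
#' @param mode `"gaussian"` or `"ideal"`.
#' @param denominator `"standard"` (\eqn{2 D_0^2}) or `"as_printed"`
#'   (\eqn{2 D_0}); only used by the Gaussian form.
#' @return A `height` x `width` matrix with values in `[0, 1]`, equal to
#'   0 at the spectrum center.
#' @export
build_highpass_filter <- function(height, width, cutoff,
                                  mode = c("gaussian", "ideal"),
                                  denominator = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff frequency must be a positive number", call. = FALSE)
  if (height < 2L || width < 2L)
    stop("filter grid must be at least 2 x 2", call. = FALSE)
  cu <- floor(height / 2) + 1
  cv <- floor(width / 2) + 1
  D2 <- outer((seq_len(height) - cu)^2, (seq_len(width) - cv)^2, `+`)
  if (mode == "ideal") {
    H <- (sqrt(D2) > cutoff) * 1
  } else {
    den <- if (denominator == "standard") 2 * cutoff^2 else 2 * cutoff
    H <- 1 - exp(-D2 / den)
  }
  H
}

# circular shifts putting the DC bin at floor(n/2)+1 and back
fftshift_idx  <- function(n) { p <- floor(n / 2); c((n - p + 1):n, seq_len(n - p)) }
ifftshift_idx <- function(n) { q <- ceiling(n / 2); c((n - q + 1):n, seq_len(n - q)) }

#' Sharpen a radiograph by frequency-domain filtering
#'
#' Transforms the image with a 2-D FFT, shifts the zero frequency to the
#' center, multiplies pointwise by a high-pass transfer grid
#' ([build_highpass_filter()]), inverse-transforms, and takes the real
#' part. Negative values are clipped to 0 and, if the maximum exceeds
#' 255, the result is rescaled linearly into `[0, 255]`, so the filtered
#' image stays on the original intensity scale and the subtraction step
#' ([enhance_by_subtraction()]) remains meaningful.
#'
#' The transform is taken at the native image size (no padding).
#'
#' @param img Intensity matrix in `[0, 255]`.
#' @inheritParams build_highpass_filter
#' @return Filtered intensity matrix, same extent as `img`.
#' @export
apply_frequency_filter <- function(img, cutoff,
                                   mode = c("gaussian", "ideal"),
                                   denominator = c("standard", "as_printed")) {
  img <- as_radiograph(img)
  h <- nrow(img); w <- ncol(img)
  H <- build_highpass_filter(h, w, cutoff, mode, denominator)
  Fs <- stats::fft(img)[fftshift_idx(h), fftshift_idx(w)]
  G <- (Fs * H)[ifftshift_idx(h), ifftshift_idx(w)]
  g <- Re(stats::fft(G, inverse = TRUE)) / (h * w)
  g[g < 0] <- 0
  mx <- max(g)
  if (mx > 255) g <- g * (255 / mx)
  g
}

#' Subtraction enhancement
#'
#' Subtracts the high-pass filtered image from the original, pixelwise,
#' clipping the result to `[0, 255]`. High-frequency impurities and edge
#' ringing picked up by the filter are thereby removed from the original
#' while the broad intensity bands (background, alveolar bone, teeth)
#' are preserved, which sharpens the subsequent binarization.
#'
#' @param original,filtered Intensity matrices of equal extent.
#' @return Enhanced intensity matrix.
#' @export
enhance_by_subtraction <- function(original, filtered) {
  if (!identical(dim(original), dim(filtered)))
    stop("original and filtered images must have identical dimensions",
         call. = FALSE)
  clip255(original - filtered)
}

#' Otsu threshold selection
#'
#' Selects the intensity threshold `t` in `0..254` that maximizes the
#' between-class variance of the split into background (pixels `<= t`)
#' and foreground (pixels `> t`), by exhaustive sweep over all 255
#' candidate splits of the 8-bit histogram. Maximizing between-class
#' variance is equivalent to minimizing the pooled within-class
#' variance. Ties are broken toward the smallest `t`. Non-integer
#' intensities are floored onto the 8-bit grid before the sweep.
#'
#' @param img Intensity matrix with at least two distinct (floored)
#'   intensity values.
#' @return Integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(img) {
  v <- floor(as.vector(img))
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("cannot threshold a constant image (degenerate histogram)",
         call. = FALSE)
  p <- counts / length(v)
  w0 <- cumsum(p)[1:255]
  mu <- cumsum(p * (0:255))
  muT <- mu[256L]
  sb <- (muT * w0 - mu[1:255])^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  which.max(sb) - 1L   # first maximum = smallest t on ties
}

#' Binarize at a threshold
#'
#' Pixels strictly greater than `t` become 255 (foreground: teeth and
#' alveolar bone), all others 0 (background).
#'
#' @param img Intensity matrix.
#' @param t Threshold in `[0, 254]`.
#' @return Matrix over `{0, 255}` with the extent of `img`.
#' @export
binarize <- function(img, t) {
  if (t < 0 || t > 254) stop("threshold must lie in [0, 254]", call. = FALSE)
  (img > t) * 255
}

#' Full preprocessing chain for a bitewing film
#'
#' Runs high-pass filtering, subtraction enhancement, Otsu threshold
#' selection and binarization in sequence, returning every intermediate.
#'
#' @param img Raw grayscale bitewing, intensities in `[0, 255]`.
#' @param cutoff Cutoff frequency \eqn{D_0} of the high-pass filter;
#'   the default 30 suits bitewings a few hundred pixels across.
#' @inheritParams build_highpass_filter
#' @return A list of class `"bitewing_preprocess"` with elements
#'   `filtered`, `enhanced`, `threshold` and `binary`.
#' @export
preprocess_bitewing <- function(img, cutoff = 30,
                                mode = c("gaussian", "ideal"),
                                denominator = c("standard", "as_printed")) {
  img <- as_radiograph(img)
  filtered <- apply_frequency_filter(img, cutoff, mode, denominator)
  enhanced <- enhance_by_subtraction(img, filtered)
  t <- otsu_threshold(enhanced)
  structure(list(filtered = filtered, enhanced = enhanced,
                 threshold = t, binary = binarize(enhanced, t)),
            class = "bitewing_preprocess")
}

#' @export
print.bitewing_preprocess <- function(x, ...) {
  cat("Bitewing preprocessing result\n")
  cat(sprintf("  image extent : %d x %d\n", nrow(x$binary), ncol(x$binary)))
  cat(sprintf("  Otsu threshold: %d\n", x$threshold))
  cat(sprintf("  foreground    : %.1f%% of pixels\n",
              100 * mean(x$binary == 255)))
  invisible(x)
}
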