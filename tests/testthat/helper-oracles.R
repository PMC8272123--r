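# Independent oracles, coded from first principles and kept free of the
# package's implementation paths.

# direct O(N^4) 2-D discrete Fourier transform
oracle_dft2 <- function(x, inverse = FALSE) {
  m <- nrow(x); n <- ncol(x)
  sgn <- if (inverse) 2i else -2i
  out <- matrix(0 + 0i, m, n)
  for (u in seq_len(m)) for (v in seq_len(n)) {
    s <- 0 + 0i
    for (i in seq_len(m)) for (j in seq_len(n)) {
      s <- s + x[i, j] *
        exp(sgn * pi * ((u - 1) * (i - 1) / m + (v - 1) * (j - 1) / n))
    }
    out[u, v] <- s
  }
  out
}

# the whole frequency-domain sharpening chain with the direct DFT
oracle_highpass_chain <- function(img, cutoff) {
  m <- nrow(img); n <- ncol(img)
  FF <- oracle_dft2(img)
  cu <- floor(m / 2) + 1; cv <- floor(n / 2) + 1
  G <- matrix(0 + 0i, m, n)
  for (u in seq_len(m)) for (v in seq_len(n)) {
    # position of (u, v) after centering the zero frequency
    us <- ((u - 1 + floor(m / 2)) %% m) + 1
    vs <- ((v - 1 + floor(n / 2)) %% n) + 1
    D2 <- (us - cu)^2 + (vs - cv)^2
    G[u, v] <- FF[u, v] * (1 - exp(-D2 / (2 * cutoff^2)))
  }
  g <- Re(oracle_dft2(G, inverse = TRUE)) / (m * n)
  g[g < 0] <- 0
  if (max(g) > 255) g <- g * 255 / max(g)
  g
}

# exhaustive between-class-variance sweep over all 255 splits
oracle_otsu <- function(img) {
  v <- floor(as.vector(img))
  best_t <- NA_integer_; best_var <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best_var) { best_var <- bc; best_t <- t }
  }
  best_t
}

# per-pixel nearest-neighbor rotation about the image center
oracle_rotate_nearest <- function(img, angle) {
  h <- nrow(img); w <- ncol(img)
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  a <- angle * pi / 180
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    si <- round(ci + cos(a) * (i - ci) + sin(a) * (j - cj))
    sj <- round(cj - sin(a) * (i - ci) + cos(a) * (j - cj))
    if (si >= 1 && si <= h && sj >= 1 && sj <= w) out[i, j] <- img[si, sj]
  }
  out
}

# brute-force (angle, row) search: double loop, same tie-break order
oracle_row_separator <- function(bin, angle_range, step) {
  angles <- seq(-angle_range, angle_range, by = step)
  angles <- angles[order(abs(angles), angles)]
  h <- nrow(bin)
  center <- (h + 1) / 2
  best <- NULL
  for (a in angles) {
    rot <- oracle_rotate_nearest(bin, a)
    rs <- rowSums(rot)
    nz <- which(rs > 0)
    if (length(nz) == 0L) next
    band <- seq(nz[1L], nz[length(nz)])
    band <- band[order(abs(band - center), band)]
    for (r in band) {
      if (is.null(best) || rs[r] < best$score)
        best <- list(angle = a, index = r, score = rs[r])
    }
  }
  best
}
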