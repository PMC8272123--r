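# Small fixtures built in code.

# a clean two-band binary bitewing: white blocks with a zero row gap
fixture_two_rows <- function(h = 60, w = 80, gap = 28:32) {
  bin <- matrix(0, h, w)
  bin[setdiff(5:(h - 4), gap), 8:(w - 7)] <- 255
  bin
}

# a binary tooth row of `n` vertical white blocks separated by zero gaps;
# returns the image and the gap column intervals
fixture_tooth_row <- function(n = 4, h = 50, w = 120, gap_w = 4) {
  bin <- matrix(0, h, w)
  tw <- floor((w - (n - 1) * gap_w - 10) / n)
  gaps <- matrix(0L, max(n - 1, 0), 2)
  x <- 6L
  for (m in seq_len(n)) {
    bin[8:(h - 7), x:(x + tw - 1L)] <- 255
    if (m < n) gaps[m, ] <- c(x + tw, x + tw + gap_w - 1L)
    x <- x + tw + gap_w
  }
  list(bin = bin, gaps = gaps)
}

# tiny labeled half-tooth pool for database tests (small images for speed)
fixture_pool <- function(n_pos = 8, n_neg = 30, finding = "caries",
                         seed = 5, rows = 40, cols = 20) {
  kinds <- c(rep(finding, n_pos), rep("normal", n_neg))
  seeds <- withr::with_seed(seed, sample.int(1e6, length(kinds)))
  lapply(seq_along(kinds), function(i) {
    s <- generate_half_tooth(kinds[i], seed = seeds[i], rows = rows,
                             cols = cols)
    s$id <- sprintf("fix_%03d_%s", i, kinds[i])
    s$source <- s$id
    s
  })
}
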