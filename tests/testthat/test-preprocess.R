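test_that("high-pass transfer grid has the Gaussian closed form", {
  H <- build_highpass_filter(64, 64, 10)
  cu <- floor(64 / 2) + 1
  expect_equal(H[cu, cu], 0)                      # DC fully suppressed
  expect_equal(H[cu, cu + 10], 1 - exp(-1 / 2))   # value at D = D0
  expect_equal(H[cu, cu + 30], 1 - exp(-30^2 / (2 * 100)))
  # non-decreasing along a ray from the center
  ray <- H[cu, cu:64]
  expect_true(all(diff(ray) >= 0))
  # radial symmetry about the spectrum center
  expect_equal(H[cu + 5, cu + 3], H[cu - 5, cu - 3])
  expect_equal(H[cu + 5, cu - 3], H[cu - 5, cu + 3])
})

test_that("ideal high-pass is a sharp cut at the cutoff", {
  H <- build_highpass_filter(64, 64, 10, mode = "ideal")
  cu <- floor(64 / 2) + 1
  expect_equal(H[cu, cu + 10], 0)  # D == D0 suppressed
  expect_equal(H[cu, cu + 25], 1)  # D = 25 > D0 = 10 passes
  expect_true(all(H %in% c(0, 1)))
})

test_that("printed-form denominator variant is exposed", {
  Hs <- build_highpass_filter(16, 16, 4)
  Hp <- build_highpass_filter(16, 16, 4, denominator = "as_printed")
  cu <- floor(16 / 2) + 1
  expect_equal(Hp[cu, cu + 2], 1 - exp(-4 / (2 * 4)))
  expect_false(isTRUE(all.equal(Hs, Hp)))
})

test_that("invalid filter parameters are rejected", {
  expect_error(build_highpass_filter(8, 8, 0), "positive")
  expect_error(build_highpass_filter(8, 8, -3), "positive")
  expect_error(build_highpass_filter(1, 8, 5), "2 x 2")
})

test_that("frequency filtering suppresses a constant image entirely", {
  out <- apply_frequency_filter(matrix(137, 16, 16), 5)
  expect_equal(max(abs(out)), 0)
})

test_that("a lone bright pixel survives high-pass filtering at its location", {
  img <- matrix(0, 16, 16)
  img[6, 11] <- 255
  out <- apply_frequency_filter(img, 2)
  expect_equal(which(out == max(out)), which(img == 255))
})

test_that("frequency filtering matches an independently coded DFT chain", {
  for (s in 1:3) {
    img <- withr::with_seed(s, matrix(sample(0:255, 64, TRUE), 8, 8))
    expect_equal(apply_frequency_filter(img, 2.5),
                 oracle_highpass_chain(img, 2.5), tolerance = 1e-9)
  }
})

test_that("subtraction enhancement is a clipped pixelwise difference", {
  a <- matrix(200, 4, 4); b <- matrix(50, 4, 4)
  expect_equal(enhance_by_subtraction(a, b), matrix(150, 4, 4))
  expect_equal(enhance_by_subtraction(a, a), matrix(0, 4, 4))
  expect_equal(enhance_by_subtraction(matrix(10, 4, 4), matrix(30, 4, 4)),
               matrix(0, 4, 4))  # clipping floor
  expect_error(enhance_by_subtraction(a, matrix(0, 4, 5)), "dimensions")
})

test_that("Otsu picks the smallest maximizing threshold", {
  img <- matrix(c(rep(50, 60), rep(200, 40)), 10, 10)
  expect_equal(otsu_threshold(img), 50)  # all t in [50,199] tie; smallest wins
  img2 <- matrix(c(rep(0, 32), rep(255, 32)), 8, 8)
  expect_equal(otsu_threshold(img2), 0)
  expect_error(otsu_threshold(matrix(7, 4, 4)), "degenerate")
})

test_that("Otsu equals the exhaustive variance sweep on random images", {
  for (s in 1:20) {
    img <- withr::with_seed(100 + s, matrix(sample(0:255, 64, TRUE), 8, 8))
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("binarize uses the strict-greater rule and is idempotent", {
  img <- matrix(c(0, 120, 130, 125), 2, 2)
  expect_equal(binarize(img, 125), matrix(c(0, 0, 255, 0), 2, 2))
  expect_equal(binarize(matrix(255, 2, 2), 0), matrix(255, 2, 2))
  expect_equal(binarize(matrix(0, 2, 2), 0), matrix(0, 2, 2))
  b <- binarize(img, 100)
  expect_equal(binarize(b, 0), b)
  expect_error(binarize(img, 255), "\\[0, 254\\]")
})

test_that("enhanced binarization recovers the tooth/background split", {
  sp <- scene_spec(teeth_per_row = 6, noise_sd = 1, seed = 31)
  gb <- generate_bitewing(sp)
  canvas <- gb$truth$canvas
  tooth_px <- canvas >= (sp$alveolar + sp$tooth) / 2
  bg_px <- canvas <= (sp$background + sp$alveolar) / 2
  pre <- preprocess_bitewing(gb$image)
  fg <- pre$binary == 255
  expect_gte(mean(fg[tooth_px]), 0.95)  # tooth coverage
  expect_lte(mean(fg[bg_px]), 0.05)     # background leakage
})
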