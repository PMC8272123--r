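test_that("standardization fixes the 200 x 100 extent", {
  big <- matrix(runif(400 * 200, 0, 255), 400, 200)
  expect_equal(dim(standardize_half_image(big)), c(200, 100))
  already <- matrix(runif(200 * 100, 0, 255), 200, 100)
  expect_identical(standardize_half_image(already), already)
  expect_equal(range(standardize_half_image(matrix(50, 33, 17))), c(50, 50))
})

test_that("contrast stretch maps the percentile range onto [0, 255]", {
  img <- matrix(runif(200 * 100, 100, 150), 200, 100)
  out <- enhance_contrast(img, "stretch")
  expect_lte(min(out), 1)
  expect_gte(max(out), 254)
  cst <- matrix(77, 200, 100)
  expect_identical(enhance_contrast(cst, "stretch"), cst)
  expect_identical(enhance_contrast(cst, "equalize"), cst)
  full <- matrix(seq(0, 255, length.out = 200 * 100), 200, 100)
  out2 <- enhance_contrast(full, "stretch")
  mid <- full > 30 & full < 225  # off the clipped tails
  expect_lt(max(abs(out2[mid] - full[mid])), 16)
})

test_that("augmentation is seeded, bounded and involutive under flips", {
  img <- standardize_half_image(generate_half_tooth("caries", seed = 2)$image)
  a1 <- augment_image(img, seed = 10)
  a2 <- augment_image(img, seed = 10)
  expect_identical(a1, a2)
  expect_equal(dim(a1), c(200, 100))
  expect_true(all(a1 >= 0 & a1 <= 255))
  expect_false(identical(unclass(a1), unclass(img)))
  idpars <- list(flip_v = FALSE, flip_h = FALSE, rotation = 0, zoom = 1,
                 shift = c(0, 0), gain = 1, brightness = 0)
  ident <- toothcutter:::apply_augmentation(img, idpars)
  attr(ident, "augment_params") <- NULL
  expect_identical(ident, img)
  fl <- idpars; fl$flip_h <- TRUE
  once <- toothcutter:::apply_augmentation(img, fl)
  expect_identical(unname(once[1, ]), unname(rev(img[1, ])))
  twice <- toothcutter:::apply_augmentation(once, fl)
  attr(twice, "augment_params") <- NULL
  expect_identical(twice, img)
})

test_that("balancing augments scarce positives up to the target", {
  pool <- fixture_pool(n_pos = 8, n_neg = 30)
  db <- balance_database(pool, "caries", target_count = 20, seed = 3)
  expect_length(db$positives, 20)
  expect_length(db$negatives, 20)
  expect_equal(sum(db$pos_meta$augmented), 12)
  expect_length(db$augmentation_log, 12)
  expect_true(all(vapply(db$positives, function(x)
    all(dim(x) == c(200, 100)), logical(1))))
  # augmented copies trace back to real positives
  expect_true(all(db$pos_meta$source %in%
                    db$pos_meta$id[!db$pos_meta$augmented]))
})

test_that("balancing subsamples abundant positives without augmentation", {
  pool <- fixture_pool(n_pos = 25, n_neg = 30, finding = "restoration")
  db <- balance_database(pool, "restoration", target_count = 15, seed = 3)
  expect_length(db$positives, 15)
  expect_equal(sum(db$pos_meta$augmented), 0)
  db2 <- balance_database(pool, "restoration", target_count = 25, seed = 3)
  expect_length(db2$positives, 25)  # exact fit: no augmentation either
  expect_equal(sum(db2$pos_meta$augmented), 0)
})

test_that("balancing guards its preconditions", {
  pool <- fixture_pool(n_pos = 0, n_neg = 10)
  expect_error(balance_database(pool, "caries", target_count = 5, seed = 1),
               "zero positive")
  pool2 <- fixture_pool(n_pos = 4, n_neg = 3)
  expect_error(balance_database(pool2, "caries", target_count = 5, seed = 1),
               "negative samples")
})

test_that("splits are stratified, leakage-free and deterministic", {
  pool <- fixture_pool(n_pos = 10, n_neg = 60)
  db <- balance_database(pool, "caries", target_count = 30, seed = 3)
  db <- split_dataset(db, seed = 5)
  sp <- db$split
  expect_setequal(unique(sp$split), c("train", "validation", "test"))
  # augmented copies always share their source's split
  for (src in unique(sp$source))
    expect_length(unique(sp$split[sp$source == src]), 1)
  # no test image shares provenance with any train/validation image
  test_src <- sp$source[sp$split == "test"]
  expect_length(intersect(test_src, sp$source[sp$split != "test"]), 0)
  db2 <- split_dataset(db, seed = 5)
  expect_identical(db$split, db2$split)
  db3 <- split_dataset(db, seed = 6)
  expect_false(identical(db$split, db3$split))
  expect_error(split_dataset(db, train_frac = 1), "strictly between")
})

test_that("unaugmented databases split exactly 70/30 with original-only test", {
  pool <- fixture_pool(n_pos = 30, n_neg = 40, finding = "restoration")
  db <- balance_database(pool, "restoration", target_count = 20, seed = 3)
  db <- split_dataset(db, seed = 5)
  tab <- table(db$split$split, db$split$class)
  expect_equal(unname(tab["test", "positive"]), 6)    # round(20 * 0.3)
  expect_equal(unname(tab["test", "negative"]), 6)
  expect_equal(sum(tab[, "positive"]), 20)
  expect_false(any(db$split$augmented[db$split$split == "test"]))
})
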