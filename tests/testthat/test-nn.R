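test_that("layer plan reproduces the modified architecture extents", {
  plan <- alexnet_plan(c(200, 100, 3), classes = 2, fc_width = 1280)
  expect_equal(nrow(plan), 25)
  act <- function(name) plan$activation[plan$name == name]
  expect_equal(act("input"), "200 x 100 x 3")
  expect_equal(act("conv1"), "48 x 23 x 96")
  expect_equal(act("pool1"), "23 x 11 x 96")
  expect_equal(act("conv2"), "23 x 11 x 256")
  expect_equal(act("pool2"), "11 x 5 x 256")
  expect_equal(act("conv3"), "11 x 5 x 384")
  expect_equal(act("conv5"), "11 x 5 x 256")
  expect_equal(act("pool5"), "5 x 2 x 256")
  expect_equal(act("fc6"), "1 x 1 x 1280")
  expect_equal(act("fc8"), "1 x 1 x 2")
  expect_equal(act("classoutput"), "2")
  expect_equal(plan$kind[c(2, 3, 4, 5)],
               c("convolution", "relu", "normalization", "maxpooling"))
})

test_that("the canonical input reproduces original AlexNet extents", {
  plan <- alexnet_plan(c(227, 227, 3), classes = 1000, fc_width = 4096)
  act <- function(name) plan$activation[plan$name == name]
  expect_equal(act("conv1"), "55 x 55 x 96")
  expect_equal(act("pool1"), "27 x 27 x 96")
  expect_equal(act("pool2"), "13 x 13 x 256")
  expect_equal(act("pool5"), "6 x 6 x 256")
  expect_equal(act("fc6"), "1 x 1 x 4096")
  expect_equal(act("classoutput"), "1000")
})

test_that("the realized model passes its own extent audit", {
  m <- build_alexnet(seed = 1)
  expect_s3_class(m, "bitewing_cnn")
  expect_equal(m$layers$conv1$out_dim, c(48, 23, 96))
  expect_equal(m$layers$pool5$out_dim, c(5, 2, 256))
  expect_equal(m$layers$fc8$out_dim, c(1, 1, 2))
  expect_equal(m$init, "random")
  expect_error(build_alexnet(weights = list(conv9 = list(W = 1, b = 1))),
               "no trainable layer")
  expect_error(
    build_alexnet(weights = list(conv1 = list(W = matrix(0, 2, 2), b = 0))),
    "extent mismatch")
})

test_that("analytic gradients match numerical differentiation", {
  tc <- asNamespace("toothcutter")
  set.seed(9)
  dims <- c(9L, 7L, 2L)
  layers <- list(tc$nn_conv(dims, 4L, 3L, 2L, 1L))
  d <- layers[[1]]$out_dim
  layers <- c(layers, list(tc$nn_relu(d), tc$nn_lrn(d),
                           tc$nn_maxpool(d, 2L, 2L)))
  d <- layers[[4]]$out_dim
  layers <- c(layers, list(tc$nn_fc(d, 3L)))
  layers <- lapply(layers, tc$nn_init)
  x <- matrix(rnorm(prod(dims[1:2]) * dims[3]), dims[3])
  label <- 2L
  loss_of <- function(ls)
    tc$softmax_xent(tc$net_forward(ls, x)$logits, label)$loss
  fwd <- tc$net_forward(layers, x)
  g <- tc$net_backward(layers, fwd$caches,
                       tc$softmax_xent(fwd$logits, label)$dlogits)
  eps <- 1e-6
  for (li in c(1L, 5L)) {
    for (k in sample(length(layers[[li]]$W), 10)) {
      lp <- layers; lp[[li]]$W[k] <- lp[[li]]$W[k] + eps
      lm <- layers; lm[[li]]$W[k] <- lm[[li]]$W[k] - eps
      expect_equal(g[[li]]$W[k], (loss_of(lp) - loss_of(lm)) / (2 * eps),
                   tolerance = 1e-5)
    }
    for (k in seq_along(layers[[li]]$b)) {
      lp <- layers; lp[[li]]$b[k] <- lp[[li]]$b[k] + eps
      lm <- layers; lm[[li]]$b[k] <- lm[[li]]$b[k] - eps
      expect_equal(g[[li]]$b[k], (loss_of(lp) - loss_of(lm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("response normalization backward matches its numerical gradient", {
  tc <- asNamespace("toothcutter")
  set.seed(4)
  xl <- matrix(rnorm(24) * 3, 6)   # 6 channels so the window truncates
  l <- tc$nn_lrn(c(2L, 2L, 6L))
  f <- tc$layer_forward(l, xl)
  dy <- matrix(rnorm(24), 6)
  bk <- tc$layer_backward(l, dy, f$cache)
  eps <- 1e-6
  for (k in seq_along(xl)) {
    xp <- xl; xp[k] <- xp[k] + eps
    xm <- xl; xm[k] <- xm[k] - eps
    num <- (sum(dy * tc$layer_forward(l, xp)$y) -
              sum(dy * tc$layer_forward(l, xm)$y)) / (2 * eps)
    expect_equal(bk$dx[k], num, tolerance = 1e-6)
  }
})

test_that("truth tables keep counts and the accuracy formula consistent", {
  tt <- truth_table(tp = 9, fn = 1, fp = 0, tn = 10)
  expect_equal(tt$accuracy, 95)
  expect_equal(tt$total, 20)
  expect_equal(tt$tp + tt$fn, 10)  # actual positives conserved
  perfect <- truth_table(5, 0, 0, 5)
  expect_equal(perfect$accuracy, 100)
  expect_error(truth_table(0, 0, 0, 0), "empty")
  out <- capture.output(print(tt))
  expect_true(any(grepl("90", out)))   # row-normalized 90/10 visible
  expect_true(any(grepl("95.00", out, fixed = TRUE)))
})

test_that("a zero learning rate leaves the weights untouched", {
  m <- build_alexnet(seed = 2)
  imgs <- lapply(1:2, function(i) standardize_half_image(
    generate_half_tooth(c("normal", "restoration")[i], seed = i)$image))
  cfg <- train_config(learn_rate = 0, max_epochs = 1, minibatch_size = 2,
                      validation_patience = Inf, seed = 1)
  m2 <- train_cnn(m, list(images = imgs, labels = c(1L, 2L)), cfg)
  expect_identical(m2$layers$conv1$W, m$layers$conv1$W)
  expect_identical(m2$layers$fc8$W, m$layers$fc8$W)
  expect_equal(nrow(m2$history), 1)
})

test_that("training is deterministic given the seed", {
  imgs <- lapply(1:4, function(i) standardize_half_image(
    generate_half_tooth(c("normal", "restoration")[(i %% 2) + 1],
                        seed = 10 + i)$image))
  labs <- c(2L, 1L, 2L, 1L)
  cfg <- train_config(learn_rate = 1e-4, max_epochs = 1, minibatch_size = 2,
                      validation_patience = Inf, seed = 99)
  h1 <- train_cnn(build_alexnet(seed = 5),
                  list(images = imgs, labels = labs), cfg)$history
  h2 <- train_cnn(build_alexnet(seed = 5),
                  list(images = imgs, labels = labs), cfg)$history
  expect_identical(h1$train_loss, h2$train_loss)
})

test_that("prediction and the per-tooth report expose calibrated phrasing", {
  mc <- build_alexnet(seed = 3)
  mr <- build_alexnet(seed = 4)
  half <- standardize_half_image(generate_half_tooth("normal",
                                                     seed = 8)$image)
  pr <- predict(mc, half)
  expect_equal(dim(pr), c(1, 2))
  expect_equal(unname(rowSums(pr)), 1, tolerance = 1e-12)
  rep <- predict_tooth(mc, mr, half)
  expect_s3_class(rep, "tooth_report")
  expect_match(rep$text[1], "% to be (normal|caries|restorations)")
  if (length(rep$findings) == 0) {
    expect_lt(rep$caries_prob, 0.5)
    expect_lt(rep$restoration_prob, 0.5)
    expect_match(rep$text, "normal")
  }
  expect_error(predict_tooth(mc, mr, matrix(0, 10, 10)), "standardize")
})
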