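#' Layer plan of the modified AlexNet
#'
#' Computes the 25-layer plan of the classifier: AlexNet's canonical
#' kernels (conv-1 11x11 stride 4 pad 0; all pools 3x3 stride 2; conv-2
#' 5x5 pad 2; conv-3..5 3x3 pad 1) with the input extent changed to
#' 200 x 100 x 3, the fully connected widths reduced to 1280, and a
#' 2-way class output. Per-layer activation extents follow the floor
#' arithmetic `floor((in - kernel + 2*pad)/stride) + 1`. With the
#' canonical 227 x 227 x 3 input and 1000 classes the plan reproduces
#' original AlexNet (55x55x96 conv-1, 6x6x256 pool-5, 4096-wide fully
#' connected layers).
#'
#' @param input_dim Length-3 input extent `c(rows, cols, channels)`.
#' @param classes Number of output classes.
#' @param fc_width Width of the two hidden fully connected layers.
#' @return A data frame with columns `layer`, `name`, `kind`, `rows`,
#'   `cols`, `channels` and `activation` (e.g. `"48 x 23 x 96"`).
#' @export
alexnet_plan <- function(input_dim = c(200L, 100L, 3L), classes = 2L,
                         fc_width = 1280L) {
  specs <- list(
    list("input", "input", NA, NA, NA, NA),
    list("conv1", "convolution", 96L, 11L, 4L, 0L),
    list("relu1", "relu", NA, NA, NA, NA),
    list("norm1", "normalization", NA, NA, NA, NA),
    list("pool1", "maxpooling", NA, 3L, 2L, 0L),
    list("conv2", "convolution", 256L, 5L, 1L, 2L),
    list("relu2", "relu", NA, NA, NA, NA),
    list("norm2", "normalization", NA, NA, NA, NA),
    list("pool2", "maxpooling", NA, 3L, 2L, 0L),
    list("conv3", "convolution", 384L, 3L, 1L, 1L),
    list("relu3", "relu", NA, NA, NA, NA),
    list("conv4", "convolution", 384L, 3L, 1L, 1L),
    list("relu4", "relu", NA, NA, NA, NA),
    list("conv5", "convolution", 256L, 3L, 1L, 1L),
    list("relu5", "relu", NA, NA, NA, NA),
    list("pool5", "maxpooling", NA, 3L, 2L, 0L),
    list("fc6", "fully_connected", fc_width, NA, NA, NA),
    list("relu6", "relu", NA, NA, NA, NA),
    list("drop6", "dropout", NA, NA, NA, NA),
    list("fc7", "fully_connected", fc_width, NA, NA, NA),
    list("relu7", "relu", NA, NA, NA, NA),
    list("drop7", "dropout", NA, NA, NA, NA),
    list("fc8", "fully_connected", classes, NA, NA, NA),
    list("softmax", "softmax", NA, NA, NA, NA),
    list("classoutput", "classoutput", NA, NA, NA, NA))
  dim <- as.integer(input_dim)
  rows <- list()
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    kind <- s[[2]]
    if (kind == "convolution") {
      dim <- c(conv_out_extent(dim[1L], s[[4]], s[[5]], s[[6]]),
               conv_out_extent(dim[2L], s[[4]], s[[5]], s[[6]]),
               s[[3]])
    } else if (kind == "maxpooling") {
      dim <- c(conv_out_extent(dim[1L], s[[4]], s[[5]], 0L),
               conv_out_extent(dim[2L], s[[4]], s[[5]], 0L),
               dim[3L])
    } else if (kind == "fully_connected") {
      dim <- c(1L, 1L, s[[3]])
    } else if (kind == "classoutput") {
      dim <- c(1L, 1L, dim[3L])
    }
    if (any(dim < 1L))
      stop("layer plan is inconsistent: empty extent at ", s[[1]],
           call. = FALSE)
    rows[[k]] <- data.frame(layer = k, name = s[[1]], kind = kind,
                            rows = dim[1L], cols = dim[2L],
                            channels = dim[3L])
  }
  plan <- do.call(rbind, rows)
  plan$activation <- ifelse(
    plan$kind == "classoutput", as.character(plan$channels),
    ifelse(plan$rows == 1L & plan$cols == 1L,
           sprintf("1 x 1 x %d", plan$channels),
           sprintf("%d x %d x %d", plan$rows, plan$cols, plan$channels)))
  plan
}

#' Build the modified AlexNet classifier
#'
#' Instantiates the trainable network behind [alexnet_plan()]: five
#' convolutions with ReLU activations, local response normalization
#' after the first two (depth 5, alpha 1e-4, beta 0.75, k 2), three
#' 3x3/stride-2 max pools, two dropout-regularized fully connected
#' layers of width `fc_width`, and a `classes`-way softmax output. The
#' realized per-layer extents are audited against the plan at build
#' time and any inconsistency is an error.
#'
#' Weights are drawn from a He-normal distribution under `seed` unless
#' `weights` supplies pretrained parameters (a named list of `W`/`b`
#' pairs per trainable layer, the transfer-learning entry point); the
#' initialization mode is recorded in the model.
#'
#' @inheritParams alexnet_plan
#' @param seed Integer seed for weight initialization.
#' @param weights Optional named list (`conv1`..`conv5`, `fc6`..`fc8`)
#'   of lists with elements `W` and `b`.
#' @param dropout_rate Dropout probability (default 0.5).
#' @return An object of class `"bitewing_cnn"` with elements `layers`,
#'   `plan`, `input_dim`, `classes`, `init` and (after training)
#'   `history`.
#' @export
build_alexnet <- function(input_dim = c(200L, 100L, 3L), classes = 2L,
                          fc_width = 1280L, seed = 1, weights = NULL,
                          dropout_rate = 0.5) {
  input_dim <- as.integer(input_dim)
  plan <- alexnet_plan(input_dim, classes, fc_width)
  dim <- input_dim
  layers <- list()
  add <- function(layer, name) {
    layers[[name]] <<- layer
    dim <<- layer$out_dim
  }
  add(nn_conv(dim, 96L, 11L, 4L, 0L), "conv1")
  add(nn_relu(dim), "relu1")
  add(nn_lrn(dim), "norm1")
  add(nn_maxpool(dim), "pool1")
  add(nn_conv(dim, 256L, 5L, 1L, 2L), "conv2")
  add(nn_relu(dim), "relu2")
  add(nn_lrn(dim), "norm2")
  add(nn_maxpool(dim), "pool2")
  add(nn_conv(dim, 384L, 3L, 1L, 1L), "conv3")
  add(nn_relu(dim), "relu3")
  add(nn_conv(dim, 384L, 3L, 1L, 1L), "conv4")
  add(nn_relu(dim), "relu4")
  add(nn_conv(dim, 256L, 3L, 1L, 1L), "conv5")
  add(nn_relu(dim), "relu5")
  add(nn_maxpool(dim), "pool5")
  add(nn_fc(dim, fc_width), "fc6")
  add(nn_relu(dim), "relu6")
  add(nn_dropout(dim, dropout_rate), "drop6")
  add(nn_fc(dim, fc_width), "fc7")
  add(nn_relu(dim), "relu7")
  add(nn_dropout(dim, dropout_rate), "drop7")
  add(nn_fc(dim, classes), "fc8")

  # audit the realized extents against the plan (layers 2..23)
  realized <- t(vapply(layers, `[[`, numeric(3), "out_dim"))
  planned <- as.matrix(plan[2:23, c("rows", "cols", "channels")])
  if (!all(realized == planned))
    stop("model build error: realized layer extents disagree with the plan",
         call. = FALSE)

  init <- "random"
  layers <- withr::with_seed(as.integer(seed), lapply(layers, nn_init))
  if (!is.null(weights)) {
    for (nm in names(weights)) {
      if (is.null(layers[[nm]]$W))
        stop("no trainable layer named ", nm, call. = FALSE)
      if (!all(dim(weights[[nm]]$W) == dim(layers[[nm]]$W)))
        stop("pretrained weight extent mismatch at ", nm, call. = FALSE)
      layers[[nm]]$W <- weights[[nm]]$W
      layers[[nm]]$b <- weights[[nm]]$b
    }
    init <- "pretrained"
  }
  structure(list(layers = layers, plan = plan, input_dim = input_dim,
                 classes = classes, fc_width = fc_width, seed = seed,
                 init = init, history = NULL, config = NULL,
                 finding = NULL),
            class = "bitewing_cnn")
}

#' @export
print.bitewing_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    if (is.null(l$W)) 0L else length(l$W) + length(l$b), integer(1)))
  cat(sprintf("Modified AlexNet: input %s, %d classes, %s weights (%s parameters)\n",
              paste(x$input_dim, collapse = " x "), x$classes, x$init,
              format(np, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final train acc %.1f%%, val acc %.1f%%\n",
                nrow(x$history), 100 * utils::tail(x$history$train_acc, 1),
                100 * utils::tail(x$history$val_acc, 1)))
  invisible(x)
}

#' @export
summary.bitewing_cnn <- function(object, ...) {
  print(object)
  print(object$plan[, c("layer", "name", "kind", "activation")],
        row.names = FALSE)
  invisible(object)
}

#' Training hyperparameters
#'
#' Defaults follow the study settings this classifier is built for:
#' momentum 0.9, learning rate 0.00006, at most 100 epochs, mini-batch
#' size 64, and validation patience 10 (training stops early after 10
#' consecutive epochs without improvement in validation loss;
#' validation is evaluated once per epoch).
#'
#' @param momentum SGD momentum coefficient.
#' @param learn_rate Learning rate.
#' @param max_epochs Maximum number of epochs.
#' @param minibatch_size Mini-batch size.
#' @param validation_patience Early-stopping patience (epochs); `Inf`
#'   disables early stopping.
#' @param seed Integer seed for shuffling, dropout and initialization
#'   order.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(momentum = 0.9, learn_rate = 0.00006,
                         max_epochs = 100, minibatch_size = 64,
                         validation_patience = 10, seed = 1) {
  structure(list(momentum = momentum, learn_rate = learn_rate,
                 max_epochs = max_epochs, minibatch_size = minibatch_size,
                 validation_patience = validation_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

# image [0,255] -> (channels x positions) input map in [-0.5, 0.5]
prepare_input <- function(img, input_dim) {
  if (inherits(img, "half_tooth")) img <- img$image
  if (!is.matrix(img) || nrow(img) != input_dim[1L] ||
      ncol(img) != input_dim[2L])
    stop(sprintf("input image must be %d x %d (got %s); standardize first",
                 input_dim[1L], input_dim[2L],
                 paste(dim(img), collapse = " x ")), call. = FALSE)
  v <- as.vector(img) / 255 - 0.5
  matrix(rep(v, input_dim[3L]), nrow = input_dim[3L], byrow = TRUE)
}

# collect images and 1-based labels (1 = negative, 2 = positive) of a split
db_split_data <- function(db, which_split) {
  if (is.null(db$split)) stop("run split_dataset() first", call. = FALSE)
  ids <- c(db$pos_meta$id, db$neg_meta$id)
  imgs <- c(db$positives, db$negatives)
  lab <- rep(c(2L, 1L), c(length(db$positives), length(db$negatives)))
  keep <- ids %in% db$split$id[db$split$split == which_split]
  list(images = imgs[keep], labels = lab[keep], ids = ids[keep])
}

zero_like_grads <- function(layers) lapply(layers, function(l)
  if (is.null(l$W)) NULL else list(W = l$W * 0, b = l$b * 0))

#' Train the classifier by mini-batch SGD with momentum
#'
#' Stochastic gradient descent with momentum on the softmax
#' cross-entropy loss. Mini-batches are drawn in random (seeded) order
#' each epoch; gradients are averaged over the batch. Validation loss
#' and accuracy are evaluated once per epoch and training stops early
#' when validation loss has not improved for
#' `config$validation_patience` consecutive epochs. The run is
#' deterministic given the seed (single-threaded BLAS assumed for
#' bitwise identity).
#'
#' @param model A `"bitewing_cnn"` from [build_alexnet()].
#' @param db A split `"finding_database"` ([split_dataset()]), or a list
#'   with elements `images` (list of matrices), `labels` (1 = negative,
#'   2 = positive) and optionally `val_images`, `val_labels`.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The trained model; `$history` holds per-epoch
#'   `train_loss`, `train_acc`, `val_loss`, `val_acc`.
#' @export
train_cnn <- function(model, db, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "bitewing_cnn"))
  if (inherits(db, "finding_database")) {
    tr <- db_split_data(db, "train")
    va <- db_split_data(db, "validation")
    model$finding <- db$finding
  } else {
    tr <- list(images = db$images, labels = db$labels)
    va <- list(images = db$val_images %||% list(),
               labels = db$val_labels %||% integer(0))
  }
  if (length(tr$images) == 0L) stop("empty training split", call. = FALSE)
  layers <- model$layers
  vel <- zero_like_grads(layers)
  trainable <- which(!vapply(vel, is.null, logical(1)))
  hist <- list()
  best_val <- Inf; bad <- 0L
  withr::with_seed(config$seed, {
    xs <- lapply(tr$images, prepare_input, input_dim = model$input_dim)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(seq_along(xs))
      ep_loss <- 0; ep_correct <- 0L
      for (b0 in seq(1L, length(ord), by = config$minibatch_size)) {
        batch <- ord[seq(b0, min(b0 + config$minibatch_size - 1L,
                                 length(ord)))]
        acc <- zero_like_grads(layers)
        for (i in batch) {
          fwd <- net_forward(layers, xs[[i]], training = TRUE)
          sx <- softmax_xent(fwd$logits, tr$labels[i])
          ep_loss <- ep_loss + sx$loss
          ep_correct <- ep_correct +
            (which.max(sx$probs) == tr$labels[i])
          g <- net_backward(layers, fwd$caches, sx$dlogits)
          for (li in trainable) {
            acc[[li]]$W <- acc[[li]]$W + g[[li]]$W
            acc[[li]]$b <- acc[[li]]$b + g[[li]]$b
          }
        }
        nb <- length(batch)
        for (li in trainable) {
          vel[[li]]$W <- config$momentum * vel[[li]]$W -
            config$learn_rate * acc[[li]]$W / nb
          vel[[li]]$b <- config$momentum * vel[[li]]$b -
            config$learn_rate * acc[[li]]$b / nb
          layers[[li]]$W <- layers[[li]]$W + vel[[li]]$W
          layers[[li]]$b <- layers[[li]]$b + vel[[li]]$b
        }
      }
      n_tr <- length(xs)
      row <- data.frame(epoch = epoch,
                        train_loss = ep_loss / n_tr,
                        train_acc = ep_correct / n_tr,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (length(va$images) > 0L) {
        vl <- 0; vc <- 0L
        for (i in seq_along(va$images)) {
          xv <- prepare_input(va$images[[i]], model$input_dim)
          fwd <- net_forward(layers, xv, training = FALSE,
                             keep_caches = FALSE)
          sx <- softmax_xent(fwd$logits, va$labels[i])
          vl <- vl + sx$loss
          vc <- vc + (which.max(sx$probs) == va$labels[i])
        }
        row$val_loss <- vl / length(va$images)
        row$val_acc <- vc / length(va$images)
      }
      hist[[epoch]] <- row
      if (verbose)
        cat(sprintf(
          "epoch %3d  train loss %.4f acc %.3f  val loss %s acc %s\n",
          epoch, row$train_loss, row$train_acc,
          formatC(row$val_loss, format = "f", digits = 4),
          formatC(row$val_acc, format = "f", digits = 3)))
      if (is.finite(row$val_loss)) {
        if (row$val_loss < best_val - 1e-10) {
          best_val <- row$val_loss; bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= config$validation_patience) break
        }
      }
    }
  })
  model$layers <- layers
  model$history <- do.call(rbind, hist)
  model$config <- config
  model
}

#' @export
#' @rdname train_cnn
#' @param x A trained `"bitewing_cnn"`.
#' @param ... Unused.
plot.bitewing_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Loss", col = "darkorange",
       ylim = range(c(h$train_loss, h$val_loss), na.rm = TRUE))
  if (any(is.finite(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, col = "black")
  plot(h$epoch, 100 * h$train_acc, type = "l", xlab = "epoch",
       ylab = "accuracy (%)", main = "Accuracy", col = "blue",
       ylim = c(0, 100))
  if (any(is.finite(h$val_acc)))
    graphics::lines(h$epoch, 100 * h$val_acc, col = "black")
  invisible(x)
}

#' Predict finding probabilities for half-tooth images
#'
#' @param object A trained `"bitewing_cnn"`.
#' @param newdata A single standardized image matrix, a `"half_tooth"`,
#'   or a list of either.
#' @param type `"prob"` for class probabilities, `"class"` for 1/2
#'   labels (1 = negative, 2 = positive).
#' @param ... Unused.
#' @return A matrix of probabilities (columns `negative`, `positive`)
#'   or an integer vector of class labels.
#' @export
predict.bitewing_cnn <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata) || inherits(newdata, "half_tooth"))
    newdata <- list(newdata)
  probs <- t(vapply(newdata, function(img) {
    x <- prepare_input(img, object$input_dim)
    softmax_probs(net_forward(object$layers, x, training = FALSE,
                              keep_caches = FALSE)$logits)
  }, numeric(object$classes)))
  colnames(probs) <- if (object$classes == 2L)
    c("negative", "positive") else NULL
  if (type == "prob") probs else max.col(probs)
}

#' Truth tables (2x2 confusion matrices)
#'
#' `truth_table()` records the four confusion counts of a binary
#' judgment and the accuracy, `(tp + tn) / total * 100` percent.
#' Printing shows both raw counts and the row-normalized percentage
#' form (each actual-class row summing to 100%).
#'
#' @param tp,fn,fp,tn Confusion counts.
#' @return An object of class `"truth_table"` with fields `tp`, `fn`,
#'   `fp`, `tn`, `total` and `accuracy` (percent).
#' @export
truth_table <- function(tp, fn, fp, tn) {
  total <- tp + fn + fp + tn
  if (total == 0L) stop("empty evaluation", call. = FALSE)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, total = total,
                 accuracy = (tp + tn) / total * 100),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  rn <- function(a, b) if (a + b == 0) c(NA, NA) else 100 * c(a, b) / (a + b)
  m <- rbind(True = rn(x$tp, x$fn), False = rn(x$fp, x$tn))
  colnames(m) <- c("True", "False")
  cat("Truth table (rows: actual, cols: predicted)\n")
  cat(sprintf("  counts: tp %d  fn %d  fp %d  tn %d\n", x$tp, x$fn, x$fp,
              x$tn))
  print(round(m, 2))
  cat(sprintf("  accuracy: %.2f%%\n", x$accuracy))
  invisible(x)
}

#' Evaluate a trained model on labeled images
#'
#' Judges each image by the argmax of the 2-way softmax and tallies the
#' counts into a [truth_table()].
#'
#' @param model A trained `"bitewing_cnn"`.
#' @param db A split `"finding_database"`, or `NULL` if `images` and
#'   `labels` are given directly.
#' @param split Which split to evaluate (default `"test"`).
#' @param images,labels Alternative direct input: list of standardized
#'   images and 1/2 labels (1 = negative, 2 = positive).
#' @return A `"truth_table"`.
#' @export
evaluate_cnn <- function(model, db = NULL, split = "test",
                         images = NULL, labels = NULL) {
  if (!is.null(db)) {
    d <- db_split_data(db, split)
    images <- d$images; labels <- d$labels
  }
  if (length(images) == 0L) stop("empty evaluation split", call. = FALSE)
  if (length(labels) != length(images) || !all(labels %in% 1:2))
    stop("labels must pair 1/2 codes with images", call. = FALSE)
  pred <- predict(model, images, type = "class")
  truth_table(tp = sum(pred == 2L & labels == 2L),
              fn = sum(pred == 1L & labels == 2L),
              fp = sum(pred == 2L & labels == 1L),
              tn = sum(pred == 1L & labels == 1L))
}

#' Per-tooth finding report from both finding models
#'
#' Runs the caries and the restoration model on one standardized
#' half-tooth image and phrases each positive finding as a percentage
#' (e.g. `"99.9% to be caries"`). A tooth may be positive for both
#' findings; if neither model reaches 50%, the verdict is normal and
#' the reported percentage is the smaller of the two negative-class
#' probabilities.
#'
#' @param model_caries,model_restoration Trained `"bitewing_cnn"`s.
#' @param half A standardized 200 x 100 image or `"half_tooth"`.
#' @return An object of class `"tooth_report"` with `caries_prob`,
#'   `restoration_prob` (positive-class probabilities), `findings`
#'   (character vector) and `text` (report lines).
#' @export
predict_tooth <- function(model_caries, model_restoration, half) {
  p_c <- predict(model_caries, half)[1L, "positive"]
  p_r <- predict(model_restoration, half)[1L, "positive"]
  findings <- c("caries", "restoration")[c(p_c >= 0.5, p_r >= 0.5)]
  text <- if (length(findings) == 0L) {
    sprintf("%.1f%% to be normal", 100 * min(1 - p_c, 1 - p_r))
  } else {
    c(if (p_c >= 0.5) sprintf("%.1f%% to be caries", 100 * p_c),
      if (p_r >= 0.5) sprintf("%.1f%% to be restorations", 100 * p_r))
  }
  structure(list(caries_prob = p_c, restoration_prob = p_r,
                 findings = findings, text = text),
            class = "tooth_report")
}

#' @export
print.tooth_report <- function(x, ...) {
  cat(paste(x$text, collapse = ""), "\n")
  invisible(x)
}
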