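# Minimal CNN engine on base-R linear algebra.
#
# Feature maps travel between layers as (channels x positions) matrices,
# positions in column-major (row-fastest) order of the (H, W) plane, so
# as.vector(t(x)) is the (row, col, channel) column-major tensor vector.
# Convolutions are im2col gathers followed by a single BLAS matmul; the
# gather/scatter index tables are precomputed per layer at build time.
# All functions here are internal; build_alexnet() assembles them.

conv_out_extent <- function(n, kernel, stride, pad)
  floor((n - kernel + 2 * pad) / stride) + 1L

nn_conv <- function(in_dim, filters, kernel, stride = 1L, pad = 0L) {
  H <- in_dim[1L]; W <- in_dim[2L]; C <- in_dim[3L]
  OH <- conv_out_extent(H, kernel, stride, pad)
  OW <- conv_out_extent(W, kernel, stride, pad)
  if (OH < 1L || OW < 1L)
    stop("convolution output extent is empty", call. = FALSE)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  k2 <- kernel * kernel
  patch_off <- rep(rep(seq_len(kernel) - 1L, times = kernel) +
                     rep(seq_len(kernel) - 1L, each = kernel) * Hp, C) +
    rep(seq_len(C) - 1L, each = k2) * (Hp * Wp)
  tl0 <- as.vector(outer((seq_len(OH) - 1L) * stride,
                         (seq_len(OW) - 1L) * stride * Hp, `+`))
  idx <- outer(patch_off, tl0, `+`) + 1L
  storage.mode(idx) <- "integer"
  pad_idx <- as.vector(outer(outer(pad + seq_len(H),
                                   (pad + seq_len(W) - 1L) * Hp, `+`),
                             (seq_len(C) - 1L) * (Hp * Wp), `+`))
  grp <- as.vector(idx)
  list(kind = "conv", in_dim = in_dim,
       out_dim = c(OH, OW, filters),
       kernel = kernel, stride = stride, pad = pad,
       idx = idx, pad_idx = pad_idx, padlen = Hp * Wp * C,
       grp = grp, ugrp = sort(unique(grp)),
       fan_in = k2 * C, filters = filters,
       W = NULL, b = NULL)
}

nn_relu <- function(in_dim) list(kind = "relu", in_dim = in_dim,
                                 out_dim = in_dim)

nn_lrn <- function(in_dim, depth = 5L, alpha = 1e-4, beta = 0.75, k = 2) {
  list(kind = "lrn", in_dim = in_dim, out_dim = in_dim,
       depth = depth, half = (depth - 1L) %/% 2L,
       alpha = alpha, beta = beta, k = k)
}

nn_maxpool <- function(in_dim, kernel = 3L, stride = 2L) {
  H <- in_dim[1L]; W <- in_dim[2L]; C <- in_dim[3L]
  OH <- conv_out_extent(H, kernel, stride, 0L)
  OW <- conv_out_extent(W, kernel, stride, 0L)
  k2 <- kernel * kernel
  patch_off <- rep(seq_len(kernel) - 1L, times = kernel) +
    rep(seq_len(kernel) - 1L, each = kernel) * H
  tl0 <- as.vector(outer((seq_len(OH) - 1L) * stride,
                         (seq_len(OW) - 1L) * stride * H, `+`))
  tl_all <- as.vector(outer(tl0, (seq_len(C) - 1L) * (H * W), `+`))
  idx <- outer(patch_off, tl_all, `+`) + 1L
  storage.mode(idx) <- "integer"
  list(kind = "maxpool", in_dim = in_dim, out_dim = c(OH, OW, C),
       kernel = kernel, stride = stride, idx = idx, k2 = k2)
}

nn_fc <- function(in_dim, out_n) {
  in_n <- prod(in_dim)
  list(kind = "fc", in_dim = in_dim, out_dim = c(1L, 1L, out_n),
       in_map = length(in_dim) == 3L && in_dim[1L] > 1L,
       in_n = in_n, out_n = out_n, fan_in = in_n, W = NULL, b = NULL)
}

nn_dropout <- function(in_dim, rate = 0.5)
  list(kind = "dropout", in_dim = in_dim, out_dim = in_dim, rate = rate)

# He-normal initialization for trainable layers
nn_init <- function(layer) {
  if (layer$kind == "conv") {
    layer$W <- matrix(stats::rnorm(layer$filters * layer$fan_in,
                                   sd = sqrt(2 / layer$fan_in)),
                      layer$filters, layer$fan_in)
    layer$b <- numeric(layer$filters)
  } else if (layer$kind == "fc") {
    layer$W <- matrix(stats::rnorm(layer$out_n * layer$in_n,
                                   sd = sqrt(2 / layer$in_n)),
                      layer$out_n, layer$in_n)
    layer$b <- numeric(layer$out_n)
  }
  layer
}

# windowed sums over the channel (row) axis, window c-half .. c+half
chan_window_sum <- function(M, half) {
  C <- nrow(M)
  CS <- M
  if (C > 1L) for (cc in 2:C) CS[cc, ] <- CS[cc - 1L, ] + M[cc, ]
  hi <- pmin(C, seq_len(C) + half)
  lo <- seq_len(C) - half - 1L
  out <- CS[hi, , drop = FALSE]
  pos <- lo >= 1L
  if (any(pos)) out[pos, ] <- out[pos, ] - CS[lo[pos], , drop = FALSE]
  out
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$kind,
    conv = {
      xp <- numeric(layer$padlen)
      xp[layer$pad_idx] <- as.vector(t(x))
      cols <- matrix(xp[layer$idx], nrow(layer$idx))
      list(y = layer$W %*% cols + layer$b, cache = list(cols = cols))
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask))
    },
    lrn = {
      s <- layer$k + (layer$alpha / layer$depth) *
        chan_window_sum(x * x, layer$half)
      sb <- s^(-layer$beta)
      list(y = x * sb, cache = list(x = x, s = s, sb = sb))
    },
    maxpool = {
      xv <- as.vector(t(x))
      cols <- matrix(xv[layer$idx], layer$k2)
      m <- cols[1L, ]; arg <- rep(1L, length(m))
      for (r in 2:layer$k2) {
        v <- cols[r, ]; u <- v > m
        m[u] <- v[u]; arg[u] <- r
      }
      P0 <- prod(layer$out_dim[1:2])
      list(y = t(matrix(m, P0, layer$in_dim[3L])),
           cache = list(arg = arg))
    },
    fc = {
      xv <- if (is.matrix(x)) as.vector(t(x)) else x
      list(y = drop(layer$W %*% xv) + layer$b, cache = list(xv = xv))
    },
    dropout = {
      if (!training) return(list(y = x, cache = list(mask = NULL)))
      mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
      list(y = x * mask, cache = list(mask = mask))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

layer_backward <- function(layer, dy, cache, need_dx = TRUE) {
  switch(layer$kind,
    conv = {
      grads <- list(W = tcrossprod(dy, cache$cols), b = rowSums(dy))
      dx <- NULL
      if (need_dx) {
        dcols <- crossprod(layer$W, dy)
        g <- rowsum(as.vector(dcols), layer$grp)
        dxp <- numeric(layer$padlen)
        dxp[layer$ugrp] <- g
        dxv <- dxp[layer$pad_idx]
        dx <- t(matrix(dxv, prod(layer$in_dim[1:2]), layer$in_dim[3L]))
      }
      list(dx = dx, grads = grads)
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    lrn = {
      inner <- chan_window_sum(dy * cache$x * cache$sb / cache$s,
                               layer$half)
      dx <- dy * cache$sb -
        (2 * layer$alpha * layer$beta / layer$depth) * cache$x * inner
      list(dx = dx, grads = NULL)
    },
    maxpool = {
      dyv <- as.vector(t(dy))
      lin <- layer$idx[cbind(cache$arg, seq_along(dyv))]
      g <- rowsum(dyv, lin)
      dxv <- numeric(prod(layer$in_dim))
      dxv[as.integer(rownames(g))] <- g
      list(dx = t(matrix(dxv, prod(layer$in_dim[1:2]), layer$in_dim[3L])),
           grads = NULL)
    },
    fc = {
      grads <- list(W = outer(dy, cache$xv), b = dy)
      dx <- NULL
      if (need_dx) {
        dxv <- drop(crossprod(layer$W, dy))
        dx <- if (layer$in_map)
          t(matrix(dxv, prod(layer$in_dim[1:2]), layer$in_dim[3L])) else dxv
      }
      list(dx = dx, grads = grads)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    }
  )
}

# forward through all layers; x is the (channels x positions) input map
net_forward <- function(layers, x, training = FALSE, keep_caches = TRUE) {
  caches <- if (keep_caches) vector("list", length(layers)) else NULL
  for (li in seq_along(layers)) {
    st <- layer_forward(layers[[li]], x, training)
    x <- st$y
    if (keep_caches) caches[[li]] <- st$cache
  }
  list(logits = x, caches = caches)
}

softmax_probs <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

# cross-entropy loss and gradient at the logits for a 1-based label
softmax_xent <- function(logits, label) {
  p <- softmax_probs(logits)
  dlogits <- p
  dlogits[label] <- dlogits[label] - 1
  list(loss = -log(max(p[label], 1e-12)), probs = p, dlogits = dlogits)
}

net_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dy <- dlogits
  for (li in rev(seq_along(layers))) {
    st <- layer_backward(layers[[li]], dy, caches[[li]], need_dx = li > 1L)
    grads[li] <- list(st$grads)  # [[<- would drop NULL entries
    dy <- st$dx
  }
  grads
}
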