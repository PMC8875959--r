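# Minimal convolutional network engine.
#
# There is no deep-learning framework in the supported stack, so the small
# CNNs used here are implemented directly: valid 3x3 convolutions via
# im2col (a precomputed sparse gather matrix per layer geometry), ReLU,
# 2x2 mean pooling (a sparse averaging matrix), and a dense softmax head.
# Backpropagation is analytic; correctness is pinned down by the
# finite-difference tests. All batch data flows as B x D matrices whose
# column order is the native R array order of an (h, w, c) image.

# im2col geometry for a valid, stride-1, k x k convolution. `gidx` maps
# patch slots to input pixels (a gather); the sparse transpose `tG` is
# kept only for the scatter in the input-gradient path.
conv_geometry <- function(h, w, cin, k, fout) {
  oh <- h - k + 1L
  ow <- w - k + 1L
  npos <- oh * ow
  ksz <- k * k * cin
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  di <- rep(seq_len(k), times = k * cin)
  dj <- rep(rep(seq_len(k), each = k), times = cin)
  ch <- rep(seq_len(cin), each = k * k)
  OI <- rep(oi, each = ksz); OJ <- rep(oj, each = ksz)
  DI <- rep(di, times = npos); DJ <- rep(dj, times = npos)
  CH <- rep(ch, times = npos)
  gidx <- (OI + DI - 1L) + (OJ + DJ - 2L) * h + (CH - 1L) * h * w
  tG <- Matrix::t(Matrix::sparseMatrix(
    i = gidx, j = seq_len(npos * ksz), x = 1,
    dims = c(h * w * cin, npos * ksz)))
  list(oh = oh, ow = ow, npos = npos, ksz = ksz, fout = fout,
       gidx = gidx, tG = tG, out_shape = c(oh, ow, fout))
}

# 2x2 mean pooling, stride 2; a trailing odd row/column is dropped.
# idx4 holds the four (disjoint) input-index vectors per output pixel.
pool_geometry <- function(h, w, cin) {
  oh <- h %/% 2L
  ow <- w %/% 2L
  oi <- rep(seq_len(oh), times = ow * cin)
  oj <- rep(rep(seq_len(ow), each = oh), times = cin)
  ch <- rep(seq_len(cin), each = oh * ow)
  idx4 <- lapply(0:3, function(q) {
    a <- q %% 2L; b <- q %/% 2L
    (2L * oi - 1L + a) + (2L * oj - 2L + b) * h + (ch - 1L) * h * w
  })
  list(idx4 = idx4, in_dim = h * w * cin,
       out_shape = c(oh, ow, cin))
}

# The architecture catalogue. Two small variants stand in for the large
# ImageNet architectures the cross-architecture comparison varies.
cnn_architectures <- function() {
  list(
    small  = list(conv_filters = c(8L), kernel = 3L),
    medium = list(conv_filters = c(8L, 16L), kernel = 3L)
  )
}

cnn_init <- function(architecture_id, input_shape, n_classes, seed = 1L) {
  archs <- cnn_architectures()
  if (!architecture_id %in% names(archs)) {
    stop("unknown architecture_id: ", architecture_id, call. = FALSE)
  }
  spec <- archs[[architecture_id]]
  h <- input_shape[1]; w <- input_shape[2]; cin <- input_shape[3]
  layers <- list()
  with_seed(seed, {
    for (f in spec$conv_filters) {
      geo <- conv_geometry(h, w, cin, spec$kernel, f)
      W <- matrix(stats::rnorm(geo$ksz * f, sd = sqrt(2 / geo$ksz)),
                  geo$ksz, f)
      layers[[length(layers) + 1L]] <- c(
        list(type = "conv", W = W, b = rep(0, f)), geo)
      layers[[length(layers) + 1L]] <- list(type = "relu")
      pg <- pool_geometry(geo$oh, geo$ow, f)
      layers[[length(layers) + 1L]] <- c(list(type = "pool"), pg)
      h <- pg$out_shape[1]; w <- pg$out_shape[2]; cin <- f
    }
    d <- h * w * cin
    layers[[length(layers) + 1L]] <- list(
      type = "dense",
      W = matrix(stats::rnorm(d * n_classes, sd = sqrt(1 / d)), d, n_classes),
      b = rep(0, n_classes))
  })
  structure(
    list(architecture_id = architecture_id,
         input_shape = as.integer(input_shape),
         n_classes = as.integer(n_classes), layers = layers),
    class = "uap_cnn")
}

# Forward pass. X is B x D. Returns logits (B x K) and, when requested,
# the per-layer cache needed by cnn_backward.
cnn_forward <- function(model, X, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    X <- switch(layer$type,
      conv = {
        P <- X[, layer$gidx, drop = FALSE]     # B x (npos*ksz) gather
        Pm <- matrix(t(P), nrow = layer$ksz)   # ksz x (npos*B)
        Z <- crossprod(layer$W, Pm) + layer$b  # fout x (npos*B)
        if (keep_cache) cache[[li]] <- Pm
        B <- nrow(P)
        A <- aperm(array(Z, dim = c(layer$fout, layer$npos, B)), c(2, 1, 3))
        t(matrix(A, nrow = layer$npos * layer$fout))
      },
      relu = {
        if (keep_cache) cache[[li]] <- X > 0
        X * (X > 0)
      },
      pool = 0.25 * (X[, layer$idx4[[1]], drop = FALSE] +
                     X[, layer$idx4[[2]], drop = FALSE] +
                     X[, layer$idx4[[3]], drop = FALSE] +
                     X[, layer$idx4[[4]], drop = FALSE]),
      dense = {
        if (keep_cache) cache[[li]] <- X
        t(t(X %*% layer$W) + layer$b)
      })
  }
  list(logits = X, cache = cache)
}

# Backward pass from dlogits (B x K). Returns the parameter gradients
# (indexed like model$layers) and, when `need_input`, the gradient
# w.r.t. the input batch (training skips it; the attack loop needs it).
cnn_backward <- function(model, cache, dlogits, need_input = TRUE) {
  grads <- vector("list", length(model$layers))
  dY <- dlogits
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    dY <- switch(layer$type,
      dense = {
        Xin <- cache[[li]]
        grads[[li]] <- list(dW = crossprod(Xin, dY), db = colSums(dY))
        tcrossprod(dY, layer$W)
      },
      pool = {
        B <- nrow(dY)
        dX <- matrix(0, B, layer$in_dim)
        q <- 0.25 * dY
        for (m in 1:4) dX[, layer$idx4[[m]]] <- q
        dX
      },
      relu = dY * cache[[li]],
      conv = {
        B <- nrow(dY)
        A <- aperm(array(t(dY), dim = c(layer$npos, layer$fout, B)),
                   c(2, 1, 3))
        dZm <- matrix(A, nrow = layer$fout)        # fout x (npos*B)
        Pm <- cache[[li]]
        grads[[li]] <- list(dW = tcrossprod(Pm, dZm), db = rowSums(dZm))
        if (li == 1L && !need_input) {
          NULL # innermost layer; input gradient not requested
        } else {
          dPm <- layer$W %*% dZm                   # ksz x (npos*B)
          dP <- t(matrix(dPm, nrow = layer$ksz * layer$npos))
          as.matrix(dP %*% layer$tG)               # scatter-accumulate
        }
      })
  }
  list(grads = grads, dinput = dY)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy over a batch and its logit gradient.
ce_loss_grad <- function(logits, y0) {
  B <- nrow(logits)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(B), y0 + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B)
}

# One SGD-with-momentum training run over a labelled matrix dataset.
# Deterministic given the seed (single-threaded, fixed shuffling).
cnn_sgd <- function(model, X, y0, epochs, batch_size, lr,
                    momentum = 0.9, lr_decay = 0.5, decay_every = NULL,
                    augment = NULL, seed = 1L, max_updates = NULL,
                    lr_scale = NULL) {
  n <- nrow(X)
  updates <- 0L
  if (is.null(lr_scale)) lr_scale <- rep(1, length(model$layers))
  if (n < 1L || batch_size < 1L) stop("empty data or batch", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (is.null(decay_every)) decay_every <- max(1L, ceiling(epochs / 3))
  vel <- lapply(model$layers, function(l) {
    if (!is.null(l$W)) list(vW = l$W * 0, vb = l$b * 0)
  })
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      rate <- lr * lr_decay^((ep - 1L) %/% decay_every)
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        if (!is.null(max_updates) && updates >= max_updates) break
        updates <- updates + 1L
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        if (!is.null(augment)) Xb <- augment(Xb)
        fwd <- cnn_forward(model, Xb, keep_cache = TRUE)
        lg <- ce_loss_grad(fwd$logits, y0[idx])
        bwd <- cnn_backward(model, fwd$cache, lg$dlogits,
                            need_input = FALSE)
        for (li in seq_along(model$layers)) {
          g <- bwd$grads[[li]]
          if (is.null(g)) next
          vel[[li]]$vW <- momentum * vel[[li]]$vW -
            rate * lr_scale[li] * as.matrix(g$dW)
          vel[[li]]$vb <- momentum * vel[[li]]$vb -
            rate * lr_scale[li] * g$db
          model$layers[[li]]$W <- model$layers[[li]]$W + vel[[li]]$vW
          model$layers[[li]]$b <- model$layers[[li]]$b + vel[[li]]$vb
        }
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      losses[ep] <- if (nb > 0L) ep_loss / nb else NA_real_
    }
  })
  attr(model, "train_losses") <- losses
  model
}

# Random horizontal flips and small circular shifts, applied per batch.
make_augmenter <- function(shape, flip = TRUE, shift_max = 2L) {
  h <- shape[1]; w <- shape[2]; cc <- shape[3]
  function(Xb) {
    B <- nrow(Xb)
    A <- array(t(Xb), dim = c(h, w, cc, B))
    for (i in seq_len(B)) {
      if (flip && stats::runif(1) < 0.5) {
        A[, , , i] <- A[, w:1, , i, drop = FALSE]
      }
      if (shift_max > 0L) {
        dy <- sample(-shift_max:shift_max, 1L)
        dx <- sample(-shift_max:shift_max, 1L)
        if (dy != 0L) A[, , , i] <-
            A[((seq_len(h) - 1L - dy) %% h) + 1L, , , i, drop = FALSE]
        if (dx != 0L) A[, , , i] <-
            A[, ((seq_len(w) - 1L - dx) %% w) + 1L, , i, drop = FALSE]
      }
    }
    t(matrix(A, nrow = h * w * cc))
  }
}
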