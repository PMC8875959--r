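#' Training configuration
#'
#' Hyperparameters for the two training regimes the package contrasts:
#' `transfer` (fine-tuning a source-pool-pretrained backbone, default
#' learning rate 0.01 so the pretrained features move little) and
#' `scratch` (random initialization, trained for
#' `epochs * epochs_scratch_multiplier` epochs — the multiplier-of-6
#' convention — at the full learning rate). The schedule is step decay:
#' the rate is multiplied by `lr_decay` every `decay_every` epochs
#' (default: a third of the run).
#'
#' @param epochs base number of epochs (the transfer-learning count).
#' @param epochs_scratch_multiplier factor applied to `epochs` when
#'   training from scratch; default 6.
#' @param batch_size minibatch size.
#' @param lr initial learning rate; defaults to 0.01 for `transfer`,
#'   0.05 otherwise.
#' @param lr_decay multiplicative step-decay factor.
#' @param decay_every epochs between decays (default `ceiling(epochs/3)`).
#' @param momentum SGD momentum.
#' @param augmentation logical: random horizontal flips and small
#'   circular shifts during training.
#' @param seed seed controlling initialization and shuffling; training is
#'   deterministic given the seed (pure R, single-threaded).
#' @param init_mode `"transfer"` or `"scratch"`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 8L, epochs_scratch_multiplier = 6L,
                         batch_size = 32L, lr = NULL, lr_decay = 0.5,
                         decay_every = NULL, momentum = 0.9,
                         augmentation = FALSE, seed = 1L,
                         init_mode = c("transfer", "scratch")) {
  init_mode <- match.arg(init_mode)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (is.null(lr)) lr <- if (init_mode == "transfer") 0.01 else 0.02
  structure(
    list(epochs = as.integer(epochs),
         epochs_scratch_multiplier = as.integer(epochs_scratch_multiplier),
         batch_size = as.integer(batch_size), lr = lr, lr_decay = lr_decay,
         decay_every = decay_every, momentum = momentum,
         augmentation = isTRUE(augmentation), seed = as.integer(seed),
         init_mode = init_mode),
    class = "train_config")
}

new_handle <- function(net, architecture_id, init_mode, config,
                       class_names = NULL, test_accuracy = NA_real_,
                       subclass = "cnn_classifier") {
  structure(
    list(net = net, n_classes = net$n_classes,
         input_shape = net$input_shape, architecture_id = architecture_id,
         init_mode = init_mode, config_echo = config,
         class_names = class_names, test_accuracy = test_accuracy),
    class = c(subclass, "uap_classifier"))
}

#' @export
print.uap_classifier <- function(x, ...) {
  cat(sprintf("<%s> arch=%s K=%d input=%s init=%s%s\n",
              class(x)[1], x$architecture_id, x$n_classes,
              paste(x$input_shape, collapse = "x"), x$init_mode,
              if (is.finite(x$test_accuracy))
                sprintf(" test_acc=%.3f", x$test_accuracy) else ""))
  invisible(x)
}

run_sgd <- function(net, train_set, y0, config, epochs, lr,
                    max_updates = NULL, lr_scale = NULL) {
  X <- as_matrix(train_set)
  if (nrow(X) < config$batch_size) {
    stop("dataset smaller than one batch (", nrow(X), " < ",
         config$batch_size, ")", call. = FALSE)
  }
  augment <- if (config$augmentation) {
    make_augmenter(image_shape(train_set))
  }
  cnn_sgd(net, X, y0, epochs = epochs, batch_size = config$batch_size,
          lr = lr, momentum = config$momentum, lr_decay = config$lr_decay,
          decay_every = config$decay_every, augment = augment,
          seed = config$seed, max_updates = max_updates,
          lr_scale = lr_scale)
}

#' Pretrain a backbone on the source pool
#'
#' The surrogate pretraining task classifies pool images by the texture
#' family that generated them (the `surrogate_labels` attribute emitted by
#' [generate_source_pool()]), standing in for supervised pretraining on a
#' large natural-image corpus: the convolutional features it learns are
#' features of the source domain, which is exactly the structure
#' transfer-learning vulnerability requires.
#'
#' @param pool an unlabelled [image_set()] carrying `surrogate_labels`.
#' @param config a [train_config()].
#' @param architecture_id `"small"` or `"medium"`.
#' @return a classifier handle over the surrogate classes (a backbone;
#'   pass it to [finetune()]).
#' @export
pretrain_backbone <- function(pool, config = train_config(init_mode = "scratch"),
                              architecture_id = "small") {
  stopifnot(inherits(pool, "image_set"))
  sur <- attr(pool, "surrogate_labels")
  if (is.null(sur)) {
    stop("pool carries no surrogate labels; use generate_source_pool()",
         call. = FALSE)
  }
  net <- cnn_init(architecture_id, image_shape(pool),
                  n_classes = max(sur) + 1L, seed = config$seed)
  net <- run_sgd(net, pool, sur, config, epochs = config$epochs,
                 lr = config$lr)
  new_handle(net, architecture_id, init_mode = "pretrained", config)
}

# Replace the dense head with a freshly initialized K-class head.
replace_head <- function(net, n_classes, seed) {
  li <- length(net$layers)
  stopifnot(net$layers[[li]]$type == "dense")
  d <- nrow(net$layers[[li]]$W)
  with_seed(seed, {
    net$layers[[li]]$W <- matrix(stats::rnorm(d * n_classes,
                                              sd = sqrt(1 / d)),
                                 d, n_classes)
  })
  net$layers[[li]]$b <- rep(0, n_classes)
  net$n_classes <- as.integer(n_classes)
  net
}

#' Fine-tune a pretrained backbone on the target dataset
#'
#' Replaces the classification head for the K target classes and trains
#' all layers at the (low) transfer learning rate for `config$epochs`
#' epochs. The result carries `init_mode = "transfer"`.
#'
#' @param backbone handle returned by [pretrain_backbone()].
#' @param train labelled target-domain [image_set()].
#' @param config a [train_config()] with `init_mode = "transfer"`.
#' @param test optional labelled [image_set()]; when given, test accuracy
#'   is computed and stored on the handle.
#' @param max_updates optional cap on the number of SGD updates (0 gives
#'   the backbone-with-new-head baseline; used by tests).
#' @return a classifier handle with `init_mode = "transfer"`.
#' @export
finetune <- function(backbone, train, config = train_config(),
                     test = NULL, max_updates = NULL) {
  stopifnot(inherits(backbone, "cnn_classifier"), inherits(train, "image_set"))
  if (!identical(as.integer(image_shape(train)), backbone$input_shape)) {
    stop("training images do not match the backbone input shape",
         call. = FALSE)
  }
  if (is.null(train$labels)) stop("training set must be labelled",
                                  call. = FALSE)
  k <- length(train$class_names)
  net <- replace_head(backbone$net, k, seed = config$seed)
  # pretrained features move at the (low) transfer rate; the freshly
  # initialized head trains 5x faster, the usual fine-tuning split
  lr_scale <- rep(1, length(net$layers))
  lr_scale[length(net$layers)] <- 5
  net <- run_sgd(net, train, train$labels, config,
                 epochs = config$epochs, lr = config$lr,
                 max_updates = max_updates, lr_scale = lr_scale)
  h <- new_handle(net, backbone$architecture_id, init_mode = "transfer",
                  config, class_names = train$class_names)
  if (!is.null(test)) h$test_accuracy <- accuracy(h, test)
  h
}

#' Train a classifier from random initialization
#'
#' The scratch regime of the transfer-vs-scratch contrast: no pretrained
#' weights, `epochs * epochs_scratch_multiplier` epochs (default 6x, the
#' convention that scratch training needs far more epochs to converge).
#'
#' @param train labelled target-domain [image_set()].
#' @param config a [train_config()] (its `init_mode` is forced to
#'   `"scratch"`).
#' @param architecture_id `"small"` or `"medium"`.
#' @param test optional test [image_set()] for the accuracy field.
#' @return a classifier handle with `init_mode = "scratch"`; its
#'   `config_echo$effective_epochs` records the multiplied epoch count.
#' @export
train_scratch <- function(train, config = train_config(init_mode = "scratch"),
                          architecture_id = "small", test = NULL) {
  stopifnot(inherits(train, "image_set"))
  if (is.null(train$labels)) stop("training set must be labelled",
                                  call. = FALSE)
  config$init_mode <- "scratch"
  eff <- config$epochs * config$epochs_scratch_multiplier
  config$effective_epochs <- eff
  net <- cnn_init(architecture_id, image_shape(train),
                  n_classes = length(train$class_names), seed = config$seed)
  net <- run_sgd(net, train, train$labels, config, epochs = eff,
                 lr = config$lr)
  h <- new_handle(net, architecture_id, init_mode = "scratch", config,
                  class_names = train$class_names)
  if (!is.null(test)) h$test_accuracy <- accuracy(h, test)
  h
}

#' A plain linear softmax classifier
#'
#' A hand-specifiable classifier satisfying the same prediction and
#' gradient contract as the trained CNNs. Used as the analytic oracle in
#' tests (its loss gradient has the closed form
#' `W (softmax(Wx + b) - onehot(y))`) and handy for didactic examples.
#'
#' @param W weight matrix, `D x K` (`D` = prod of `input_shape`).
#' @param b bias vector of length `K`.
#' @param input_shape integer `c(h, w, c)`; defaults to `c(D, 1, 1)`.
#' @return a classifier handle of class `linear_classifier`.
#' @export
linear_classifier <- function(W, b = rep(0, ncol(W)), input_shape = NULL) {
  W <- as.matrix(W)
  if (is.null(input_shape)) input_shape <- c(nrow(W), 1L, 1L)
  stopifnot(prod(input_shape) == nrow(W), length(b) == ncol(W))
  net <- list(W = W, b = b, n_classes = ncol(W),
              input_shape = as.integer(input_shape))
  new_handle(net, architecture_id = "linear", init_mode = "fixed",
             config = NULL, subclass = "linear_classifier")
}

# Internal: class scores (logits) for a B x D matrix.
class_scores <- function(clf, X) UseMethod("class_scores")

#' @export
class_scores.cnn_classifier <- function(clf, X) {
  cnn_forward(clf$net, X)$logits
}

#' @export
class_scores.linear_classifier <- function(clf, X) {
  t(t(X %*% clf$net$W) + clf$net$b)
}

coerce_batch <- function(clf, images) {
  if (inherits(images, "image_set")) {
    if (!identical(as.integer(image_shape(images)), clf$input_shape)) {
      stop("image shape does not match the classifier input shape",
           call. = FALSE)
    }
    return(as_matrix(images))
  }
  if (is.matrix(images)) {
    if (ncol(images) != prod(clf$input_shape)) {
      stop("matrix width does not match the classifier input size",
           call. = FALSE)
    }
    return(images)
  }
  if (is.array(images) && length(dim(images)) == 3L) {
    if (!identical(as.integer(dim(images)), clf$input_shape)) {
      stop("image shape does not match the classifier input shape",
           call. = FALSE)
    }
    return(matrix(as.vector(images), nrow = 1L))
  }
  if (is.array(images) && length(dim(images)) == 4L) {
    return(coerce_batch(clf, image_set(images)))
  }
  stop("cannot interpret `images` as image data", call. = FALSE)
}

#' Predict class indices
#'
#' Argmax over class scores, ties broken towards the lowest class index.
#' Deterministic in evaluation mode (the networks have no stochastic
#' layers), and invariant to how the input is batched.
#'
#' @param object a classifier handle.
#' @param images an [image_set()], an `n x h x w x c` array, a single
#'   `h x w x c` image, or a pre-flattened `n x D` matrix.
#' @param batch_size internal evaluation batch size.
#' @param ... unused.
#' @return integer vector of 0-based class indices.
#' @export
predict.uap_classifier <- function(object, images, batch_size = 256L, ...) {
  X <- coerce_batch(object, images)
  n <- nrow(X)
  out <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    s <- class_scores(object, X[idx, , drop = FALSE])
    out[idx] <- max.col(s, ties.method = "first") - 1L
  }
  out
}

#' Classification accuracy on a labelled image set
#' @param clf a classifier handle.
#' @param data a labelled [image_set()].
#' @return fraction of correct predictions.
#' @export
accuracy <- function(clf, data) {
  stopifnot(inherits(data, "image_set"), !is.null(data$labels))
  mean(predict(clf, data) == data$labels)
}

#' Gradient of the classification loss w.r.t. the input image
#'
#' Returns the input gradient of the cross-entropy loss evaluated at
#' `(image, label)`. For a non-targeted attack the caller passes the
#' image's current predicted class and ascends this gradient (increasing
#' the loss of the prediction); for a targeted attack the caller passes
#' the target class and descends it. The gradient always has exactly the
#' input's shape; a non-finite gradient raises an error rather than being
#' silently zeroed.
#'
#' @param clf a classifier handle.
#' @param image a single `h x w x c` array (or plain vector of length D).
#' @param label 0-based class index the loss is evaluated against.
#' @param mode `"nontargeted"` or `"targeted"` (documentation of intent;
#'   the returned quantity is the loss gradient at `(image, label)` in
#'   both cases — the sign convention lives in [fgsm_step()]).
#' @return numeric array with the input's shape.
#' @export
loss_gradient <- function(clf, image, label,
                          mode = c("nontargeted", "targeted")) {
  match.arg(mode)
  UseMethod("loss_gradient")
}

finish_gradient <- function(g, image) {
  if (any(!is.finite(g))) {
    stop("non-finite loss gradient encountered", call. = FALSE)
  }
  if (is.array(image)) array(g, dim = dim(image)) else as.numeric(g)
}

check_label <- function(clf, label) {
  label <- as.integer(label)
  if (label < 0L || label >= clf$n_classes) {
    stop("label must be in [0, K)", call. = FALSE)
  }
  label
}

#' @export
loss_gradient.cnn_classifier <- function(clf, image, label,
                                         mode = c("nontargeted", "targeted")) {
  label <- check_label(clf, label)
  x <- matrix(if (is.array(image)) as.vector(image) else image, nrow = 1L)
  fwd <- cnn_forward(clf$net, x, keep_cache = TRUE)
  lg <- ce_loss_grad(fwd$logits, label)
  g <- cnn_backward(clf$net, fwd$cache, lg$dlogits)$dinput
  finish_gradient(g, image)
}

#' @export
loss_gradient.linear_classifier <- function(clf, image, label,
                                            mode = c("nontargeted", "targeted")) {
  label <- check_label(clf, label)
  x <- if (is.array(image)) as.vector(image) else as.numeric(image)
  p <- softmax_rows(matrix(x %*% clf$net$W + clf$net$b, nrow = 1L))[1, ]
  p[label + 1L] <- p[label + 1L] - 1
  finish_gradient(clf$net$W %*% p, image)
}

#' Persist a classifier handle
#'
#' Writes the handle as RDS with a JSON sidecar recording architecture,
#' init mode, config echo and test accuracy.
#'
#' @param clf a classifier handle.
#' @param path output RDS path; the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "uap_classifier"))
  saveRDS(clf, path)
  side <- list(architecture_id = clf$architecture_id,
               init_mode = clf$init_mode, n_classes = clf$n_classes,
               input_shape = clf$input_shape,
               test_accuracy = clf$test_accuracy,
               config = clf$config_echo[!vapply(clf$config_echo, is.null,
                                                logical(1))])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "uap_classifier"))
  x
}
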