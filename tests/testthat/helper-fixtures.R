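# Shared fixtures, memoised so expensive objects (trained models, the
# acceptance experiment tables) are built once per test run.

fixture <- local({
  env <- new.env(parent = emptyenv())
  function(name, expr) {
    if (!exists(name, envir = env, inherits = FALSE)) {
      assign(name, force(expr), envir = env)
    }
    get(name, envir = env, inherits = FALSE)
  }
})

# The shared unit-test world: default geometry (32 px) but a smaller
# test split, trained briefly; built once and memoised.
tiny_spec <- function(seed = 11L) {
  domain_spec(n_classes = 4L, n_images = 400L, n_test = 100L,
              image_size = 32L, seed = seed)
}

tiny_world <- function() {
  fixture("tiny_world", {
    spec <- tiny_spec()
    data <- generate_target_dataset(spec)
    pool <- generate_source_pool(spec)
    list(spec = spec, data = data, pool = pool)
  })
}

# A quickly trained CNN on the tiny world.
tiny_model <- function() {
  fixture("tiny_model", {
    w <- tiny_world()
    train_scratch(w$data$train,
                  train_config(epochs = 2L, init_mode = "scratch",
                               seed = 5L),
                  architecture_id = "small", test = w$data$test)
  })
}

tiny_backbone <- function() {
  fixture("tiny_backbone", {
    pretrain_backbone(tiny_world()$pool,
                      train_config(epochs = 2L, init_mode = "scratch",
                                   seed = 5L),
                      architecture_id = "small")
  })
}

# Hand-specified two-class linear model on 1x2x1 images: logit margin is
# w . x + b with w = W[,2] - W[,1]. Used as the analytic attack oracle.
linear_fixture <- function(W = matrix(c(1, 0, 0, 1), 2, 2), b = c(0, 0)) {
  linear_classifier(W, b, input_shape = c(1L, 2L, 1L))
}

# Build an image_set from a plain matrix of rows (n x D) on a 1 x D grid.
rowset <- function(X, labels = NULL, k = NULL) {
  n <- nrow(X); d <- ncol(X)
  arr <- array(0, dim = c(n, 1L, d, 1L))
  for (i in seq_len(n)) arr[i, 1L, , 1L] <- X[i, ]
  image_set(arr, labels = labels,
            class_names = if (!is.null(k)) paste0("c", seq_len(k) - 1L),
            domain_tag = "target")
}

# Closed-form input gradient of the cross-entropy loss for a linear
# softmax model (the independent oracle for gradient/attack tests).
linear_ce_grad <- function(W, b, x, label0) {
  z <- as.vector(x %*% W + b)
  p <- exp(z - max(z)); p <- p / sum(p)
  p[label0 + 1L] <- p[label0 + 1L] - 1
  as.vector(W %*% p)
}
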