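test_that("train_config validates and applies the scratch multiplier", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(batch_size = 0), "batch_size")
  cfg <- train_config(epochs = 2L, init_mode = "scratch")
  expect_equal(cfg$lr, 0.02)
  w <- tiny_world()
  clf <- train_scratch(w$data$train, cfg, "small")
  expect_equal(clf$config_echo$effective_epochs,
               2L * cfg$epochs_scratch_multiplier)
  expect_identical(clf$init_mode, "scratch")
})

test_that("training is deterministic given the seed", {
  w <- tiny_world()
  cfg <- train_config(epochs = 1L, init_mode = "scratch", seed = 9L)
  a <- train_scratch(w$data$train, cfg, "small")
  b <- train_scratch(w$data$train, cfg, "small")
  probe <- w$data$test[1:20]
  expect_identical(predict(a, probe), predict(b, probe))
  expect_identical(a$net$layers[[1]]$W, b$net$layers[[1]]$W)
})

test_that("pretraining learns the surrogate task above chance", {
  w <- tiny_world()
  backbone <- tiny_backbone()
  sur <- attr(w$pool, "surrogate_labels")
  acc <- mean(predict(backbone, w$pool) == sur)
  expect_gt(acc, 1 / (max(sur) + 1L))
  # pool smaller than one batch is a configuration error
  expect_error(
    pretrain_backbone(w$pool[1:8],
                      train_config(epochs = 1L, batch_size = 32L)),
    "batch")
  # a pool without surrogate labels is rejected
  expect_error(pretrain_backbone(w$data$test[1:40],
                                 train_config(epochs = 1L)),
               "surrogate")
})

test_that("finetune replaces the head and respects shape contracts", {
  w <- tiny_world()
  backbone <- tiny_backbone()
  clf <- finetune(backbone, w$data$train,
                  train_config(epochs = 1L, seed = 5L),
                  test = w$data$test)
  expect_identical(clf$init_mode, "transfer")
  expect_equal(clf$n_classes, 4L)
  expect_true(is.finite(clf$test_accuracy))

  # zero training steps leave the backbone-with-new-head baseline intact
  base <- finetune(backbone, w$data$train,
                   train_config(epochs = 1L, seed = 5L), max_updates = 0L)
  head_only <- uapsim:::replace_head(backbone$net, 4L, seed = 5L)
  probe <- as_matrix(w$data$test[1:10])
  expect_equal(uapsim:::cnn_forward(base$net, probe)$logits,
               uapsim:::cnn_forward(head_only, probe)$logits)

  # incompatible image shape is an input error
  big <- generate_target_dataset(domain_spec(n_images = 8L, n_test = 4L,
                                             image_size = 20L,
                                             n_classes = 4L, seed = 1L))
  expect_error(finetune(backbone, big$train, train_config(epochs = 1L)),
               "shape")
})

test_that("prediction breaks ties towards the lowest class and is
          batching invariant", {
  # constant-score degenerate head: all logits equal
  degenerate <- linear_classifier(matrix(0, 4, 3), c(0, 0, 0),
                                  input_shape = c(2L, 2L, 1L))
  X <- matrix(runif(20), 5, 4)
  expect_true(all(predict(degenerate, X) == 0L))

  clf <- tiny_model()
  w <- tiny_world()
  batched <- predict(clf, w$data$test)
  onebyone <- vapply(seq_len(length(w$data$test)), function(i) {
    predict(clf, w$data$test[i])
  }, integer(1))
  expect_identical(batched, onebyone)
  expect_true(all(batched >= 0L & batched < 4L))
})

test_that("a hand-built linear model flips exactly at the margin", {
  # two-class model, margin = w.x + b2 - b1 with w = W[,2] - W[,1]
  W <- matrix(c(1, -1, 2, 1), 2, 2) # w = c(1, 2)
  b <- c(0.5, 0)                    # flips when x1 + 2 x2 = 0.5
  clf <- linear_classifier(W, b, input_shape = c(1L, 2L, 1L))
  below <- matrix(c(0.1, 0.1), 1) # margin -0.2 -> class 0
  above <- matrix(c(0.3, 0.2), 1) # margin +0.2 -> class 1
  expect_equal(predict(clf, below), 0L)
  expect_equal(predict(clf, above), 1L)
})

test_that("loss gradients match closed form and finite differences", {
  # linear model: closed form W (softmax - onehot)
  set.seed(42)
  W <- matrix(rnorm(8), 4, 2)
  b <- c(0.1, -0.2)
  clf <- linear_classifier(W, b, input_shape = c(2L, 2L, 1L))
  x <- array(runif(4), dim = c(2, 2, 1))
  g <- loss_gradient(clf, x, 1L)
  expect_equal(dim(g), dim(x))
  expect_equal(as.vector(g),
               linear_ce_grad(W, b, as.vector(x), 1L), tolerance = 1e-12)

  # CNN gradient vs central finite differences along random directions
  clf2 <- tiny_model()
  w <- tiny_world()
  x2 <- array(w$data$test$images[3, , , ], dim = c(32, 32, 1))
  g2 <- loss_gradient(clf2, x2, 2L)
  expect_equal(dim(g2), dim(x2))
  lossfn <- function(v) {
    lg <- uapsim:::ce_loss_grad(
      uapsim:::cnn_forward(clf2$net, matrix(v, nrow = 1))$logits, 2L)
    lg$loss
  }
  set.seed(7)
  h <- 1e-4
  for (rep in 1:5) {
    d <- rnorm(length(x2)); d <- d / sqrt(sum(d^2))
    fd <- (lossfn(as.vector(x2) + h * d) -
             lossfn(as.vector(x2) - h * d)) / (2 * h)
    an <- sum(as.vector(g2) * d)
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
  }

  # non-finite gradients surface as errors, never silently zeroed
  bad <- linear_classifier(matrix(c(Inf, 0, 0, 1), 2, 2))
  expect_error(loss_gradient(bad, c(0.5, 0.5), 0L), "non-finite")
  expect_error(loss_gradient(clf, x, 5L), "label")
})

test_that("classifier handles round-trip through persistence", {
  clf <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  write_classifier(clf, path)
  back <- read_classifier(path)
  w <- tiny_world()
  expect_identical(predict(back, w$data$test[1:10]),
                   predict(clf, w$data$test[1:10]))
})
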