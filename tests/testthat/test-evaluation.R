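# A hand-enumerable fixture: two-pixel images under a two-class linear
# model with identity-like weights; predictions depend only on which
# pixel is larger, so every clean/adversarial prediction below is
# computed by hand.
hand_model <- function() linear_fixture(W = matrix(c(1, -1, -1, 1), 2, 2))

test_that("fooling rate matches hand enumeration and its edge cases", {
  clf <- hand_model()
  # clean predictions: x1 > x2 -> class 0; images 2 and 4 sit close to
  # the boundary so the chosen rho flips exactly those two
  X <- rowset(rbind(c(0.9, 0.1),   # clean class 0, wide margin
                    c(0.55, 0.45), # clean class 0
                    c(0.1, 0.9),   # clean class 1, wide margin
                    c(0.45, 0.55)))# clean class 1, thin margin
  # rho = (+0.15, -0.15) pushes towards class 0; hand enumeration:
  # img1 (1, 0) -> 0; img2 (0.7, 0.3) -> 0; img3 (0.25, 0.75) -> 1;
  # img4 (0.6, 0.4) -> 0 (flipped). Rf = 1/4.
  pert <- perturbation(array(c(0.15, -0.15), dim = c(1, 2, 1)),
                       p = Inf, xi = 0.15, source_tag = "random")
  expect_equal(fooling_rate(clf, X, pert), 0.25)

  # zero perturbation: Rf exactly 0
  zero <- perturbation(array(0, dim = c(1, 2, 1)), p = Inf, xi = 0.1,
                       source_tag = "random")
  expect_identical(fooling_rate(clf, X, zero), 0)

  # saturating perturbation: (-0.5, +0.5) flips both class-0 images
  flip_all <- perturbation(array(c(-0.5, 0.5), dim = c(1, 2, 1)),
                           p = Inf, xi = 0.5, source_tag = "random")
  Xsym <- rowset(rbind(c(0.8, 0.2), c(0.7, 0.3)))
  expect_equal(fooling_rate(clf, Xsym, flip_all), 1)
})

test_that("success rate reduces to its baseline at rho = 0", {
  clf <- hand_model()
  X <- rowset(rbind(c(0.9, 0.1), c(0.55, 0.45), c(0.1, 0.9),
                    c(0.45, 0.55)))
  zero <- perturbation(array(0, dim = c(1, 2, 1)), p = Inf, xi = 0.1,
                       source_tag = "random")
  s <- success_rate(clf, X, zero, 1L)
  expect_identical(s$rate, s$baseline)
  expect_equal(s$baseline, 0.5) # images 3 and 4 are class 1
  # all-adversarial-to-target saturation
  drive1 <- perturbation(array(c(-0.5, 0.5), dim = c(1, 2, 1)),
                         p = Inf, xi = 0.5, source_tag = "random")
  expect_equal(success_rate(clf, X, drive1, 1L)$rate, 1)
  expect_error(success_rate(clf, X, zero, 7L), "y")
})

test_that("confusion matrices reproduce a hand enumeration", {
  clf <- hand_model()
  zero <- perturbation(array(0, dim = c(1, 2, 1)), p = Inf, xi = 0.1,
                       source_tag = "random")
  X <- rowset(rbind(c(0.9, 0.1), c(0.55, 0.45), c(0.1, 0.9),
                    c(0.45, 0.55)))
  cm0 <- confusion_matrices(clf, X, zero)
  expect_equal(unname(cm0$counts), diag(c(2L, 2L)))
  expect_equal(unname(cm0$row_normalized), diag(2))

  # drive everything into class 0: single-column mass, dominant class 0
  drive0 <- perturbation(array(c(0.5, -0.5), dim = c(1, 2, 1)),
                         p = Inf, xi = 0.5, source_tag = "random")
  cm <- confusion_matrices(clf, X, drive0)
  expect_equal(unname(colSums(cm$counts)), c(4L, 0L))
  expect_equal(cm$dominant_class, 0L)

  # six-image, three-class hand fixture: predictions are the argmax
  # coordinate, so clean/adversarial classes are read off directly
  W3 <- diag(3)
  clf3 <- linear_classifier(W3, input_shape = c(1L, 3L, 1L))
  X3 <- rowset(rbind(c(0.9, 0.1, 0.0),  # clean 0
                     c(0.8, 0.0, 0.1),  # clean 0
                     c(0.0, 0.9, 0.1),  # clean 1
                     c(0.1, 0.6, 0.3),  # clean 1
                     c(0.0, 0.1, 0.9),  # clean 2
                     c(0.2, 0.0, 0.8))) # clean 2
  # rho boosts coordinate 2 by 0.85; adversarial predictions by hand:
  # img1 (0.9,0.95,0) -> 1; img2 (0.8,0.85,0.1) -> 1; img3 -> 1;
  # img4 -> 1; img5 (0,0.95,0.9) -> 1; img6 (0.2,0.85,0.8) -> 1
  rho3 <- array(c(0, 0.85, 0), dim = c(1, 3, 1))
  p3 <- perturbation(rho3, p = Inf, xi = 0.85, source_tag = "random")
  cm3 <- confusion_matrices(clf3, X3, p3)
  expected <- matrix(0L, 3, 3)
  expected[, 2] <- c(2L, 2L, 2L)
  expect_equal(unname(cm3$counts), expected)
  expect_equal(cm3$dominant_class, 1L)
  # zero-count rows normalize to zero, populated rows sum to one
  rs <- rowSums(cm3$row_normalized)
  expect_equal(unname(rs), c(1, 1, 1))
  cm_sub <- confusion_matrices(clf3, X3[3:4], p3) # only clean class 1
  expect_equal(unname(rowSums(cm_sub$row_normalized)), c(0, 1, 0))
})

test_that("metric identities hold on a trained model", {
  clf <- tiny_model()
  w <- tiny_world()
  X <- w$data$test
  u <- random_uap(image_shape(X), xi = 0.3, p = Inf, seed = 12L)
  rep <- evaluate_uap(clf, X, u, target_class = 2L)
  # Rf from confusion counts equals the direct Rf to 1e-12
  expect_equal(rep$r_f,
               1 - sum(diag(rep$confusion_counts)) /
                 sum(rep$confusion_counts),
               tolerance = 1e-12)
  expect_equal(sum(rep$confusion_counts), rep$n_images)
  nz <- rowSums(rep$confusion_counts) > 0
  expect_equal(unname(rowSums(rep$confusion)[nz]),
               rep(1, sum(nz)), tolerance = 1e-9)
  expect_true(all(rowSums(rep$confusion)[!nz] == 0))
  # Rs baseline equals the clean composition's target entry
  comp <- label_composition(clf, X)
  expect_identical(rep$r_s_baseline, unname(comp[3]))
  # metrics are invariant to the ordering of X
  perm <- sample(length(X))
  expect_equal(fooling_rate(clf, X[perm], u), rep$r_f)
  expect_equal(success_rate(clf, X[perm], u, 2L)$rate, rep$r_s)
})

test_that("label_composition is a probability vector with sane extremes", {
  clf <- tiny_model()
  w <- tiny_world()
  comp <- label_composition(clf, w$pool)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_true(all(comp >= 0))
  # constant-output classifier: one-hot composition
  const <- linear_classifier(matrix(0, 4, 3), c(5, 0, 0),
                             input_shape = c(2L, 2L, 1L))
  imgs <- array(runif(4 * 16), dim = c(16, 2, 2, 1))
  comp0 <- label_composition(const, image_set(imgs))
  expect_equal(unname(comp0), c(1, 0, 0))
})

test_that("evaluation reports persist to JSON and CSV", {
  clf <- tiny_model()
  w <- tiny_world()
  u <- random_uap(c(32L, 32L, 1L), xi = 0.2, p = Inf, seed = 3L)
  rep <- evaluate_uap(clf, w$data$test, u)
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  j <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(j$r_f, rep$r_f)
  expect_true(file.exists(file.path(dir, "confusion_counts.csv")))
})
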