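test_that("zeta_to_xi is zeta times the mean image norm", {
  # two 5x5 images: constant 0.6 (L2 norm 3) and constant 1.0 (L2 norm 5)
  imgs <- array(0, dim = c(2, 5, 5, 1))
  imgs[1, , , ] <- 0.6
  imgs[2, , , ] <- 1.0
  ref <- image_set(imgs)
  expect_equal(zeta_to_xi(0.04, ref, 2), 0.04 * mean(c(3, 5)))
  expect_equal(zeta_to_xi(0.04, ref, 2), 0.16)
  expect_equal(zeta_to_xi(0, ref, 2), 0)
  # p = inf with all images max-valued at 1.0
  expect_equal(zeta_to_xi(0.08, ref[2], Inf), 0.08)
  expect_error(zeta_to_xi(0.04, ref[integer(0)], 2), "empty")
})

test_that("project_lp clips, rescales, and leaves interior points alone", {
  expect_equal(project_lp(c(0.5, -0.2), 0.3, Inf), c(0.3, -0.2))
  expect_equal(project_lp(c(3, 4), 1, 2), c(0.6, 0.8))
  inside <- c(0.1, -0.05)
  expect_identical(project_lp(inside, 0.3, Inf), inside)
  expect_identical(project_lp(inside, 1, 2), inside)
  expect_error(project_lp(inside, 0, 2), "xi")
})

test_that("fgsm_step implements sign / normalized steps with direction", {
  expect_equal(fgsm_step(c(2, -1), 0.1, Inf), c(0.1, -0.1))
  expect_equal(fgsm_step(c(3, 4), 0.1, 2), c(0.06, 0.08))
  expect_equal(fgsm_step(c(0, 0), 0.1, 2), c(0, 0))
  expect_equal(fgsm_step(c(0, 0), 0.1, Inf), c(0, 0))
  expect_equal(fgsm_step(c(2, -1), 0.1, Inf, "descend"), c(-0.1, 0.1))
  expect_error(fgsm_step(c(1, 2), 0, Inf), "epsilon")
  expect_error(fgsm_step(c(1, NaN), 0.1, Inf), "non-finite")
})

test_that("attack_config enforces its invariants", {
  expect_error(attack_config(p = 1), "p must be")
  expect_error(attack_config(zeta = 0.04, xi = 0.1), "exactly one")
  expect_error(attack_config(), "exactly one")
  expect_error(attack_config(xi = -1), "xi")
  expect_error(attack_config(xi = 0.1, i_max = 0), "i_max")
  expect_error(attack_config(xi = 0.1, epsilon = -0.1), "epsilon")
  cfg <- attack_config(p = 2, xi = 0.1)
  expect_equal(cfg$epsilon, 0.0005)
  cfg2 <- attack_config(p = Inf, zeta = 0.04)
  expect_equal(cfg2$epsilon, 0.0013)
})

test_that("random perturbations sit exactly on the sphere, reproducibly", {
  for (p in list(2, Inf)) {
    u <- random_uap(c(8L, 8L, 1L), xi = 0.37, p = p, seed = 4L)
    expect_equal(lp_norm(u$rho, p), 0.37, tolerance = 1e-9)
    expect_identical(u$source_tag, "random")
    v <- random_uap(c(8L, 8L, 1L), xi = 0.37, p = p, seed = 4L)
    expect_identical(u$rho, v$rho)
    w <- random_uap(c(8L, 8L, 1L), xi = 0.37, p = p, seed = 5L)
    expect_false(identical(u$rho, w$rho))
  }
  # Monte-Carlo oracle: isotropic directions cancel, so the mean of many
  # draws has a norm far below the radius
  draws <- sapply(1:1000, function(s) {
    as.vector(random_uap(c(4L, 4L, 1L), 1, 2, seed = s)$rho)
  })
  expect_lt(lp_norm(rowMeans(draws), 2), 0.2)
  expect_error(random_uap(c(4L, 4L, 1L), 0, 2), "xi")
})

test_that("single-image loops equal one projected FGSM step (linear oracle)", {
  W <- matrix(c(1, -1, -1, 1), 2, 2)
  clf <- linear_fixture(W = W)
  x <- matrix(c(0.8, 0.2), 1) # predicted class 0
  X <- rowset(x)
  big_xi <- 10
  cfg <- attack_config(p = Inf, epsilon = 0.05, xi = big_xi, i_max = 1L,
                       seed = 1L)
  u <- generate_uap_nontargeted(clf, X, cfg)
  pred0 <- predict(clf, X)
  oracle <- fgsm_step(linear_ce_grad(W, c(0, 0), c(0.8, 0.2), pred0),
                      0.05, Inf, "ascend")
  expect_equal(as.vector(u$rho), project_lp(oracle, big_xi, Inf),
               tolerance = 1e-12)
  expect_equal(u$log$n_updates, 1L)

  # targeted to the already-predicted class: skip, rho stays zero
  cfg_same <- attack_config(p = Inf, epsilon = 0.05, xi = big_xi,
                            i_max = 1L, seed = 1L, target_class = pred0)
  ut <- generate_uap_targeted(clf, X, cfg_same)
  expect_true(all(ut$rho == 0))
  expect_equal(ut$log$n_updates, 0L)
  expect_equal(ut$log$n_skips, 1L)

  # targeted to the other class: one projected descend step
  y <- 1L - pred0
  cfg_y <- attack_config(p = Inf, epsilon = 0.05, xi = big_xi, i_max = 1L,
                         seed = 1L, target_class = y)
  uy <- generate_uap_targeted(clf, X, cfg_y)
  oracle_y <- fgsm_step(linear_ce_grad(W, c(0, 0), c(0.8, 0.2), y),
                        0.05, Inf, "descend")
  expect_equal(as.vector(uy$rho), project_lp(oracle_y, big_xi, Inf),
               tolerance = 1e-12)
})

test_that("the skip rule suppresses updates on already-won images", {
  # strong epsilon flips the lone image within the first pass; the
  # second pass must skip it entirely
  clf <- linear_fixture(W = matrix(c(1, -1, -1, 1), 2, 2))
  X <- rowset(matrix(c(0.6, 0.4), 1))
  cfg <- attack_config(p = Inf, epsilon = 0.5, xi = 10, i_max = 2L,
                       seed = 1L)
  u <- generate_uap_nontargeted(clf, X, cfg)
  expect_equal(u$log$n_updates, 1L)
  expect_equal(u$log$n_skips, 1L)
  expect_equal(u$log$pass_rate, c(1, 1))
})

test_that("budget invariant holds on every attack path", {
  set.seed(31)
  w <- tiny_world()
  clf <- tiny_model()
  ref <- w$data$train
  for (p in list(2, Inf)) {
    for (zeta in c(0.02, 0.08)) {
      cfg <- attack_config(p = p, zeta = zeta, i_max = 1L, seed = 3L)
      u <- generate_uap_nontargeted(clf, w$data$train[1:40], cfg,
                                    reference = ref)
      xi <- zeta_to_xi(zeta, ref, p)
      expect_lte(lp_norm(u$rho, p), xi + 1e-6)
      expect_equal(u$xi, xi)
      expect_equal(u$zeta, zeta)
      tcfg <- attack_config(p = p, zeta = zeta, i_max = 1L, seed = 3L,
                            target_class = 1L)
      ut <- generate_uap_targeted(clf, w$data$train[1:40], tcfg,
                                  reference = ref)
      expect_lte(lp_norm(ut$rho, p), xi + 1e-6)
    }
  }
})

test_that("attacks are bit-reproducible from the seed", {
  w <- tiny_world()
  clf <- tiny_model()
  cfg <- attack_config(p = Inf, zeta = 0.04, i_max = 2L, seed = 17L)
  a <- generate_uap_nontargeted(clf, w$data$train[1:30], cfg,
                                reference = w$data$train)
  b <- generate_uap_nontargeted(clf, w$data$train[1:30], cfg,
                                reference = w$data$train)
  expect_identical(a$rho, b$rho)
  expect_identical(a$log, b$log)
})

test_that("a vanishing inner step yields a vanishing perturbation", {
  w <- tiny_world()
  clf <- tiny_model()
  cfg <- attack_config(p = Inf, epsilon = 1e-7, zeta = 0.08, i_max = 1L,
                       seed = 2L)
  u <- generate_uap_nontargeted(clf, w$data$train[1:40], cfg,
                                reference = w$data$train)
  expect_lt(lp_norm(u$rho, Inf), 1e-4)
  expect_lt(fooling_rate(clf, w$data$test, u), 0.05)
})

test_that("attack preconditions are enforced", {
  clf <- tiny_model()
  w <- tiny_world()
  cfg <- attack_config(p = Inf, zeta = 0.04, target_class = 1L)
  expect_error(generate_uap_nontargeted(clf, w$data$train[1:5], cfg),
               "target_class")
  cfg2 <- attack_config(p = Inf, zeta = 0.04)
  expect_error(generate_uap_targeted(clf, w$data$train[1:5], cfg2),
               "target_class")
  cfg3 <- attack_config(p = Inf, zeta = 0.04, target_class = 9L)
  expect_error(generate_uap_targeted(clf, w$data$train[1:5], cfg3),
               "\\[0, K\\)")
  # shape mismatch (e.g. forgetting the upstream gray transform)
  wrong <- generate_target_dataset(domain_spec(n_images = 8L, n_test = 4L,
                                               image_size = 20L,
                                               seed = 1L))$train
  expect_error(generate_uap_nontargeted(clf, wrong,
                                        attack_config(p = Inf, xi = 0.1)),
               "shape")
})

test_that("perturbations round-trip through text persistence", {
  u <- random_uap(c(6L, 6L, 1L), xi = 0.2, p = Inf, seed = 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_perturbation(u, path)
  back <- read_perturbation(path)
  expect_equal(back$rho, u$rho, tolerance = 1e-12)
  expect_identical(back$p, u$p)
  expect_equal(back$xi, u$xi)
  expect_identical(back$source_tag, "random")
})

test_that("sweep_epsilon reports attacker-side rates and the argmax", {
  w <- tiny_world()
  clf <- tiny_model()
  cfg <- attack_config(p = Inf, zeta = 0.08, i_max = 1L, seed = 1L)
  sw <- sweep_epsilon(clf, w$data$train[1:25], cfg,
                      epsilons = c(0.001, 0.02),
                      reference = w$data$train)
  expect_equal(nrow(sw), 2L)
  expect_true(all(sw$rate_on_X >= 0 & sw$rate_on_X <= 1))
  expect_true(attr(sw, "best") %in% sw$epsilon)
})
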