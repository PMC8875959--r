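#' Lp norm of a perturbation or image
#' @param v numeric vector or array.
#' @param p 2 or `Inf`.
#' @return the norm.
#' @export
lp_norm <- function(v, p) {
  v <- as.numeric(v)
  if (identical(p, 2) || identical(p, 2L)) sqrt(sum(v^2))
  else if (is.infinite(p)) max(abs(v))
  else stop("p must be 2 or Inf", call. = FALSE)
}

#' A universal adversarial perturbation with its budget
#'
#' Bundles the perturbation array rho with the norm order `p`, absolute
#' budget `xi` (pixel units, images in `[0,1]`), the relative magnitude
#' `zeta` (ratio of `xi` to the mean image norm of the reference set) and
#' the provenance tag. Construction enforces the budget invariant
#' `||rho||_p <= xi + 1e-6`.
#'
#' @param rho numeric array (the classifier's input shape).
#' @param p norm order, 2 or `Inf`.
#' @param xi norm budget.
#' @param zeta relative magnitude (may be `NA` when no reference set was
#'   involved, e.g. pure random controls).
#' @param source_tag one of `"training"`, `"source_pool"`, `"random"`.
#' @param target_class 0-based target class for targeted perturbations.
#' @param log optional attack-loop log (per-pass rates, update counters).
#' @return an object of class `perturbation`.
#' @export
perturbation <- function(rho, p, xi, zeta = NA_real_,
                         source_tag = c("training", "source_pool", "random"),
                         target_class = NULL, log = NULL) {
  source_tag <- match.arg(source_tag)
  nrm <- lp_norm(rho, p)
  if (nrm > xi + 1e-6) {
    stop(sprintf("budget violated: ||rho||_p = %.8g > xi = %.8g", nrm, xi),
         call. = FALSE)
  }
  structure(
    list(rho = rho, p = p, xi = xi, zeta = zeta, source_tag = source_tag,
         target_class = target_class, log = log),
    class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf("<perturbation> p=%s xi=%.5g ||rho||=%.5g source=%s%s\n",
              if (is.infinite(x$p)) "inf" else x$p, x$xi,
              lp_norm(x$rho, x$p), x$source_tag,
              if (!is.null(x$target_class))
                sprintf(" target=%d", x$target_class) else ""))
  invisible(x)
}

#' Attack hyperparameters
#'
#' Exactly one of `zeta` / `xi` must be given; `zeta` is converted to an
#' absolute budget against a reference image set by [zeta_to_xi()] at
#' attack time. The inner-step strength defaults follow the reference
#' values for this attack family: `epsilon = 0.0005` under `p = 2` and
#' `epsilon = 0.0013` under `p = Inf`. `i_max` counts passes over the
#' input set; the desk-scale default is 5 passes (hundreds of images per
#' pass) so the total number of inner updates is of the same order as one
#' pass over a corpus-sized pool.
#'
#' @param p norm order, 2 or `Inf`.
#' @param epsilon inner fast-gradient-sign step strength; must be > 0.
#' @param zeta relative perturbation magnitude.
#' @param xi absolute norm budget.
#' @param i_max number of passes over the input set (>= 1).
#' @param max_inner_iter inner fast-gradient-sign steps per visited image.
#'   The reference behaviour is 1 (a single epsilon-step per visit); a
#'   larger value iterates the inner attack until the visited image is
#'   fooled (non-targeted) or reaches the target (targeted), up to the
#'   cap, which is how the classical algorithm behaves when one
#'   epsilon-step is too small to cross the margin of a robust model.
#' @param target_class optional 0-based target class; its presence makes
#'   the attack targeted.
#' @param seed seed for the per-pass visiting order.
#' @return an object of class `attack_config`.
#' @export
attack_config <- function(p = Inf, epsilon = NULL, zeta = NULL, xi = NULL,
                          i_max = 5L, max_inner_iter = 1L,
                          target_class = NULL, seed = 1L) {
  if (!(identical(p, 2) || identical(p, 2L) || is.infinite(p))) {
    stop("p must be 2 or Inf", call. = FALSE)
  }
  if (is.null(epsilon)) epsilon <- if (is.infinite(p)) 0.0013 else 0.0005
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (i_max < 1L) stop("i_max must be >= 1", call. = FALSE)
  if (is.null(zeta) == is.null(xi)) {
    stop("exactly one of zeta or xi must be given", call. = FALSE)
  }
  if (!is.null(xi) && xi <= 0) stop("xi must be > 0", call. = FALSE)
  if (!is.null(zeta) && zeta <= 0) stop("zeta must be > 0", call. = FALSE)
  if (max_inner_iter < 1L) stop("max_inner_iter must be >= 1", call. = FALSE)
  structure(
    list(p = p, epsilon = epsilon, zeta = zeta, xi = xi,
         i_max = as.integer(i_max),
         max_inner_iter = as.integer(max_inner_iter),
         target_class = if (!is.null(target_class)) as.integer(target_class),
         seed = as.integer(seed)),
    class = "attack_config")
}

#' Convert a relative magnitude to an absolute norm budget
#'
#' `xi = zeta * mean_i ||x_i||_p` over the reference image set, so equal
#' `zeta` means equal absolute budget across perturbation sources for a
#' given task.
#'
#' @param zeta relative magnitude (>= 0).
#' @param reference a non-empty [image_set()].
#' @param p norm order.
#' @return the absolute budget `xi`.
#' @export
zeta_to_xi <- function(zeta, reference, p) {
  stopifnot(inherits(reference, "image_set"))
  if (length(reference) == 0L) stop("reference set is empty", call. = FALSE)
  if (zeta < 0) stop("zeta must be >= 0", call. = FALSE)
  X <- as_matrix(reference)
  norms <- if (is.infinite(p)) apply(abs(X), 1, max) else sqrt(rowSums(X^2))
  zeta * mean(norms)
}

#' Project onto the Lp ball of radius xi
#'
#' `p = Inf`: coordinate-wise clip to `[-xi, xi]`. `p = 2`: rescale by
#' `xi / ||rho||_2` only when outside the ball. Inputs already inside the
#' ball are returned unchanged.
#'
#' @param rho numeric array.
#' @param xi ball radius (> 0).
#' @param p norm order.
#' @return array of the same shape satisfying the budget.
#' @export
project_lp <- function(rho, xi, p) {
  if (xi <= 0) stop("xi must be > 0", call. = FALSE)
  if (is.infinite(p)) {
    pmin(pmax(rho, -xi), xi)
  } else {
    nrm <- lp_norm(rho, 2)
    if (nrm > xi) rho * (xi / nrm) else rho
  }
}

#' One fast-gradient-sign step
#'
#' `p = Inf`: `epsilon * sign(g)`. `p = 2`: `epsilon * g / ||g||_2` (the
#' L2-normalized analogue of the sign step). `direction = "descend"`
#' negates the step (targeted attacks descend the target-class loss). A
#' zero gradient yields a zero step.
#'
#' @param gradient loss gradient w.r.t. the input.
#' @param epsilon step strength (> 0).
#' @param p norm order.
#' @param direction `"ascend"` or `"descend"`.
#' @return step array of the gradient's shape.
#' @export
fgsm_step <- function(gradient, epsilon, p,
                      direction = c("ascend", "descend")) {
  direction <- match.arg(direction)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (any(!is.finite(gradient))) {
    stop("non-finite gradient in fgsm_step", call. = FALSE)
  }
  step <- if (is.infinite(p)) {
    epsilon * sign(gradient)
  } else {
    nrm <- lp_norm(gradient, 2)
    if (nrm == 0) gradient * 0 else epsilon * gradient / nrm
  }
  if (direction == "descend") -step else step
}

resolve_xi <- function(config, reference) {
  if (!is.null(config$xi)) {
    xi <- config$xi
    zeta <- if (!is.null(reference)) {
      xi / zeta_to_xi(1, reference, config$p)
    } else NA_real_
  } else {
    xi <- zeta_to_xi(config$zeta, reference, config$p)
    zeta <- config$zeta
  }
  list(xi = xi, zeta = zeta)
}

source_tag_of <- function(X) {
  if (X$domain_tag == "source_pool") "source_pool" else "training"
}

# Shared iterative loop. `want_update(adv_pred, clean_pred_i)` decides
# whether image i still drives an update; `grad_label(adv_pred,
# clean_pred_i)` is the class the loss is evaluated against.
uap_loop <- function(clf, X, config, reference, direction, want_update,
                     grad_label, rate_fn, source_tag, target_class = NULL) {
  stopifnot(inherits(X, "image_set"))
  n <- length(X)
  if (n == 0L) stop("X is empty", call. = FALSE)
  if (!identical(as.integer(image_shape(X)), clf$input_shape)) {
    stop("X does not match the classifier input shape (apply ",
         "gray_transform() upstream if needed)", call. = FALSE)
  }
  bud <- resolve_xi(config, reference)
  Xm <- as_matrix(X)
  clean <- predict(clf, Xm)
  d <- prod(clf$input_shape)
  rho <- numeric(d)
  n_updates <- 0L; n_skips <- 0L
  pass_rate <- numeric(config$i_max)
  with_seed(config$seed, {
    for (pass in seq_len(config$i_max)) {
      ord <- sample.int(n)
      for (i in ord) {
        xadv <- clip01(Xm[i, ] + rho)
        adv_pred <- predict(clf, matrix(xadv, nrow = 1L))
        if (!want_update(adv_pred, clean[i])) {
          n_skips <- n_skips + 1L
          next
        }
        # inner attack at the current adversarial point: epsilon-steps
        # until this image is won or the inner cap is reached; the
        # accumulated displacement is folded into rho, then projected
        delta <- numeric(d)
        for (j in seq_len(config$max_inner_iter)) {
          g <- loss_gradient(clf, xadv, grad_label(adv_pred, clean[i]),
                             mode = if (is.null(target_class))
                               "nontargeted" else "targeted")
          delta <- delta + as.vector(
            fgsm_step(g, config$epsilon, config$p, direction))
          n_updates <- n_updates + 1L
          if (j == config$max_inner_iter) break
          xadv <- clip01(Xm[i, ] + rho + delta)
          adv_pred <- predict(clf, matrix(xadv, nrow = 1L))
          if (!want_update(adv_pred, clean[i])) break
        }
        rho <- project_lp(rho + delta, bud$xi, config$p)
      }
      adv_all <- clip01(sweep(Xm, 2, rho, "+"))
      pass_rate[pass] <- rate_fn(predict(clf, adv_all), clean)
    }
  })
  perturbation(array(rho, dim = clf$input_shape), p = config$p,
               xi = bud$xi, zeta = bud$zeta, source_tag = source_tag,
               target_class = target_class,
               log = list(pass_rate = pass_rate, n_updates = n_updates,
                          n_skips = n_skips))
}

#' Generate a non-targeted universal adversarial perturbation
#'
#' Starts from `rho = 0` and makes `i_max` passes over `X` in a seeded
#' random order without replacement. Each image whose perturbed prediction
#' still matches its clean prediction (not yet fooled) contributes one
#' projected fast-gradient-sign ascent step on the loss of its current
#' predicted class, evaluated at the current adversarial point
#' `clip(x + rho)`; already-fooled images are skipped. The budget
#' `||rho||_p <= xi` is enforced after every step.
#'
#' @param clf a classifier handle.
#' @param X the input [image_set()] the perturbation is crafted from
#'   (target-domain training images or the out-of-domain pool).
#' @param config an [attack_config()] without `target_class`.
#' @param reference image set defining the `zeta` to `xi` conversion;
#'   defaults to `X`. Pass the target-domain training set when attacking
#'   from another source so budgets are comparable across sources.
#' @return a [perturbation()]; its `log` records the per-pass fooling
#'   fraction on `X` and update/skip counters.
#' @export
generate_uap_nontargeted <- function(clf, X, config, reference = X) {
  stopifnot(inherits(config, "attack_config"))
  if (!is.null(config$target_class)) {
    stop("config carries a target_class; use generate_uap_targeted()",
         call. = FALSE)
  }
  uap_loop(clf, X, config, reference, direction = "ascend",
           want_update = function(adv_pred, clean_i) adv_pred == clean_i,
           grad_label = function(adv_pred, clean_i) adv_pred,
           rate_fn = function(adv, clean) mean(adv != clean),
           source_tag = source_tag_of(X))
}

#' Generate a targeted universal adversarial perturbation
#'
#' Same loop structure as [generate_uap_nontargeted()], but an image
#' contributes an update only while its perturbed prediction differs from
#' the target class `y`, and the step descends the target-class loss
#' (pushing every image towards `y`). Images already predicted as `y` are
#' skipped, so the success rate on `X` can only be driven up from its
#' clean baseline.
#'
#' @inheritParams generate_uap_nontargeted
#' @param config an [attack_config()] with `target_class` set.
#' @return a [perturbation()] with `target_class` recorded; `log` holds
#'   the per-pass target-class rate on `X`.
#' @export
generate_uap_targeted <- function(clf, X, config, reference = X) {
  stopifnot(inherits(config, "attack_config"))
  y <- config$target_class
  if (is.null(y)) stop("config$target_class must be set", call. = FALSE)
  if (y < 0L || y >= clf$n_classes) {
    stop("target_class must be in [0, K)", call. = FALSE)
  }
  uap_loop(clf, X, config, reference, direction = "descend",
           want_update = function(adv_pred, clean_i) adv_pred != y,
           grad_label = function(adv_pred, clean_i) y,
           rate_fn = function(adv, clean) mean(adv == y),
           source_tag = source_tag_of(X), target_class = y)
}

#' Random perturbation control
#'
#' Samples a random vector on the sphere of radius `xi`: under `p = 2` an
#' isotropic direction (normalized standard-normal draw) scaled to
#' `||rho||_2 = xi`; under `p = Inf` i.i.d. uniform coordinates in
#' `[-xi, xi]` rescaled so the maximum absolute coordinate equals `xi`.
#'
#' @param shape integer `c(h, w, c)`.
#' @param xi radius (> 0).
#' @param p norm order.
#' @param seed integer seed.
#' @return a [perturbation()] with `source_tag = "random"` and
#'   `||rho||_p = xi` exactly (within 1e-6).
#' @export
random_uap <- function(shape, xi, p, seed = 1L) {
  if (xi <= 0) stop("xi must be > 0", call. = FALSE)
  d <- prod(shape)
  rho <- with_seed(seed, {
    if (is.infinite(p)) {
      v <- stats::runif(d, -xi, xi)
      v * (xi / max(abs(v)))
    } else {
      v <- stats::rnorm(d)
      v * (xi / sqrt(sum(v^2)))
    }
  })
  perturbation(array(rho, dim = shape), p = p, xi = xi,
               source_tag = "random")
}

#' Sweep the inner-step strength
#'
#' Runs the non-targeted (or targeted, when `config$target_class` is
#' set) generator once per candidate `epsilon` and reports the final
#' per-pass rate achieved on the input set `X` — the attacker-side
#' selection criterion: performance is measured on the images used to
#' craft the perturbation, never on held-out data.
#'
#' @param clf a classifier handle.
#' @param X input [image_set()].
#' @param config an [attack_config()]; its `epsilon` is overridden.
#' @param epsilons candidate strengths.
#' @param reference `zeta`-reference set (see
#'   [generate_uap_nontargeted()]).
#' @return `data.frame` with columns `epsilon` and `rate_on_X`, plus
#'   attribute `best` (the epsilon maximizing `rate_on_X`).
#' @export
sweep_epsilon <- function(clf, X, config,
                          epsilons = c(0.0005, 0.0013, 0.005, 0.02),
                          reference = X) {
  rates <- vapply(epsilons, function(eps) {
    cfg <- config
    cfg$epsilon <- eps
    u <- if (is.null(config$target_class)) {
      generate_uap_nontargeted(clf, X, cfg, reference)
    } else {
      generate_uap_targeted(clf, X, cfg, reference)
    }
    utils::tail(u$log$pass_rate, 1)
  }, numeric(1))
  out <- data.frame(epsilon = epsilons, rate_on_X = rates)
  attr(out, "best") <- epsilons[which.max(rates)]
  out
}

#' Persist a perturbation as plain text
#'
#' The array goes to CSV (one value per line, shape in the sidecar); the
#' JSON sidecar records p, xi, zeta, source, target class and the attack
#' log, so the artifact is self-describing.
#'
#' @param pert a [perturbation()].
#' @param path output CSV path; the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_perturbation <- function(pert, path) {
  stopifnot(inherits(pert, "perturbation"))
  utils::write.csv(data.frame(value = as.vector(pert$rho)), path,
                   row.names = FALSE)
  side <- list(shape = as.integer(dim(pert$rho)),
               p = if (is.infinite(pert$p)) "inf" else pert$p,
               xi = pert$xi, zeta = pert$zeta, source_tag = pert$source_tag,
               target_class = pert$target_class, log = pert$log)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_perturbation
#' @export
read_perturbation <- function(path) {
  vals <- utils::read.csv(path)$value
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- if (identical(side$p, "inf")) Inf else as.numeric(side$p)
  perturbation(array(vals, dim = side$shape), p = p, xi = side$xi,
               zeta = if (is.null(side$zeta)) NA_real_ else side$zeta,
               source_tag = side$source_tag,
               target_class = side$target_class, log = side$log)
}
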