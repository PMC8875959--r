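#' Apply a perturbation to an image set
#'
#' Adds rho to every image and clips to the valid pixel range `[0, 1]`
#' (the perturbation itself is stored unclipped; clipping happens at the
#' classifier boundary, consistently during generation and evaluation).
#'
#' @param X an [image_set()].
#' @param pert a [perturbation()] (or a bare array of the image shape).
#' @return an [image_set()] of adversarial images.
#' @export
apply_perturbation <- function(X, pert) {
  stopifnot(inherits(X, "image_set"))
  rho <- if (inherits(pert, "perturbation")) pert$rho else pert
  if (!identical(as.integer(dim(rho)), as.integer(image_shape(X)))) {
    stop("perturbation shape does not match the image shape", call. = FALSE)
  }
  d <- dim(X$images)
  adv <- clip01(X$images + rep(rho, each = d[1]))
  image_set(array(adv, dim = d), labels = X$labels,
            class_names = X$class_names, domain_tag = X$domain_tag)
}

#' Fooling rate of a perturbation
#'
#' Fraction of images whose prediction changes under the perturbation,
#' measured against the clean predictions (not the true labels):
#' `Rf = |X|^-1 sum_x 1[C(x) != C(clip(x + rho))]`.
#'
#' @param clf a classifier handle.
#' @param X a non-empty [image_set()].
#' @param pert a [perturbation()].
#' @return the rate in `[0, 1]`.
#' @export
fooling_rate <- function(clf, X, pert) {
  if (length(X) == 0L) stop("X is empty", call. = FALSE)
  clean <- predict(clf, X)
  adv <- predict(clf, apply_perturbation(X, pert))
  mean(adv != clean)
}

#' Targeted success rate with its clean baseline
#'
#' `Rs = |X|^-1 sum_x 1[C(clip(x + rho)) = y]`, plus the baseline: the
#' identical quantity with no perturbation (the clean rate of the target
#' class, which a class-balanced K-class test set puts near 1/K).
#'
#' @param clf a classifier handle.
#' @param X a non-empty [image_set()].
#' @param pert a [perturbation()].
#' @param y 0-based target class.
#' @return list with elements `rate` and `baseline`, both in `[0, 1]`.
#' @export
success_rate <- function(clf, X, pert, y) {
  if (length(X) == 0L) stop("X is empty", call. = FALSE)
  y <- as.integer(y)
  if (y < 0L || y >= clf$n_classes) stop("y must be in [0, K)", call. = FALSE)
  clean <- predict(clf, X)
  adv <- predict(clf, apply_perturbation(X, pert))
  list(rate = mean(adv == y), baseline = mean(clean == y))
}

#' Prediction-transition confusion matrices
#'
#' Entry (i, j) counts images whose clean prediction is class i and whose
#' adversarial prediction is class j (`rows = "clean"`; switch to
#' `rows = "truth"` to index rows by true labels for figure-style
#' matrices). Rows of the normalized matrix sum to 1; rows with zero
#' count are all-zero rather than NaN. The dominant class is the column
#' with the largest total adversarial count, ties towards the lowest
#' class index.
#'
#' @param clf a classifier handle.
#' @param X a non-empty [image_set()] (labelled when `rows = "truth"`).
#' @param pert a [perturbation()].
#' @param rows `"clean"` or `"truth"`.
#' @return list with `counts` (K x K integer), `row_normalized` (K x K),
#'   `dominant_class` (0-based integer).
#' @export
confusion_matrices <- function(clf, X, pert, rows = c("clean", "truth")) {
  rows <- match.arg(rows)
  if (length(X) == 0L) stop("X is empty", call. = FALSE)
  k <- clf$n_classes
  row_idx <- if (rows == "clean") {
    predict(clf, X)
  } else {
    if (is.null(X$labels)) stop("rows = 'truth' needs labels", call. = FALSE)
    X$labels
  }
  adv <- predict(clf, apply_perturbation(X, pert))
  counts <- matrix(0L, k, k,
                   dimnames = list(paste0("from", 0:(k - 1)),
                                   paste0("to", 0:(k - 1))))
  for (i in seq_along(adv)) {
    counts[row_idx[i] + 1L, adv[i] + 1L] <-
      counts[row_idx[i] + 1L, adv[i] + 1L] + 1L
  }
  rs <- rowSums(counts)
  row_normalized <- counts / ifelse(rs > 0, rs, 1)
  dominant_class <- which.max(colSums(counts)) - 1L
  list(counts = counts, row_normalized = row_normalized,
       dominant_class = as.integer(dominant_class))
}

#' Predicted-label composition of an image pool
#'
#' The per-class frequency of predictions over a (typically unlabelled)
#' pool. An imbalanced composition of the pool's predicted labels is the
#' mechanism that shapes which classes a pool-crafted perturbation can
#' and cannot attack effectively.
#'
#' @param clf a classifier handle.
#' @param pool a non-empty [image_set()].
#' @return numeric vector of length K summing to 1, named by class index.
#' @export
label_composition <- function(clf, pool) {
  if (length(pool) == 0L) stop("pool is empty", call. = FALSE)
  pred <- predict(clf, pool)
  k <- clf$n_classes
  freq <- tabulate(pred + 1L, nbins = k) / length(pred)
  names(freq) <- paste0("class", 0:(k - 1))
  freq
}

#' Full evaluation report for one perturbation
#'
#' Computes the fooling rate, the targeted success rate and baseline
#' (when a target class applies), the prediction-transition confusion
#' matrices and the dominant class in one pass, with a metadata echo of
#' the perturbation sidecar.
#'
#' @param clf a classifier handle.
#' @param X a non-empty [image_set()] (normally test images).
#' @param pert a [perturbation()].
#' @param target_class 0-based target class; defaults to the
#'   perturbation's own, if any.
#' @return an object of class `eval_report`.
#' @export
evaluate_uap <- function(clf, X, pert, target_class = pert$target_class) {
  if (length(X) == 0L) stop("X is empty", call. = FALSE)
  if (!is.null(target_class) &&
      (target_class < 0L || target_class >= clf$n_classes)) {
    stop("target_class must be in [0, K)", call. = FALSE)
  }
  clean <- predict(clf, X)
  adv <- predict(clf, apply_perturbation(X, pert))
  k <- clf$n_classes
  counts <- matrix(0L, k, k)
  for (i in seq_along(adv)) {
    counts[clean[i] + 1L, adv[i] + 1L] <-
      counts[clean[i] + 1L, adv[i] + 1L] + 1L
  }
  rs <- rowSums(counts)
  report <- list(
    r_f = mean(adv != clean),
    r_s = if (!is.null(target_class)) mean(adv == target_class),
    r_s_baseline = if (!is.null(target_class)) mean(clean == target_class),
    confusion_counts = counts,
    confusion = counts / ifelse(rs > 0, rs, 1),
    dominant_class = as.integer(which.max(colSums(counts)) - 1L),
    n_images = length(X),
    metadata = list(architecture_id = clf$architecture_id,
                    init_mode = clf$init_mode,
                    p = pert$p, xi = pert$xi, zeta = pert$zeta,
                    source_tag = pert$source_tag,
                    target_class = target_class))
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d Rf=%.3f%s dominant=%d\n",
              x$n_images, x$r_f,
              if (!is.null(x$r_s))
                sprintf(" Rs=%.3f (baseline %.3f)", x$r_s, x$r_s_baseline)
              else "", x$dominant_class))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Scalars and metadata go to JSON; the confusion matrices go to CSV.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scal <- report[c("r_f", "r_s", "r_s_baseline", "dominant_class",
                   "n_images", "metadata")]
  scal <- scal[!vapply(scal, is.null, logical(1))]
  scal$metadata$p <- if (is.infinite(scal$metadata$p)) "inf"
                     else scal$metadata$p
  jsonlite::write_json(scal, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$confusion_counts,
                   file.path(dir, "confusion_counts.csv"))
  utils::write.csv(report$confusion,
                   file.path(dir, "confusion_row_normalized.csv"))
  invisible(dir)
}
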