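#' Ordered image collection with a shared shape
#'
#' An `image_set` stores a stack of images as a single numeric array of
#' dimension `n x height x width x channels`, with pixel values in `[0, 1]`.
#' Class labels, when present, are 0-based integer indices into
#' `class_names` (the convention used throughout: predictions, target
#' classes and confusion-matrix axes are all 0-based class indices).
#'
#' @param images numeric array `n x h x w x c`, values in `[0, 1]`.
#' @param labels optional integer vector of length `n`, each in `[0, K)`.
#' @param class_names character vector of length `K` naming the classes.
#' @param domain_tag `"target"` or `"source_pool"`.
#' @return an object of class `image_set`.
#' @export
image_set <- function(images, labels = NULL, class_names = NULL,
                      domain_tag = c("target", "source_pool")) {
  domain_tag <- match.arg(domain_tag)
  if (!is.array(images) || length(dim(images)) != 4L) {
    stop("`images` must be a 4-d array (n x height x width x channels)",
         call. = FALSE)
  }
  storage.mode(images) <- "double"
  if (length(images) > 0L) {
    rng <- range(images)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12) {
      stop("pixel values must lie in [0, 1]", call. = FALSE)
    }
  }
  n <- dim(images)[1]
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("one label per image required", call. = FALSE)
    k <- length(class_names)
    if (k == 0L) k <- max(labels) + 1L
    if (any(labels < 0L) || any(labels >= k)) {
      stop("labels must be integers in [0, K)", call. = FALSE)
    }
  }
  if (is.null(class_names) && !is.null(labels)) {
    class_names <- paste0("class", seq_len(max(labels) + 1L) - 1L)
  }
  structure(
    list(images = images, labels = labels,
         class_names = class_names, domain_tag = domain_tag),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_set> %d images, %dx%dx%d, domain=%s, %s\n",
              d[1], d[2], d[3], d[4], x$domain_tag,
              if (is.null(x$labels)) "unlabelled"
              else sprintf("%d classes", length(x$class_names))))
  invisible(x)
}

#' @export
length.image_set <- function(x) dim(x$images)[1]

#' Subset an image set by image index
#' @param x an `image_set`.
#' @param i integer indices of images to keep.
#' @param ... unused.
#' @export
`[.image_set` <- function(x, i, ...) {
  out <- image_set(x$images[i, , , , drop = FALSE],
                   labels = if (!is.null(x$labels)) x$labels[i],
                   class_names = x$class_names, domain_tag = x$domain_tag)
  sur <- attr(x, "surrogate_labels")
  if (!is.null(sur)) attr(out, "surrogate_labels") <- sur[i]
  out
}

#' Image shape of a set or classifier input
#' @param x an `image_set`.
#' @return integer vector `c(height, width, channels)`.
#' @export
image_shape <- function(x) {
  stopifnot(inherits(x, "image_set"))
  dim(x$images)[2:4]
}

# Flatten to an n x (h*w*c) matrix; column order is the native R array
# order (row index fastest, then column, then channel). Every layer
# geometry in the CNN assumes this order.
as_matrix <- function(x) {
  if (inherits(x, "image_set")) x <- x$images
  stopifnot(length(dim(x)) == 4L)
  matrix(x, nrow = dim(x)[1])
}

# One image (h x w x c array) as a plain vector in the same order.
as_image_vector <- function(img) {
  stopifnot(length(dim(img)) == 3L)
  as.vector(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Collapse colour channels to luminance
#'
#' Replaces every pixel by the unweighted mean of its channels, replicated
#' back across all channels so the downstream classifier sees its expected
#' channel count. Idempotent; values remain in `[0, 1]`.
#'
#' @param x an `image_set` (1 or 3 channels).
#' @return an `image_set` with identical shape and luminance content.
#' @export
gray_transform <- function(x) {
  stopifnot(inherits(x, "image_set"))
  d <- dim(x$images)
  if (!d[4] %in% c(1L, 3L)) {
    stop("gray_transform supports 1- or 3-channel images", call. = FALSE)
  }
  if (d[4] == 1L) return(x)
  lum <- (x$images[, , , 1] + x$images[, , , 2] + x$images[, , , 3]) / 3
  out <- array(lum, dim = d) # recycles luminance into each channel slab
  image_set(out, labels = x$labels, class_names = x$class_names,
            domain_tag = x$domain_tag)
}

#' Persist an image set
#'
#' Writes the array as RDS next to a JSON sidecar echoing shape, labels and
#' class names, so a run manifest stays human-inspectable.
#'
#' @param x an `image_set`.
#' @param path output path for the RDS file; the sidecar gets `.json`
#'   appended.
#' @return `path`, invisibly.
#' @export
write_image_set <- function(x, path) {
  stopifnot(inherits(x, "image_set"))
  saveRDS(x, path)
  side <- list(n = length(x), shape = as.integer(image_shape(x)),
               domain_tag = x$domain_tag, class_names = x$class_names,
               labelled = !is.null(x$labels))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "image_set"))
  x
}
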