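# Synthetic benchmarks with the statistical structure the pipeline assumes:
# paired two-class textured images (smooth background, bright elliptical
# "lesion" blobs for the positive class) and two-class feature tables with a
# known informative column subset. Everything is a pure function of its seed.

# Separable Gaussian blur with replicated edges.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
  conv_rows <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[(i - 1) + seq_len(nrow(m)), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(x))))
}

#' Specification of a paired two-class textured image set
#'
#' @param size Image size `c(rows, cols)` (default 128 x 128).
#' @param n_pairs Number of healthy/lesioned pairs (default 10).
#' @param blur_sigma Gaussian blur radius of the smooth background, pixels
#'   (default 3).
#' @param lesion_count Range `c(min, max)` of blobs per lesioned image
#'   (default 2..5).
#' @param lesion_radius Range of blob semi-axes, pixels (default 4..10).
#' @param lesion_boost Blob intensity boost, gray levels (default 80).
#' @param noise_sd Additive pixel noise standard deviation, gray levels
#'   (default 10; classes stay separable because boost > 2 * noise_sd).
#' @param seed Integer seed.
#' @return A `texture_image_spec` list.
#' @export
texture_image_spec <- function(size = c(128, 128), n_pairs = 10,
                               blur_sigma = 3, lesion_count = c(2, 5),
                               lesion_radius = c(4, 10), lesion_boost = 80,
                               noise_sd = 10, seed = 1) {
  if (lesion_boost <= 2 * noise_sd) {
    stop("texture_image_spec: lesion_boost must exceed 2 * noise_sd", call. = FALSE)
  }
  if (max(lesion_radius) * 2 >= min(size)) {
    stop("texture_image_spec: lesion radius exceeds image size", call. = FALSE)
  }
  structure(list(size = as.integer(size), n_pairs = as.integer(n_pairs),
                 blur_sigma = blur_sigma, lesion_count = as.integer(lesion_count),
                 lesion_radius = lesion_radius, lesion_boost = lesion_boost,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "texture_image_spec")
}

# Binary mask of random elliptical blobs.
lesion_mask <- function(size, count, radius_range) {
  m <- matrix(FALSE, size[1], size[2])
  rr <- matrix(seq_len(size[1]), size[1], size[2])
  cc <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  margin <- ceiling(max(radius_range)) + 1
  for (b in seq_len(count)) {
    a <- stats::runif(1, radius_range[1], radius_range[2])
    bax <- stats::runif(1, radius_range[1], radius_range[2])
    phi <- stats::runif(1, 0, pi)
    cy <- stats::runif(1, margin, size[1] - margin)
    cx <- stats::runif(1, margin, size[2] - margin)
    dy <- rr - cy; dx <- cc - cx
    u <- (dx * cos(phi) + dy * sin(phi)) / a
    w <- (-dx * sin(phi) + dy * cos(phi)) / bax
    m <- m | (u^2 + w^2 <= 1)
  }
  m
}

#' Generate a paired two-class textured image collection
#'
#' Each pair shares one smooth noise background (blurred uniform field scaled
#' to mid-gray range) and one pixel-noise draw; the "healthy" image is that
#' background, the "lesioned" image adds bright elliptical blobs before
#' clamping to `[0, 255]`. The pairing isolates the lesion signal: with a
#' single blob the two images differ only inside it, and the lesioned mean
#' intensity is strictly greater by construction.
#'
#' @param spec A [texture_image_spec()].
#' @return List with `images` (list of [gray_image()]), `labels`
#'   (0 = healthy, 1 = lesioned), `ids`, `pair` (pair index per image) and
#'   `classes`.
#' @export
make_texture_images <- function(spec = texture_image_spec()) {
  set.seed(spec$seed)
  images <- list(); labels <- integer(); ids <- character(); pair <- integer()
  for (p in seq_len(spec$n_pairs)) {
    bg <- gaussian_blur(matrix(stats::runif(prod(spec$size)), spec$size[1]),
                        spec$blur_sigma)
    bg <- (bg - min(bg)) / max(max(bg) - min(bg), 1e-12)
    base <- 30 + 100 * bg +
      matrix(stats::rnorm(prod(spec$size), 0, spec$noise_sd), spec$size[1])
    nles <- if (spec$lesion_count[1] == spec$lesion_count[2]) spec$lesion_count[1]
            else sample(spec$lesion_count[1]:spec$lesion_count[2], 1)
    mask <- lesion_mask(spec$size, nles, spec$lesion_radius)
    healthy <- pmin(pmax(round(base), 0), 255)
    lesioned <- pmin(pmax(round(base + mask * spec$lesion_boost), 0), 255)
    images <- c(images, list(gray_image(healthy), gray_image(lesioned)))
    labels <- c(labels, 0L, 1L)
    ids <- c(ids, sprintf("healthy_%03d", p), sprintf("lesioned_%03d", p))
    pair <- c(pair, p, p)
  }
  list(images = images, labels = labels, ids = ids, pair = pair,
       classes = c("healthy", "lesioned"))
}

#' Write an image collection to a class-per-subdirectory PNG layout
#'
#' @param collection As returned by [make_texture_images()].
#' @param root Output directory; subdirectories per class are created.
#' @return Invisibly, the written paths.
#' @export
write_image_dataset <- function(collection, root) {
  classes <- collection$classes
  for (cl in classes) dir.create(file.path(root, cl), recursive = TRUE,
                                 showWarnings = FALSE)
  paths <- vapply(seq_along(collection$images), function(k) {
    cl <- classes[collection$labels[k] + 1]
    p <- file.path(root, cl, paste0(collection$ids[k], ".png"))
    png::writePNG(unclass(collection$images[[k]]) / 255, p)
    p
  }, character(1))
  invisible(paths)
}

#' Specification of a planted-subset synthetic feature table
#'
#' @param n_per_class Samples per class (default 150).
#' @param D Total feature columns (default 50).
#' @param k Informative columns (default 5).
#' @param delta Class-mean shift of informative columns in units of the
#'   within-class standard deviation (default 1.5).
#' @param seed Integer seed.
#' @return A `table_spec` list.
#' @export
table_spec <- function(n_per_class = 150, D = 50, k = 5, delta = 1.5, seed = 1) {
  stopifnot(k >= 1, k < D, delta >= 0, n_per_class >= 1)
  structure(list(n_per_class = as.integer(n_per_class), D = as.integer(D),
                 k = as.integer(k), delta = delta, seed = as.integer(seed)),
            class = "table_spec")
}

#' Generate a two-class feature table with a known informative subset
#'
#' Informative columns are `N(0, 1)` for class 0 and `N(delta, 1)` for class
#' 1; the remaining `D - k` columns are `N(0, 1)` noise for both classes.
#' Column order is shuffled, with the informative positions recorded.
#'
#' @param spec A [table_spec()].
#' @return List with `data` (feature data frame: `sample_id`, `f_...`,
#'   `label`) and `informative` (column positions of the informative
#'   features within the feature block).
#' @export
make_feature_table <- function(spec = table_spec()) {
  set.seed(spec$seed)
  n <- 2 * spec$n_per_class
  y <- rep(0:1, each = spec$n_per_class)
  X <- matrix(stats::rnorm(n * spec$D), n, spec$D)
  X[y == 1, seq_len(spec$k)] <- X[y == 1, seq_len(spec$k)] + spec$delta
  perm <- sample.int(spec$D)
  X <- X[, perm, drop = FALSE]
  informative <- match(seq_len(spec$k), perm)
  colnames(X) <- sprintf("f_%03d", seq_len(spec$D))
  data <- data.frame(sample_id = sprintf("s_%04d", seq_len(n)), X,
                     label = y, check.names = FALSE, stringsAsFactors = FALSE)
  list(data = data, informative = sort(informative), spec = spec)
}

#' Deterministic planted-mask objective on the unit hypercube
#'
#' `f(position) = alpha * Hamming(binarize(position), planted)/D +
#' (1 - alpha) * S/D` — a classifier-free stand-in for the wrapper fitness
#' whose unique binary minimizer is the planted mask.
#'
#' @param planted 0/1 vector (non-empty mask).
#' @param alpha Error weight (default 0.99).
#' @param threshold Binarization threshold (default 0.5).
#' @return Objective `function(position)`.
#' @export
planted_mask_objective <- function(planted, alpha = 0.99, threshold = 0.5) {
  planted <- as.integer(planted)
  if (sum(planted) == 0) stop("planted mask must be non-empty", call. = FALSE)
  D <- length(planted)
  function(position) {
    bits <- binarize_position(position, threshold)
    alpha * sum(bits != planted) / D + (1 - alpha) * sum(bits) / D
  }
}

#' Sphere benchmark objective centered in the unit hypercube
#'
#' `f(x) = sum((x - 0.5)^2)`, minimum 0 at the center.
#'
#' @param Dim Dimension (>= 1).
#' @return Objective `function(x)`.
#' @export
sphere_objective <- function(Dim) {
  stopifnot(Dim >= 1)
  function(x) sum((x - 0.5)^2)
}
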