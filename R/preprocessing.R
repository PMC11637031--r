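# ---- image containers -------------------------------------------------------

#' Construct a quantized grayscale image
#'
#' A `gray_image` is the unit all texture features consume: an integer matrix
#' with values in `[0, levels - 1]`.
#'
#' @param pixels Integer matrix of intensities.
#' @param levels Number of gray levels `L` (default 256).
#' @return A `gray_image` object (integer matrix with a `levels` attribute).
#' @export
gray_image <- function(pixels, levels = 256L) {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("gray_image: pixel values must be finite", call. = FALSE)
  }
  if (levels < 2) stop("gray_image: levels must be >= 2", call. = FALSE)
  if (any(pixels < 0) || any(pixels > levels - 1)) {
    stop("gray_image: pixel values must lie in [0, levels - 1]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, levels = as.integer(levels), class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d levels>\n",
              nrow(x), ncol(x), attr(x, "levels")))
  invisible(x)
}

glevels <- function(img) {
  l <- attr(img, "levels")
  if (is.null(l)) 256L else as.integer(l)
}

#' Pixel matrix of an image, stripped of class and attributes
#' @param img A [gray_image()] or plain matrix.
#' @return Plain matrix of pixel values.
#' @export
pixels <- function(img) {
  x <- unclass(img)
  attr(x, "levels") <- NULL
  x
}

# ---- reading and standardizing ----------------------------------------------

# Bilinear resampling with the align-corners convention: output corner pixels
# coincide with input corner pixels, so identity resizes are exact and
# constant images stay constant.
bilinear_resize <- function(x, out_rows, out_cols) {
  nr <- nrow(x); nc <- ncol(x)
  if (out_rows < 1 || out_cols < 1) {
    stop("bilinear_resize: target size must be positive", call. = FALSE)
  }
  rpos <- if (out_rows == 1) rep(1, 1) else 1 + (seq_len(out_rows) - 1) * (nr - 1) / (out_rows - 1)
  cpos <- if (out_cols == 1) rep(1, 1) else 1 + (seq_len(out_cols) - 1) * (nc - 1) / (out_cols - 1)
  r0 <- pmin(floor(rpos), nr - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cpos), nc - 1L); c0 <- pmax(c0, 1L)
  fr <- rpos - r0; fc <- cpos - c0
  a <- x[r0, c0, drop = FALSE];     b <- x[r0, c0 + 1, drop = FALSE]
  d <- x[r0 + 1, c0, drop = FALSE]; e <- x[r0 + 1, c0 + 1, drop = FALSE]
  wfr <- matrix(fr, out_rows, out_cols)
  wfc <- matrix(fc, out_rows, out_cols, byrow = TRUE)
  (1 - wfr) * (1 - wfc) * a + (1 - wfr) * wfc * b +
    wfr * (1 - wfc) * d + wfr * wfc * e
}

#' Load an image file and standardize it to a grayscale intensity grid
#'
#' Reads a PNG or JPEG file, converts color images to a single channel by the
#' unweighted channel mean, rescales intensities to the 0..255 integer range,
#' and resizes to `target_size` with bilinear interpolation followed by
#' rounding back to integers.
#'
#' @param path Path to a PNG or JPEG file.
#' @param target_size Integer vector `c(rows, cols)`; `NULL` keeps the native size.
#' @param levels Gray levels of the result (default 256).
#' @return A [gray_image()].
#' @export
load_and_standardize <- function(path, target_size = NULL, levels = 256L) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    # drop an alpha channel if present, then average color channels
    nch <- dim(arr)[3]
    if (nch == 4 || nch == 2) arr <- arr[, , -nch, drop = FALSE]
    arr <- apply(arr, c(1, 2), mean)
  }
  px <- arr * (levels - 1)
  if (!is.null(target_size)) {
    if (length(target_size) != 2 || any(target_size < 1)) {
      stop("target_size must be two positive integers", call. = FALSE)
    }
    if (!identical(dim(px), as.integer(target_size))) {
      px <- bilinear_resize(px, target_size[1], target_size[2])
    }
  }
  gray_image(pmin(pmax(round(px), 0), levels - 1), levels = levels)
}

#' Load a labeled image dataset from a class-per-subdirectory layout
#'
#' Expects `<root>/<class_name>/*.png|jpg|jpeg`; class names are taken
#' verbatim as class labels and mapped to integer labels 0, 1, ... in
#' alphabetical order (so `healthy` < `lesioned` gives the 0/1 convention).
#' Images are returned in sorted path order for determinism.
#'
#' @param root Dataset root directory.
#' @param target_size Passed to [load_and_standardize()].
#' @param levels Gray levels.
#' @return List with `images` (list of [gray_image()]), `labels` (integer),
#'   `classes` (label mapping), and `paths`.
#' @export
load_labeled_images <- function(root, target_size = NULL, levels = 256L) {
  if (!dir.exists(root)) stop("dataset directory not found: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, full.names = FALSE, recursive = FALSE))
  if (length(classes) < 1) stop("no class subdirectories under ", root, call. = FALSE)
  paths <- character(); labels <- integer()
  for (k in seq_along(classes)) {
    p <- sort(list.files(file.path(root, classes[k]),
                         pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                         full.names = TRUE))
    if (length(p) == 0) {
      stop("class directory '", classes[k], "' contains no images", call. = FALSE)
    }
    paths <- c(paths, p)
    labels <- c(labels, rep.int(k - 1L, length(p)))
  }
  images <- lapply(paths, function(p) {
    tryCatch(load_and_standardize(p, target_size = target_size, levels = levels),
             error = function(e) stop("failed to load '", p, "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  list(images = images, labels = labels, classes = classes, paths = paths)
}

# ---- normalization ----------------------------------------------------------

#' Histogram stretching (inter-scan min-max normalization)
#'
#' Linearly maps intensities to `[0, 1]`:
#' `O(x, y) = (N(x, y) - N_min) / (N_max - N_min)`.
#' Used to match the dynamic range of images acquired on different scanners.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @return Numeric matrix in `[0, 1]` with min 0 and max 1.
#' @export
histogram_stretch <- function(img) {
  x <- pixels(img)
  storage.mode(x) <- "double"
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    stop("histogram_stretch: constant image has zero dynamic range (N_max = N_min = ",
         lo, ")", call. = FALSE)
  }
  (x - lo) / (hi - lo)
}

#' Quantize a normalized image back to discrete gray levels
#'
#' Each value `v` in `[0, 1]` maps to `floor(v * (levels - 1) + 0.5)`
#' (round half up), which keeps both endpoints exact.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param levels Number of output gray levels (default 256).
#' @return A [gray_image()].
#' @export
quantize <- function(img, levels = 256L) {
  x <- as.matrix(img)
  if (levels < 2) stop("quantize: levels must be >= 2", call. = FALSE)
  if (any(x < 0) || any(x > 1)) {
    stop("quantize: values must lie in [0, 1]", call. = FALSE)
  }
  gray_image(floor(x * (levels - 1) + 0.5), levels = levels)
}
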