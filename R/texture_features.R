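# Texture descriptors for grayscale brain-slice images: first-order histogram
# statistics, gray-level co-occurrence matrix (GLCM) features at four
# orientations, and the 256-bin local binary pattern (LBP) histogram.

# ---- first-order statistics -------------------------------------------------

#' First-order (histogram) statistics of a grayscale image
#'
#' Computes mean, variance, standard deviation, skewness, kurtosis and
#' Shannon entropy of the intensity distribution. The standard deviation uses
#' the population form (divisor `N`); variance is its square; skewness and
#' kurtosis are the standardized third and fourth central moments. Entropy is
#' computed in nats over the `L`-bin normalized intensity histogram with the
#' convention `0 * ln 0 = 0`, so `0 <= entropy <= ln(L)`.
#'
#' For a constant image the standardized moments are 0/0; they are returned
#' as 0 by convention so that degenerate inputs stay usable.
#'
#' @param img A [gray_image()].
#' @return Named numeric vector `mean`, `variance`, `std`, `skewness`,
#'   `kurtosis`, `entropy`.
#' @export
first_order_features <- function(img) {
  L <- glevels(img)
  x <- as.double(unclass(img))
  n <- length(x)
  if (n == 0) stop("first_order_features: empty image", call. = FALSE)
  m <- sum(x) / n
  dev <- x - m
  std <- sqrt(sum(dev^2) / n)
  if (std > 0) {
    skew <- sum(dev^3) / n / std^3
    kurt <- sum(dev^4) / n / std^4
  } else {
    skew <- 0
    kurt <- 0
  }
  h <- tabulate(as.integer(x) + 1L, nbins = L) / n
  h <- h[h > 0]
  ent <- -sum(h * log(h))
  c(mean = m, variance = std^2, std = std, skewness = skew,
    kurtosis = kurt, entropy = ent)
}

# ---- GLCM -------------------------------------------------------------------

glcm_offset <- function(theta, d) {
  switch(as.character(theta),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("theta must be one of 0, 45, 90, 135 (degrees)", call. = FALSE)
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered (reference, neighbor) intensity pairs at pixel distance `d`
#' and orientation `theta` (degrees; row/column offsets 0 deg -> (0, +d),
#' 45 deg -> (-d, +d), 90 deg -> (-d, 0), 135 deg -> (-d, -d)). By default the
#' matrix is asymmetric (single offset direction); `symmetric = TRUE`
#' accumulates both directions. When `normalized`, entries are divided by the
#' total pair count so they sum to one.
#'
#' @param img A [gray_image()].
#' @param d Pixel distance (>= 1).
#' @param theta Orientation in degrees: 0, 45, 90 or 135.
#' @param normalized Divide counts by the total pair count (default TRUE).
#' @param symmetric Accumulate pairs in both offset directions (default FALSE).
#' @return `L x L` matrix of class `glcm` with attributes `d`, `theta`,
#'   `normalized`.
#' @export
compute_glcm <- function(img, d = 1L, theta = 0, normalized = TRUE,
                         symmetric = FALSE) {
  if (d < 1) stop("compute_glcm: d must be >= 1", call. = FALSE)
  L <- glevels(img)
  off <- glcm_offset(theta, as.integer(d))
  x <- unclass(img)
  nr <- nrow(x); nc <- ncol(x)
  dr <- off[1]; dc <- off[2]
  if (max(1L, 1L - dr) > min(nr, nr - dr) || max(1L, 1L - dc) > min(nc, nc - dc)) {
    stop("compute_glcm: image too small for offset d = ", d, call. = FALSE)
  }
  rows <- max(1L, 1L - dr):min(nr, nr - dr)
  cols <- max(1L, 1L - dc):min(nc, nc - dc)
  i <- x[rows, cols, drop = FALSE]
  j <- x[rows + dr, cols + dc, drop = FALSE]
  G <- matrix(tabulate(as.integer(i) * L + as.integer(j) + 1L, nbins = L * L),
              nrow = L, ncol = L, byrow = TRUE)
  if (symmetric) G <- G + t(G)
  G <- G * 1.0
  if (normalized) G <- G / sum(G)
  structure(G, d = as.integer(d), theta = theta, normalized = normalized,
            class = c("glcm", "matrix"))
}

#' Haralick-type features of a normalized GLCM
#'
#' Contrast, dissimilarity, homogeneity (inverse difference moment), angular
#' second moment (ASM), energy (`sqrt(ASM)`) and correlation, all computed
#' over gray-level indices `0..L-1`. Correlation uses the marginal means and
#' standard deviations of the matrix; when a marginal deviation is zero (for
#' example a constant image) correlation is returned as 1 and the result
#' carries a `degenerate` attribute.
#'
#' @param G A normalized GLCM from [compute_glcm()].
#' @return Named numeric vector `contrast`, `dissimilarity`, `homogeneity`,
#'   `asm`, `energy`, `correlation`.
#' @export
glcm_features <- function(G) {
  if (!isTRUE(attr(G, "normalized")) && abs(sum(G) - 1) > 1e-8) {
    stop("glcm_features: G must be normalized (entries summing to 1)", call. = FALSE)
  }
  G <- unclass(G)
  L <- nrow(G)
  lev <- 0:(L - 1)
  dif <- outer(lev, lev, "-")
  contrast <- sum(dif^2 * G)
  dissimilarity <- sum(abs(dif) * G)
  homogeneity <- sum(G / (1 + dif^2))
  asm <- sum(G^2)
  energy <- sqrt(asm)
  pi_ <- rowSums(G); pj <- colSums(G)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj)
  sd_i <- sqrt(sum((lev - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((lev - mu_j)^2 * pj))
  degenerate <- (sd_i == 0 || sd_j == 0)
  correlation <- if (degenerate) 1 else
    sum(outer(lev - mu_i, lev - mu_j) * G) / (sd_i * sd_j)
  out <- c(contrast = contrast, dissimilarity = dissimilarity,
           homogeneity = homogeneity, asm = asm, energy = energy,
           correlation = correlation)
  attr(out, "degenerate") <- degenerate
  out
}

# ---- LBP --------------------------------------------------------------------

# Sample img at fractional offsets (dr, dc) from every interior pixel,
# bilinearly. Offsets within 1e-8 of an integer are snapped so the four
# axis-aligned neighbors are read exactly.
shift_sample <- function(x, dr, dc, margin) {
  nr <- nrow(x); nc <- ncol(x)
  rows <- (1 + margin):(nr - margin)
  cols <- (1 + margin):(nc - margin)
  if (abs(dr - round(dr)) < 1e-8) dr <- round(dr)
  if (abs(dc - round(dc)) < 1e-8) dc <- round(dc)
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  v <- (1 - fr) * (1 - fc) * x[rows + r0, cols + c0, drop = FALSE]
  if (fc > 0) v <- v + (1 - fr) * fc * x[rows + r0, cols + c0 + 1, drop = FALSE]
  if (fr > 0) v <- v + fr * (1 - fc) * x[rows + r0 + 1, cols + c0, drop = FALSE]
  if (fr > 0 && fc > 0) v <- v + fr * fc * x[rows + r0 + 1, cols + c0 + 1, drop = FALSE]
  v
}

#' Local binary pattern code image
#'
#' For every interior pixel, samples `P` neighbors at angles `2*pi*p/P` on the
#' circle of radius `R` (bilinear interpolation at non-integer coordinates)
#' and packs the sign bits of the neighbor-minus-center differences:
#' `code = sum_p S(g_p - g_c) * 2^p` with `S(x) = 1` iff `x >= 0`. Pixels
#' within `ceiling(R)` of the border are excluded. `method = "grid"` uses the
#' 3x3 Moore neighborhood instead of the interpolated circle.
#'
#' @param img A [gray_image()].
#' @param P Number of neighbors (default 8).
#' @param R Circle radius in pixels (default 1).
#' @param method `"circular"` (default) or `"grid"`.
#' @return Integer matrix of codes in `[0, 2^P - 1]`, size
#'   `(rows - 2*ceiling(R)) x (cols - 2*ceiling(R))`.
#' @export
lbp_code_image <- function(img, P = 8L, R = 1.0, method = c("circular", "grid")) {
  method <- match.arg(method)
  x <- unclass(img)
  storage.mode(x) <- "double"
  margin <- as.integer(ceiling(R))
  if (nrow(x) < 2 * margin + 1 || ncol(x) < 2 * margin + 1) {
    stop("lbp_code_image: image must be at least ", 2 * margin + 1, "x",
         2 * margin + 1, call. = FALSE)
  }
  centre <- x[(1 + margin):(nrow(x) - margin), (1 + margin):(ncol(x) - margin),
              drop = FALSE]
  codes <- matrix(0L, nrow(centre), ncol(centre))
  for (p in seq_len(P) - 1L) {
    a <- 2 * pi * p / P
    if (method == "circular") {
      dr <- R * sin(a); dc <- R * cos(a)
    } else {
      dr <- round(sin(a)); dc <- round(cos(a))
    }
    gp <- shift_sample(x, dr, dc, margin)
    # the sign test tolerates bilinear round-off (weights summing to 1 leave
    # errors ~1e-14 on integer intensities, far below the 1-level grid)
    codes <- codes + as.integer(gp - centre >= -1e-6) * 2L^p
  }
  codes
}

#' Histogram of LBP codes
#'
#' @param codes Code matrix from [lbp_code_image()] (P = 8, codes 0..255).
#' @param normalized Return frequencies summing to 1 instead of counts.
#' @return Numeric vector of length 256, names `lbp_000` .. `lbp_255`.
#' @export
lbp_histogram <- function(codes, normalized = FALSE) {
  h <- tabulate(as.integer(codes) + 1L, nbins = 256L)
  if (normalized) h <- h / sum(h)
  names(h) <- sprintf("lbp_%03d", 0:255)
  h
}

# ---- full descriptor --------------------------------------------------------

#' Feature-extraction configuration
#'
#' @param levels Gray levels fed to histogram and GLCM (default 256).
#' @param glcm_d GLCM pixel distance (default 1).
#' @param glcm_angles GLCM orientations in degrees (default `c(0,45,90,135)`).
#' @param glcm_average Average GLCM features over angles instead of
#'   concatenating per-angle blocks (default FALSE).
#' @param glcm_symmetric Symmetric pair accumulation (default FALSE).
#' @param lbp_P,lbp_R LBP neighbor count and radius (defaults 8, 1).
#' @param lbp_method `"circular"` or `"grid"` LBP neighborhood.
#' @param normalize Apply histogram stretching + requantization before
#'   extraction (default TRUE; inter-scan normalization switch).
#' @return A `feature_config` list.
#' @export
feature_config <- function(levels = 256L, glcm_d = 1L,
                           glcm_angles = c(0, 45, 90, 135),
                           glcm_average = FALSE, glcm_symmetric = FALSE,
                           lbp_P = 8L, lbp_R = 1.0,
                           lbp_method = "circular", normalize = TRUE) {
  structure(list(levels = as.integer(levels), glcm_d = as.integer(glcm_d),
                 glcm_angles = glcm_angles, glcm_average = glcm_average,
                 glcm_symmetric = glcm_symmetric, lbp_P = as.integer(lbp_P),
                 lbp_R = lbp_R, lbp_method = lbp_method, normalize = normalize),
            class = "feature_config")
}

#' Names of the feature vector produced by a configuration
#' @param config A [feature_config()].
#' @return Character vector of feature names.
#' @export
feature_names <- function(config = feature_config()) {
  fo <- paste0("fo_", c("mean", "variance", "std", "skewness", "kurtosis", "entropy"))
  gnames <- c("contrast", "dissimilarity", "homogeneity", "asm", "energy", "correlation")
  gl <- if (config$glcm_average) {
    paste0("glcm_avg_", gnames)
  } else {
    as.vector(vapply(config$glcm_angles,
                     function(a) paste0("glcm_", a, "deg_", gnames),
                     character(6)))
  }
  c(fo, gl, sprintf("lbp_%03d", seq_len(2^config$lbp_P) - 1))
}

#' Extract the full texture feature vector of one image
#'
#' Concatenates, in fixed order: 6 first-order statistics, 6 GLCM features
#' per orientation (24 under the default four angles), and the normalized
#' 256-bin LBP histogram — 286 values under defaults. When
#' `config$normalize` is TRUE the image is histogram-stretched and
#' requantized to `config$levels` first.
#'
#' @param img A [gray_image()].
#' @param config A [feature_config()].
#' @return Named numeric vector (length 286 under defaults).
#' @export
extract_feature_vector <- function(img, config = feature_config()) {
  if (isTRUE(config$normalize)) {
    img <- quantize(histogram_stretch(img), levels = config$levels)
  }
  fo <- first_order_features(img)
  names(fo) <- paste0("fo_", c("mean", "variance", "std", "skewness",
                               "kurtosis", "entropy"))
  gl_blocks <- lapply(config$glcm_angles, function(a) {
    G <- compute_glcm(img, d = config$glcm_d, theta = a, normalized = TRUE,
                      symmetric = config$glcm_symmetric)
    f <- glcm_features(G)
    attributes(f) <- list(names = names(f))
    f
  })
  if (config$glcm_average) {
    gl <- Reduce(`+`, gl_blocks) / length(gl_blocks)
    names(gl) <- paste0("glcm_avg_", names(gl_blocks[[1]]))
  } else {
    gl <- unlist(lapply(seq_along(gl_blocks), function(k) {
      b <- gl_blocks[[k]]
      names(b) <- paste0("glcm_", config$glcm_angles[k], "deg_", names(b))
      b
    }))
  }
  lbp <- lbp_histogram(
    lbp_code_image(img, P = config$lbp_P, R = config$lbp_R,
                   method = config$lbp_method),
    normalized = TRUE)
  c(fo, gl, lbp)
}

#' Extract a labeled feature matrix from an image collection
#'
#' One row per image, rows in the collection's (path-sorted) order.
#'
#' @param collection List with `images`, `labels` and optionally `paths`/`ids`
#'   as returned by [load_labeled_images()] or [make_texture_images()].
#' @param config A [feature_config()].
#' @return Data frame: `sample_id`, feature columns, `label`.
#' @export
extract_feature_matrix <- function(collection, config = feature_config()) {
  imgs <- collection$images
  if (length(imgs) < 1) stop("extract_feature_matrix: empty collection", call. = FALSE)
  ids <- collection$ids
  if (is.null(ids)) ids <- collection$paths
  if (is.null(ids)) ids <- sprintf("sample_%04d", seq_along(imgs))
  rows <- lapply(seq_along(imgs), function(k) {
    tryCatch(extract_feature_vector(imgs[[k]], config),
             error = function(e) stop("feature extraction failed for '",
                                      ids[k], "': ", conditionMessage(e),
                                      call. = FALSE))
  })
  mat <- do.call(rbind, rows)
  out <- data.frame(sample_id = as.character(ids), mat,
                    label = as.integer(collection$labels),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a feature matrix as CSV
#'
#' Layout: first column `sample_id`, last column `label`, named feature
#' columns in between; UTF-8 with a header row.
#'
#' @param fm Feature matrix data frame.
#' @param path CSV path.
#' @return `read_feature_csv` returns the data frame; `write_feature_csv`
#'   returns `path` invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  utils::write.csv(fm, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("feature CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(df)[1], "sample_id") ||
      !identical(names(df)[length(df)], "label")) {
    stop("feature CSV must have first column 'sample_id' and last column 'label'",
         call. = FALSE)
  }
  df$label <- as.integer(df$label)
  df
}

# Split a feature data frame into the numeric matrix X and label vector y.
feature_xy <- function(fm) {
  fcols <- setdiff(names(fm), c("sample_id", "label"))
  list(x = as.matrix(fm[, fcols, drop = FALSE]), y = as.integer(fm$label),
       names = fcols)
}
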