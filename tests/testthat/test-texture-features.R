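test_that("first-order statistics match hand-computed closed forms", {
  # constant image: single-bin histogram, all moments degenerate
  fo <- first_order_features(gray_image(matrix(7, 3, 3)))
  expect_equal(unname(fo), c(7, 0, 0, 0, 0, 0))

  # two pixels {0, 2}: m = 1, std = 1, symmetric, two equal bins
  fo <- first_order_features(gray_image(matrix(c(0L, 2L), 1)))
  expect_equal(fo[["mean"]], 1)
  expect_equal(fo[["std"]], 1)
  expect_equal(fo[["variance"]], 1)
  expect_equal(fo[["skewness"]], 0)
  expect_equal(fo[["kurtosis"]], 1)
  expect_equal(fo[["entropy"]], log(2))
})

test_that("first-order features agree with the brute-force oracle on seeded images", {
  for (s in 1:20) {
    img <- rand_gray(s)
    got <- first_order_features(img)
    want <- oracle_first_order(img)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got[["variance"]], got[["std"]]^2, tolerance = 1e-12)
    expect_lte(got[["entropy"]], log(attr(img, "levels")) + 1e-12)
  }
})

test_that("GLCM counting matches hand enumeration and the pair-count identity", {
  # constant image: all mass at the diagonal cell
  G <- compute_glcm(gray_image(matrix(3, 4, 4), levels = 8), 1, 0)
  expect_equal(G[4, 4], 1)
  expect_equal(sum(G), 1)

  # 2x2 checkerboard, horizontal offset: the two ordered pairs (0,1), (1,0)
  G <- compute_glcm(gray_image(matrix(c(0, 1, 1, 0), 2), levels = 2), 1, 0)
  expect_equal(unclass(G), matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)

  # unnormalized entries sum to the number of valid pairs at each offset
  img <- rand_gray(31)
  for (th in c(0, 45, 90, 135)) {
    G <- compute_glcm(img, 1, th, normalized = FALSE)
    npairs <- switch(as.character(th), "0" = 8 * 7, "45" = 7 * 7,
                     "90" = 7 * 8, "135" = 7 * 7)
    expect_equal(sum(G), npairs)
  }
  expect_error(compute_glcm(gray_image(matrix(0, 1, 1)), 1, 0), "too small")
})

test_that("GLCM and its features agree with the brute-force oracle at all orientations", {
  for (s in 1:20) {
    img <- rand_gray(s)
    for (th in c(0, 45, 90, 135)) {
      G <- compute_glcm(img, 1, th)
      expect_equal(unclass(G), oracle_glcm(img, 1, th), tolerance = 1e-12,
                   ignore_attr = TRUE)
      got <- glcm_features(G)
      attributes(got) <- list(names = names(got))
      expect_equal(got, oracle_glcm_features(unclass(G)), tolerance = 1e-10)
    }
  }
})

test_that("GLCM features reproduce the checkerboard closed form", {
  G <- compute_glcm(gray_image(matrix(c(0, 1, 1, 0), 2), levels = 2), 1, 0)
  f <- glcm_features(G)
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["dissimilarity"]], 1)
  expect_equal(f[["homogeneity"]], 0.5)
  expect_equal(f[["asm"]], 0.5)
  expect_equal(f[["energy"]], sqrt(0.5))
  expect_equal(f[["correlation"]], -1)
})

test_that("diagonal GLCMs give zero contrast and unit homogeneity; energy = sqrt(asm)", {
  G <- compute_glcm(gray_image(matrix(5, 6, 6), levels = 16), 1, 45)
  f <- glcm_features(G)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["dissimilarity"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["correlation"]], 1)  # degenerate marginals convention
  expect_true(attr(f, "degenerate"))
  for (s in 1:5) {
    f <- glcm_features(compute_glcm(rand_gray(s), 1, 90))
    expect_equal(f[["energy"]], sqrt(f[["asm"]]), tolerance = 1e-12)
    expect_gte(f[["correlation"]], -1 - 1e-12)
    expect_lte(f[["correlation"]], 1 + 1e-12)
  }
})

test_that("0/90 degree GLCMs transpose consistently with the image transpose", {
  img <- rand_gray(77)
  timg <- gray_image(t(unclass(img)), levels = attr(img, "levels"))
  G0 <- compute_glcm(img, 1, 0)
  G90t <- compute_glcm(timg, 1, 90)
  # horizontal pairs of an image are vertical pairs of its transpose, with
  # the neighbor direction reversed: G0(i,j) = G90_transposed(j,i)
  expect_equal(unclass(G0), t(unclass(G90t)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("LBP codes behave per the sign convention and border exclusion", {
  expect_true(all(lbp_code_image(gray_image(matrix(9, 5, 5))) == 255L))
  centre_high <- matrix(0, 3, 3); centre_high[2, 2] <- 5
  expect_equal(lbp_code_image(gray_image(centre_high)),
               matrix(0L, 1, 1))
  expect_equal(dim(lbp_code_image(rand_gray(1, 4, 4))), c(2L, 2L))
  expect_error(lbp_code_image(gray_image(matrix(0:3, 2, 2))), "at least")
})

test_that("LBP codes are invariant to adding a constant intensity", {
  set.seed(21)
  base <- matrix(sample(0:200, 100, TRUE), 10)
  a <- lbp_code_image(gray_image(base))
  b <- lbp_code_image(gray_image(base + 55L))
  expect_identical(a, b)
})

test_that("LBP histogram counts interior pixels and normalizes to one", {
  codes <- lbp_code_image(gray_image(matrix(3, 4, 4)))
  h <- lbp_histogram(codes)
  expect_equal(unname(h[256]), 4)
  expect_equal(sum(h), 4)
  for (s in 1:5) {
    codes <- lbp_code_image(rand_gray(s, 9, 7))
    expect_equal(sum(lbp_histogram(codes)), 7 * 5)
    expect_equal(sum(lbp_histogram(codes, normalized = TRUE)), 1)
  }
})

test_that("the full descriptor has 286 stably named values and is deterministic", {
  img <- rand_gray(13, 16, 16, levels = 256)
  v1 <- extract_feature_vector(img)
  v2 <- extract_feature_vector(img)
  expect_length(v1, 286)
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_names())
  expect_true(all(is.finite(v1)))
  expect_identical(names(v1)[1:6],
                   c("fo_mean", "fo_variance", "fo_std", "fo_skewness",
                     "fo_kurtosis", "fo_entropy"))
  expect_identical(names(v1)[7], "glcm_0deg_contrast")
  expect_identical(names(v1)[31], "lbp_000")
  # angle averaging shrinks the GLCM block to one set of six
  va <- extract_feature_vector(img, feature_config(glcm_average = TRUE))
  expect_length(va, 6 + 6 + 256)
})

test_that("lesioned images have strictly greater raw mean than their paired healthy image", {
  coll <- make_texture_images(texture_image_spec(n_pairs = 20, size = c(64, 64),
                                                 seed = 4))
  fm <- extract_feature_matrix(coll, feature_config(normalize = FALSE))
  les <- fm$fo_mean[fm$label == 1]
  hea <- fm$fo_mean[fm$label == 0]
  expect_true(all(les > hea))
})

test_that("feature matrices round-trip through CSV", {
  coll <- make_texture_images(texture_image_spec(size = c(16, 16), n_pairs = 2,
                                                 lesion_radius = c(2, 4),
                                                 seed = 2))
  fm <- extract_feature_matrix(coll)
  expect_equal(dim(fm), c(4, 288))
  expect_equal(fm$label, c(0L, 1L, 0L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path)
  expect_equal(back, fm, tolerance = 1e-12)
})
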