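# Independent brute-force oracles: deliberate double-loop implementations of
# the histogram, co-occurrence and rank formulas, kept free of any package
# code so they can certify the vectorized implementations.

rand_gray <- function(seed, nr = 8, nc = 8, levels = 16) {
  set.seed(seed)
  gray_image(matrix(sample(0:(levels - 1), nr * nc, replace = TRUE), nr, nc),
             levels = levels)
}

oracle_first_order <- function(img) {
  L <- attr(img, "levels")
  x <- as.vector(unclass(img))
  N <- length(x)
  m <- sum(x) / N
  std <- sqrt(sum((x - m)^2) / N)
  skew <- if (std > 0) sum((x - m)^3) / (N * std^3) else 0
  kurt <- if (std > 0) sum((x - m)^4) / (N * std^4) else 0
  h <- numeric(L)
  for (v in x) h[v + 1] <- h[v + 1] + 1
  h <- h / N
  ent <- 0
  for (k in seq_len(L)) if (h[k] > 0) ent <- ent - h[k] * log(h[k])
  c(mean = m, variance = std^2, std = std, skewness = skew, kurtosis = kurt,
    entropy = ent)
}

oracle_glcm <- function(img, d, theta) {
  L <- attr(img, "levels")
  x <- unclass(img)
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  G <- matrix(0, L, L)
  for (r in seq_len(nrow(x))) {
    for (cc in seq_len(ncol(x))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(x) && c2 >= 1 && c2 <= ncol(x)) {
        G[x[r, cc] + 1, x[r2, c2] + 1] <- G[x[r, cc] + 1, x[r2, c2] + 1] + 1
      }
    }
  }
  G / sum(G)
}

oracle_glcm_features <- function(G) {
  L <- nrow(G)
  cont <- dis <- hom <- asm <- mi <- mj <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      g <- G[i, j]; dd <- i - j
      cont <- cont + dd^2 * g
      dis <- dis + abs(dd) * g
      hom <- hom + g / (1 + dd^2)
      asm <- asm + g^2
      mi <- mi + (i - 1) * g
      mj <- mj + (j - 1) * g
    }
  }
  si <- sj <- co <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      si <- si + (i - 1 - mi)^2 * G[i, j]
      sj <- sj + (j - 1 - mj)^2 * G[i, j]
      co <- co + (i - 1 - mi) * (j - 1 - mj) * G[i, j]
    }
  }
  si <- sqrt(si); sj <- sqrt(sj)
  c(contrast = cont, dissimilarity = dis, homogeneity = hom, asm = asm,
    energy = sqrt(asm), correlation = co / (si * sj))
}

# Textbook Friedman: per-block ranks by counting, then the uncorrected
# statistic (only used on tie-free fixtures).
oracle_friedman <- function(results, lower_is_better = TRUE) {
  R <- nrow(results); k <- ncol(results)
  ranks <- matrix(0, R, k)
  for (b in seq_len(R)) {
    for (j in seq_len(k)) {
      r <- 1
      for (j2 in seq_len(k)) {
        if (j2 != j) {
          better <- if (lower_is_better) results[b, j2] < results[b, j]
                    else results[b, j2] > results[b, j]
          if (better) r <- r + 1
        }
      }
      ranks[b, j] <- r
    }
  }
  S <- colSums(ranks)
  stat <- 12 / (R * k * (k + 1)) * sum(S^2) - 3 * R * (k + 1)
  list(mean_ranks = S / R, chi_square = stat)
}

# Small helper: a trivially separable feature table where KNN(k=5) attains a
# controlled error; class 0 sits at x = 0, class 1 at x = 10 on feature 1,
# feature 2 is constant noise. `n_wrong` evaluation points of class 0 are
# planted at x = 10.
separable_fixture <- function(n_train = 10, n_eval = 10, n_wrong = 0) {
  train_x <- cbind(c(rep(0, n_train), rep(10, n_train)), 0)
  train_y <- rep(0:1, each = n_train)
  half <- n_eval / 2
  eval_x <- cbind(c(rep(0, half - n_wrong), rep(10, n_wrong), rep(10, half)), 0)
  eval_y <- rep(0:1, each = half)
  list(train_x = train_x, train_y = train_y, eval_x = eval_x, eval_y = eval_y)
}
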