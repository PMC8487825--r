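# Independent brute-force oracles, coded separately from the package
# implementations (plain loops, no shared helpers).

# symmetric reflection of index i into 1..n (edge repeated)
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# Gaussian-weighted squared patch distance by explicit loop over offsets
oracle_patch_distance <- function(img, p, q, pr, sigma) {
  offs <- -pr:pr
  g <- exp(-offs^2 / (2 * sigma^2))
  G <- outer(g, g)
  G <- G / sum(G)
  M <- nrow(img); N <- ncol(img)
  acc <- 0
  for (a in seq_along(offs)) {
    for (b in seq_along(offs)) {
      ip <- oracle_reflect(p[1] + offs[a], M); jp <- oracle_reflect(p[2] + offs[b], N)
      iq <- oracle_reflect(q[1] + offs[a], M); jq <- oracle_reflect(q[2] + offs[b], N)
      acc <- acc + G[a, b] * (img[ip, jp] - img[iq, jq])^2
    }
  }
  acc
}

# full NL-means by triple loop (pixels x window x patch offsets)
oracle_nlmeans <- function(img, h, pr, R, sigma) {
  M <- nrow(img); N <- ncol(img)
  out <- matrix(0, M, N)
  for (i in 1:M) {
    for (j in 1:N) {
      wsum <- 0; acc <- 0
      for (qi in max(1, i - R):min(M, i + R)) {
        for (qj in max(1, j - R):min(N, j + R)) {
          d <- oracle_patch_distance(img, c(i, j), c(qi, qj), pr, sigma)
          w <- exp(-d / h^2)
          wsum <- wsum + w
          acc <- acc + w * img[qi, qj]
        }
      }
      out[i, j] <- acc / wsum
    }
  }
  out
}

# GLCM counts by explicit enumeration of ordered pixel pairs
oracle_glcm_counts <- function(lvl, d, theta, Ng) {
  dd <- switch(as.character(theta),
               "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0L, Ng, Ng)
  M <- nrow(lvl); N <- ncol(lvl)
  for (i in 1:M) {
    for (j in 1:N) {
      i2 <- i + dd[1]; j2 <- j + dd[2]
      if (i2 >= 1 && i2 <= M && j2 >= 1 && j2 <= N) {
        g1 <- lvl[i, j]; g2 <- lvl[i2, j2]
        counts[g1 + 1, g2 + 1] <- counts[g1 + 1, g2 + 1] + 1L
      }
    }
  }
  counts
}

# Haralick features from a normalized GLCM, by explicit double loops
oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  con <- 0; ent <- 0; cross <- 0
  for (a in 1:Ng) {
    for (b in 1:Ng) {
      p <- P[a, b]
      con <- con + (a - b)^2 * p
      if (p > 0) ent <- ent - p * log2(p)
      cross <- cross + (a - 1) * (b - 1) * p
    }
  }
  pr <- rowSums(P); pc <- colSums(P)
  lv <- 0:(Ng - 1)
  mu1 <- sum(lv * pr); mu2 <- sum(lv * pc)
  sd1 <- sqrt(sum(lv^2 * pr) - mu1^2); sd2 <- sqrt(sum(lv^2 * pc) - mu2^2)
  list(con = con, ent = ent,
       cor = if (sd1 > 0 && sd2 > 0) (cross - mu1 * mu2) / (sd1 * sd2) else NA,
       eng = sum(P^2))
}

# one-way ANOVA F by explicit sums of squares
oracle_anova_F <- function(values, groups) {
  sp <- split(values, groups)
  k <- length(sp); N <- length(values)
  gm <- mean(values)
  ssb <- sum(vapply(sp, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(sp, function(v) sum((v - mean(v))^2), 0))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k,
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

# Pearson chi-square by explicit (O - E)^2 / E
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  X2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(X2 = X2, df = df, p = stats::pchisq(X2, df, lower.tail = FALSE))
}

# small deterministic test image
toy_image <- function(M, N, seed = 1, max_gray = 255) {
  withr::with_seed(seed, matrix(sample(0:max_gray, M * N, replace = TRUE), M, N))
}
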