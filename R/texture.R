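# Block-based first-order statistics and gray-level co-occurrence matrix
# (GLCM) texture features.

#' Partition an image into square blocks
#'
#' Non-overlapping `L x L` tiles in row-major order (left to right, then top
#' to bottom); trailing partial tiles are dropped.
#'
#' @param img Numeric matrix.
#' @param L Block side in pixels, `2 <= L <= min(dim(img))`.
#' @return List of `L x L` matrices, each with attributes `block_row` and
#'   `block_col` (1-based tile indices).
#' @export
partition_blocks <- function(img, L) {
  stopifnot(is.matrix(img))
  L <- as.integer(L)
  if (L < 2L) stop("partition_blocks(): L must be >= 2")
  if (L > min(dim(img))) stop("partition_blocks(): L exceeds image size")
  nbr <- nrow(img) %/% L
  nbc <- ncol(img) %/% L
  out <- vector("list", nbr * nbc)
  k <- 1L
  for (i in seq_len(nbr)) {
    for (j in seq_len(nbc)) {
      b <- img[((i - 1L) * L + 1L):(i * L), ((j - 1L) * L + 1L):(j * L)]
      attr(b, "block_row") <- i
      attr(b, "block_col") <- j
      out[[k]] <- b
      k <- k + 1L
    }
  }
  out
}

#' Block gray mean
#'
#' Arithmetic mean of the block pixels, `(1/L^2) * sum(y_k(i, j))`.
#'
#' @param b Numeric matrix (block).
#' @return Mean gray level.
#' @export
block_mean <- function(b) {
  if (length(b) == 0L) stop("block_mean(): empty block")
  mean(b)
}

#' Block gray-level variance
#'
#' Population variance of the block pixels (divisor `L^2`):
#' `(1/L^2) * sum((y_k(i, j) - mean)^2)`.
#'
#' @param b Numeric matrix (block).
#' @return Variance in gray-units^2, >= 0.
#' @export
block_variance <- function(b) {
  if (length(b) == 0L) stop("block_variance(): empty block")
  mean((b - mean(b))^2)
}

#' Quantize gray intensities to Ng levels
#'
#' Uniform binning of `[0, max_gray]` into `Ng` equal bins, mapping to
#' integer levels `0 .. Ng-1`.
#'
#' @param img Numeric matrix with values in `[0, max_gray]`.
#' @param Ng Number of gray levels, >= 2.
#' @param max_gray Top of the intensity range (default 255 for 8-bit).
#' @return Integer matrix of levels in `0 .. Ng-1`.
#' @export
quantize_gray <- function(img, Ng, max_gray = 255) {
  q <- floor(img * Ng / (max_gray + 1))
  q[q > Ng - 1] <- Ng - 1
  q[q < 0] <- 0
  storage.mode(q) <- "integer"
  q
}

glcm_displacement <- function(d, theta) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("compute_glcm(): theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(g1, g2)` at displacement `(d, theta)` and
#' normalizes by the total pair count R. The matrix is ordered (not
#' symmetrized) by default; `symmetric = TRUE` adds the transposed counts.
#'
#' @param img Numeric matrix. If all values are already integers in
#'   `0 .. Ng-1` they are used as levels directly; otherwise intensities are
#'   uniformly quantized from `[0, 255]` (controllable via `quantize`).
#' @param d Displacement distance in pixels, >= 1.
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @param Ng Number of gray levels.
#' @param symmetric Add the transpose (unordered pairs)? Default `FALSE`.
#' @param quantize `NULL` (auto), `TRUE` (always bin from `[0, 255]`) or
#'   `FALSE` (values must already be levels).
#' @return Object of class `glcm`: list with `counts` (Ng x Ng integer),
#'   `probs` (normalized, sums to 1), `d`, `theta`, `Ng`, `R`.
#' @export
compute_glcm <- function(img, d = 1L, theta = 0, Ng = 8L,
                         symmetric = FALSE, quantize = NULL) {
  stopifnot(is.matrix(img))
  d <- as.integer(d); Ng <- as.integer(Ng)
  if (d < 1L) stop("compute_glcm(): d must be >= 1")
  if (Ng < 2L) stop("compute_glcm(): Ng must be >= 2")
  prelevelled <- all(img == floor(img)) && min(img) >= 0 && max(img) <= Ng - 1
  if (is.null(quantize)) quantize <- !prelevelled
  q <- if (quantize) quantize_gray(img, Ng) else {
    if (!prelevelled) stop("compute_glcm(): values are not levels in 0..Ng-1")
    storage.mode(img) <- "integer"
    img
  }
  M <- nrow(q); N <- ncol(q)
  dd <- glcm_displacement(d, theta)
  dr <- dd[1]; dc <- dd[2]
  r1 <- max(1L, 1L - dr); r2 <- min(M, M - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(N, N - dc)
  if (r1 > r2 || c1 > c2) {
    stop("compute_glcm(): region smaller than the displacement (no pixel pairs)")
  }
  g1 <- q[r1:r2, c1:c2]
  g2 <- q[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  counts <- matrix(tabulate(g1 * Ng + g2 + 1L, nbins = Ng * Ng),
                   Ng, Ng, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  R <- sum(counts)
  structure(list(counts = counts, probs = counts / R,
                 d = d, theta = theta, Ng = Ng, R = R),
            class = "glcm")
}

#' GLCM contrast
#'
#' `CON = sum over (g1, g2) of (g1 - g2)^2 * P(g1, g2)`. Zero iff all mass
#' lies on the diagonal; grows with local gray-level differences.
#'
#' @param g A [compute_glcm()] object.
#' @return Non-negative contrast.
#' @export
glcm_contrast <- function(g) {
  lv <- 0:(g$Ng - 1)
  sum(outer(lv, lv, function(a, b) (a - b)^2) * g$probs)
}

#' GLCM entropy
#'
#' `ENT = -sum P * log2(P)` with `0 * log 0 := 0`; measures texture
#' complexity in bits. Maximal, `2 * log2(Ng)`, for a uniform matrix.
#'
#' @param g A [compute_glcm()] object.
#' @return Entropy in bits, >= 0.
#' @export
glcm_entropy <- function(g) {
  p <- g$probs[g$probs > 0]
  -sum(p * log2(p))
}

#' GLCM correlation
#'
#' Linear dependence of gray levels:
#' `COR = (sum g1*g2*P(g1,g2) - mu1*mu2) / (sd1*sd2)`, with `mu`, `sd` the
#' marginal means and population standard deviations of the normalized GLCM.
#' Undefined (error of class `sonovas_undefined_correlation`) when a marginal
#' standard deviation is zero, e.g. for a constant image; feature tables
#' report it as `NA`.
#'
#' @param g A [compute_glcm()] object.
#' @return Correlation in `[-1, 1]`.
#' @export
glcm_correlation <- function(g) {
  lv <- 0:(g$Ng - 1)
  pr <- rowSums(g$probs)
  pc <- colSums(g$probs)
  mu1 <- sum(lv * pr); mu2 <- sum(lv * pc)
  sd1 <- sqrt(sum(lv^2 * pr) - mu1^2)
  sd2 <- sqrt(sum(lv^2 * pc) - mu2^2)
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 1e-12 || sd2 <= 1e-12) {
    stop(structure(class = c("sonovas_undefined_correlation", "error", "condition"),
                   list(message = "glcm_correlation(): zero marginal standard deviation",
                        call = sys.call(-1))))
  }
  (sum(outer(lv, lv) * g$probs) - mu1 * mu2) / (sd1 * sd2)
}

#' GLCM energy (angular second moment)
#'
#' `ENG = sum P^2`; reflects uniformity of the gray distribution. Equals 1
#' iff all mass sits in a single cell, and `1/Ng^2` for a uniform matrix.
#' `paper_literal = TRUE` negates the value (for auditing against sources
#' that print a minus sign).
#'
#' @param g A [compute_glcm()] object.
#' @param paper_literal Negate the energy? Default `FALSE`.
#' @return Energy in `(0, 1]` (or its negative).
#' @export
glcm_energy <- function(g, paper_literal = FALSE) {
  s <- sum(g$probs^2)
  if (paper_literal) -s else s
}

#' Per-block texture feature table
#'
#' Partitions the image into `L x L` blocks and, for each block and each
#' direction, computes the first-order statistics (mean, variance) and the
#' GLCM features (contrast, entropy, correlation, energy). Correlation is
#' `NA` where undefined (constant block).
#'
#' @param img Numeric matrix with intensities in `[0, 255]`.
#' @param L Block side in pixels.
#' @param d GLCM displacement distance.
#' @param thetas Directions in degrees, subset of `c(0, 45, 90, 135)`.
#' @param Ng Gray levels for quantization.
#' @param average_thetas Average the GLCM features over directions, yielding
#'   one row per block? Default `FALSE` (one row per block-direction).
#' @param quantize Passed to [compute_glcm()].
#' @return Data frame with columns `block_row`, `block_col`, `theta`, `mean`,
#'   `variance`, `con`, `ent`, `cor`, `eng`.
#' @export
extract_features <- function(img, L = 32L, d = 1L, thetas = c(0, 45, 90, 135),
                             Ng = 8L, average_thetas = FALSE, quantize = NULL) {
  blocks <- partition_blocks(img, L)
  rows <- lapply(blocks, function(b) {
    base <- data.frame(block_row = attr(b, "block_row"),
                       block_col = attr(b, "block_col"))
    per_theta <- lapply(thetas, function(th) {
      g <- compute_glcm(b, d = d, theta = th, Ng = Ng, quantize = quantize)
      corv <- tryCatch(glcm_correlation(g),
                       sonovas_undefined_correlation = function(e) NA_real_)
      data.frame(theta = th, con = glcm_contrast(g), ent = glcm_entropy(g),
                 cor = corv, eng = glcm_energy(g))
    })
    ft <- do.call(rbind, per_theta)
    if (average_thetas) {
      ft <- data.frame(theta = NA_real_,
                       con = mean(ft$con), ent = mean(ft$ent),
                       cor = if (anyNA(ft$cor)) NA_real_ else mean(ft$cor),
                       eng = mean(ft$eng))
    }
    cbind(base[rep(1L, nrow(ft)), , drop = FALSE],
          data.frame(mean = block_mean(b), variance = block_variance(b)),
          ft)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # column order: identifiers, direction, then features
  out[, c("block_row", "block_col", "theta", "mean", "variance",
          "con", "ent", "cor", "eng")]
}
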