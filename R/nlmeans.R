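# Non-local means speckle denoiser.
#
# Each pixel p is replaced by a convex combination of the pixels q inside a
# restricted search window, with weights
#   w(p,q) = exp(-d(p,q) / h^2) / Z(p),   Z(p) = sum_q exp(-d(p,q) / h^2),
# where d(p,q) is the Gaussian-weighted squared distance between the patches
# around p and q. The Gaussian over patch offsets is normalized to sum 1, so
# the scale of h is independent of patch size.

#' Non-local means parameters
#'
#' @param h Attenuation control parameter of the exponential kernel, in gray
#'   units; larger h smooths more. Must be > 0.
#' @param patch_radius Half-width of the square patches compared (patch is
#'   `(2*patch_radius+1)^2` pixels). >= 0.
#' @param search_radius Half-width of the square search window; the window is
#'   `(2*search_radius+1)^2` pixels, clipped at image borders. Must be >=
#'   `patch_radius` is not required, only >= 0; the window restriction is
#'   what keeps the cost linear in window area.
#' @param sigma_patch Standard deviation, in pixels, of the Gaussian that
#'   weights patch offsets. > 0.
#' @param self_weight `"natural"` gives the centre pixel its kernel weight
#'   `exp(0)`; `"max_others"` replaces it by the largest weight among the
#'   other window pixels (a common variant, off by default).
#' @return An object of class `nlm_params`.
#' @export
nlm_params <- function(h = 10, patch_radius = 2L, search_radius = 10L,
                       sigma_patch = 1.0,
                       self_weight = c("natural", "max_others")) {
  self_weight <- match.arg(self_weight)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("nlm_params(): h must be a single positive number")
  }
  patch_radius <- as.integer(patch_radius)
  search_radius <- as.integer(search_radius)
  if (patch_radius < 0L) stop("nlm_params(): patch_radius must be >= 0")
  if (search_radius < 0L) stop("nlm_params(): search_radius must be >= 0")
  if (!is.finite(sigma_patch) || sigma_patch <= 0) {
    stop("nlm_params(): sigma_patch must be > 0")
  }
  structure(list(h = h, patch_radius = patch_radius,
                 search_radius = search_radius, sigma_patch = sigma_patch,
                 self_weight = self_weight),
            class = "nlm_params")
}

# Symmetric (edge-repeating) reflect padding by r pixels on every side.
pad_reflect <- function(img, r) {
  if (r == 0L) return(img)
  M <- nrow(img); N <- ncol(img)
  if (r > M || r > N) stop("pad_reflect(): radius exceeds image size")
  ridx <- c(r:1, 1:M, M:(M - r + 1L))
  cidx <- c(r:1, 1:N, N:(N - r + 1L))
  img[ridx, cidx, drop = FALSE]
}

# 1-D Gaussian over offsets -pr..pr, normalized so the separable 2-D kernel
# (outer product) sums to 1.
patch_gauss_1d <- function(pr, sigma) {
  g <- exp(-((-pr:pr)^2) / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian-weighted squared patch distance
#'
#' `d(p, q) = sum_o G(o) * (I(p + o) - I(q + o))^2` over patch offsets `o`,
#' with `G` a Gaussian normalized to sum 1 over offsets. Patches crossing the
#' image border are completed by reflect padding.
#'
#' @param img Numeric matrix.
#' @param p,q Pixel coordinates as `c(row, col)`, 1-based.
#' @param params An [nlm_params()] object.
#' @return Non-negative squared distance in gray-units^2; symmetric in (p, q).
#' @export
nlm_patch_distance <- function(img, p, q, params = nlm_params()) {
  stopifnot(is.matrix(img))
  pr <- params$patch_radius
  pad <- pad_reflect(img, pr)
  g <- patch_gauss_1d(pr, params$sigma_patch)
  K <- outer(g, g)
  Np <- pad[p[1]:(p[1] + 2L * pr), p[2]:(p[2] + 2L * pr), drop = FALSE]
  Nq <- pad[q[1]:(q[1] + 2L * pr), q[2]:(q[2] + 2L * pr), drop = FALSE]
  sum(K * (Np - Nq)^2)
}

#' Non-local means weight map at one pixel
#'
#' Computes the normalized weights `w(p, q)` over the search window centred
#' on `p` (clipped to the image), including the kernel normalizer `Z(p)`.
#'
#' @inheritParams nlm_patch_distance
#' @param p Pixel `c(row, col)`, 1-based.
#' @return A list of class `nlm_weights` with elements `p`, `rows`, `cols`
#'   (window extent), `w` (matrix of weights over the window, summing to 1)
#'   and `Z` (sum of unnormalized kernel values).
#' @export
nlm_weights <- function(img, p, params = nlm_params()) {
  stopifnot(is.matrix(img))
  M <- nrow(img); N <- ncol(img)
  R <- params$search_radius
  h2 <- params$h^2
  rows <- max(1L, p[1] - R):min(M, p[1] + R)
  cols <- max(1L, p[2] - R):min(N, p[2] + R)
  u <- matrix(NA_real_, length(rows), length(cols))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      q <- c(rows[i], cols[j])
      u[i, j] <- exp(-nlm_patch_distance(img, p, q, params) / h2)
    }
  }
  if (params$self_weight == "max_others") {
    ci <- match(p[1], rows); cj <- match(p[2], cols)
    others <- u
    others[ci, cj] <- NA_real_
    u[ci, cj] <- if (all(is.na(others))) 1 else max(others, na.rm = TRUE)
  }
  Z <- sum(u)
  structure(list(p = p, rows = rows, cols = cols, w = u / Z, Z = Z),
            class = "nlm_weights")
}

#' Denoise an image by non-local means
#'
#' Windowed non-local means with reflect-padded patch extraction. Output
#' pixels are convex combinations of window pixels, so the result stays
#' within the input range; a constant image is a fixed point.
#'
#' The implementation vectorises over window offsets: for each displacement
#' t it forms the squared-difference image against the t-shifted image and
#' convolves it (separably) with the normalized patch Gaussian, which yields
#' d(p, p + t) for all p at once.
#'
#' @param img Numeric matrix of gray intensities.
#' @param params An [nlm_params()] object.
#' @return Denoised matrix, same dimensions as `img`.
#' @export
denoise_nlmeans <- function(img, params = nlm_params()) {
  if (!is.matrix(img) || length(img) == 0L) {
    stop("denoise_nlmeans(): img must be a non-empty numeric matrix")
  }
  if (!all(is.finite(img))) stop("denoise_nlmeans(): img must be finite")
  M <- nrow(img); N <- ncol(img)
  pr <- params$patch_radius
  R <- params$search_radius
  h2 <- params$h^2
  g <- patch_gauss_1d(pr, params$sigma_patch)
  pad <- pad_reflect(img, pr)
  num <- matrix(0, M, N)
  den <- matrix(0, M, N)
  wmax <- matrix(0, M, N)
  for (dy in -R:R) {
    for (dx in -R:R) {
      if (dy == 0L && dx == 0L) next
      r1 <- max(1L, 1L - dy); r2 <- min(M, M - dy)
      c1 <- max(1L, 1L - dx); c2 <- min(N, N - dx)
      if (r1 > r2 || c1 > c2) next
      rows <- (r1 - pr):(r2 + pr)
      cols <- (c1 - pr):(c2 + pr)
      A <- pad[rows + pr, cols + pr, drop = FALSE] -
           pad[rows + pr + dy, cols + pr + dx, drop = FALSE]
      d <- conv_sep_valid(A * A, g)
      w <- exp(-d / h2)
      num[r1:r2, c1:c2] <- num[r1:r2, c1:c2] +
        w * img[(r1 + dy):(r2 + dy), (c1 + dx):(c2 + dx), drop = FALSE]
      den[r1:r2, c1:c2] <- den[r1:r2, c1:c2] + w
      wmax[r1:r2, c1:c2] <- pmax(wmax[r1:r2, c1:c2], w)
    }
  }
  wc <- if (params$self_weight == "natural") matrix(1, M, N) else {
    wmax[wmax == 0] <- 1   # degenerate 1x1 window
    wmax
  }
  num <- num + wc * img
  den <- den + wc
  num / den
}

# Separable "valid" convolution of A with the symmetric kernel g (rows then
# columns); returns a matrix shrunk by 2*pr in each dimension.
conv_sep_valid <- function(A, g) {
  k <- length(g)
  pr <- (k - 1L) %/% 2L
  if (pr == 0L) return(A * g)
  n <- nrow(A); m <- ncol(A)
  B <- matrix(0, n - 2L * pr, m)
  for (i in seq_len(k)) {
    B <- B + g[i] * A[i:(n - 2L * pr + i - 1L), , drop = FALSE]
  }
  C <- matrix(0, n - 2L * pr, m - 2L * pr)
  for (i in seq_len(k)) {
    C <- C + g[i] * B[, i:(m - 2L * pr + i - 1L), drop = FALSE]
  }
  C
}
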