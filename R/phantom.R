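# Synthetic vessel phantoms: a longitudinal B-mode-like view of a straight
# artery (near wall band, lumen, far wall band over a tissue background),
# with optional plaques protruding from the near wall into the lumen, plus a
# multiplicative-speckle + additive-Gaussian noise model. Pixel (i, j) is
# row i from the top, column j from the left; the centre of pixel i spans
# depth (i - 0.5) * pixel_size mm.

#' Vessel phantom specification
#'
#' Geometry and gray levels for a synthetic longitudinal vessel image.
#'
#' @param image_height,image_width Image size in pixels.
#' @param pixel_size Physical pixel size, mm/pixel.
#' @param wall_depth Depth of the near-wall intima surface, mm.
#' @param imt Intima-media thickness rendered for both walls, mm.
#' @param lumen_diameter Original lumen inner diameter d2, mm.
#' @param plaques List of plaques, each a list/vector with fields `center_x`
#'   (mm from the left edge), `length` (mm), `protrusion` (mm into the
#'   lumen, < `lumen_diameter`), `echo_level` (gray units in `[0, 255]`).
#' @param background_level,wall_level,lumen_level Gray levels in `[0, 255]`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height = 128L, image_width = 128L,
                         pixel_size = 0.1,
                         wall_depth = 3, imt = 0.8, lumen_diameter = 6,
                         plaques = list(),
                         background_level = 60, wall_level = 190,
                         lumen_level = 15) {
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               pixel_size = pixel_size, wall_depth = wall_depth,
               imt = imt, lumen_diameter = lumen_diameter,
               plaques = lapply(plaques, as.list),
               background_level = background_level,
               wall_level = wall_level, lumen_level = lumen_level)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  for (f in c("pixel_size", "wall_depth", "imt", "lumen_diameter")) {
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0) {
      stop("phantom_spec(): field '", f, "' must be > 0")
    }
  }
  for (f in c("background_level", "wall_level", "lumen_level")) {
    if (spec[[f]] < 0 || spec[[f]] > 255) {
      stop("phantom_spec(): field '", f, "' must lie in [0, 255]")
    }
  }
  depth_mm <- spec$image_height * spec$pixel_size
  width_mm <- spec$image_width * spec$pixel_size
  total <- spec$wall_depth + 2 * spec$imt + spec$lumen_diameter
  if (total > depth_mm) {
    stop("phantom_spec(): geometry exceeds image depth; reduce 'wall_depth', ",
         "'imt' or 'lumen_diameter' (", total, " mm > ", depth_mm, " mm)")
  }
  for (p in spec$plaques) {
    need <- c("center_x", "length", "protrusion", "echo_level")
    if (!all(need %in% names(p))) {
      stop("phantom_spec(): each plaque needs fields ",
           paste(need, collapse = ", "))
    }
    if (p$length <= 0) stop("phantom_spec(): plaque field 'length' must be > 0")
    if (p$protrusion <= 0 || p$protrusion >= spec$lumen_diameter) {
      stop("phantom_spec(): plaque field 'protrusion' must be in (0, lumen_diameter)")
    }
    if (p$echo_level < 0 || p$echo_level > 255) {
      stop("phantom_spec(): plaque field 'echo_level' must lie in [0, 255]")
    }
    if (p$center_x - p$length / 2 < 0 || p$center_x + p$length / 2 > width_mm) {
      stop("phantom_spec(): plaque field 'center_x'/'length' exceeds image width")
    }
  }
  invisible(spec)
}

#' Phantom label codes
#'
#' Integer codes used in the ground-truth label map: 0 background, 1 wall,
#' 2 lumen, 3 plaque.
#' @return Named integer vector.
#' @export
phantom_labels <- function() {
  c(background = 0L, wall = 1L, lumen = 2L, plaque = 3L)
}

#' Generate a clean vessel phantom with ground truth
#'
#' Renders the phantom deterministically (no randomness): background, two
#' wall bands of thickness `imt`, a lumen of diameter `lumen_diameter`, and
#' each plaque as a protrusion from the near wall narrowing the lumen. The
#' ground truth records, for each plaque, the true residual diameter
#' `d1 = lumen_diameter - protrusion` and the implied stenosis rate.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `vessel_phantom`: `image` (numeric matrix in
#'   `[0, 255]`), `labels` (integer matrix, see [phantom_labels()]),
#'   `geometry` (list with `imt`, `d2` and per-plaque `d1`/rate), `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  M <- spec$image_height; N <- spec$image_width
  ps <- spec$pixel_size
  depth <- (seq_len(M) - 0.5) * ps          # pixel-centre depth, mm
  x <- (seq_len(N) - 0.5) * ps              # pixel-centre lateral position, mm
  near_top <- spec$wall_depth
  lumen_top <- near_top + spec$imt
  lumen_bot <- lumen_top + spec$lumen_diameter
  far_bot <- lumen_bot + spec$imt

  lab <- matrix(phantom_labels()[["background"]], M, N)
  lab[depth >= near_top & depth < lumen_top, ] <- phantom_labels()[["wall"]]
  lab[depth >= lumen_top & depth < lumen_bot, ] <- phantom_labels()[["lumen"]]
  lab[depth >= lumen_bot & depth < far_bot, ] <- phantom_labels()[["wall"]]

  img <- matrix(spec$background_level, M, N)
  img[lab == phantom_labels()[["wall"]]] <- spec$wall_level
  img[lab == phantom_labels()[["lumen"]]] <- spec$lumen_level

  plq <- list()
  for (p in spec$plaques) {
    cols <- which(x >= p$center_x - p$length / 2 & x <= p$center_x + p$length / 2)
    rows <- which(depth >= lumen_top & depth < lumen_top + p$protrusion)
    if (length(rows) && length(cols)) {
      lab[rows, cols] <- phantom_labels()[["plaque"]]
      img[rows, cols] <- p$echo_level
    }
    d1 <- spec$lumen_diameter - p$protrusion
    plq[[length(plq) + 1L]] <- list(
      center_x = p$center_x, length = p$length, protrusion = p$protrusion,
      d1 = d1, d2 = spec$lumen_diameter,
      stenosis_rate_pct = stenosis_rate(d1, spec$lumen_diameter))
  }
  structure(list(image = img, labels = lab,
                 geometry = list(imt = spec$imt, d2 = spec$lumen_diameter,
                                 plaques = plq),
                 spec = spec),
            class = "vessel_phantom")
}

#' Speckle noise parameters
#'
#' Multiplicative unit-mean gamma speckle (a standard surrogate for
#' ultrasound speckle) plus additive Gaussian electronic noise.
#'
#' @param speckle_shape Gamma shape parameter k; the multiplier has mean 1
#'   and variance 1/k, so larger k means less speckle. `Inf` disables the
#'   multiplicative component. Must be > 0.
#' @param gaussian_sigma SD of the additive Gaussian noise, gray units, >= 0.
#' @param seed Integer RNG seed.
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(speckle_shape = 10, gaussian_sigma = 4, seed = 1L) {
  if (!(speckle_shape > 0)) stop("noise_params(): speckle_shape must be > 0")
  if (!is.finite(gaussian_sigma) || gaussian_sigma < 0) {
    stop("noise_params(): gaussian_sigma must be >= 0")
  }
  structure(list(speckle_shape = speckle_shape,
                 gaussian_sigma = gaussian_sigma,
                 seed = as.integer(seed)),
            class = "noise_params")
}

#' Add speckle and electronic noise to a clean image
#'
#' `noisy = clip(clean * m + e, 0, 255)` with `m ~ Gamma(k, rate = k)`
#' (unit mean, variance 1/k) i.i.d. per pixel and `e ~ N(0, sigma^2)`.
#' Fully reproducible from `noise$seed`.
#'
#' @param clean Numeric matrix with values in `[0, 255]`.
#' @param noise A [noise_params()] object.
#' @return Noisy matrix, clipped to `[0, 255]`.
#' @export
add_speckle <- function(clean, noise = noise_params()) {
  stopifnot(is.matrix(clean))
  if (min(clean) < 0 || max(clean) > 255) {
    stop("add_speckle(): clean image must lie in [0, 255]")
  }
  n <- length(clean)
  withr::with_seed(noise$seed, {
    m <- if (is.infinite(noise$speckle_shape)) rep(1, n) else {
      stats::rgamma(n, shape = noise$speckle_shape, rate = noise$speckle_shape)
    }
    e <- if (noise$gaussian_sigma == 0) rep(0, n) else {
      stats::rnorm(n, 0, noise$gaussian_sigma)
    }
    out <- clean * matrix(m, nrow(clean)) + matrix(e, nrow(clean))
  })
  pmin(pmax(out, 0), 255)
}

#' Read / write 8-bit grayscale PNG images
#'
#' Images are stored on disk as 8-bit grayscale PNG; in memory the package
#' uses numeric matrices in `[0, 255]`. Writing rounds to integers.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param path File path.
#' @return `read_image_png()` returns a numeric matrix in `[0, 255]`;
#'   `write_image_png()` returns `path` invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(round(pmin(pmax(img, 0), 255)) / 255, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop("read_image_png(): no such file: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]   # collapse gray-encoded-as-RGB
  round(x * 255)
}

#' Write a phantom and its ground truth to disk
#'
#' Writes `<stem>.png` (clean image), `<stem>_labels.png` (label map,
#' levels scaled by 1 gray unit per label code) and `<stem>_truth.json`
#' (true geometry: imt, d2, per-plaque d1 and stenosis rate).
#'
#' @param ph A [generate_phantom()] result.
#' @param stem Output path stem (no extension).
#' @return Invisibly, the three paths written.
#' @export
write_phantom <- function(ph, stem) {
  stopifnot(inherits(ph, "vessel_phantom"))
  paths <- c(image = paste0(stem, ".png"),
             labels = paste0(stem, "_labels.png"),
             truth = paste0(stem, "_truth.json"))
  write_image_png(ph$image, paths[["image"]])
  write_image_png(ph$labels, paths[["labels"]])
  jsonlite::write_json(ph$geometry, paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
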