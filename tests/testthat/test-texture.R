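# Block statistics and GLCM features, against hand enumeration and
# brute-force oracles.

test_that("block partition tiles row-major and drops partial tiles", {
  expect_length(partition_blocks(matrix(0, 8, 8), 4), 4)
  expect_length(partition_blocks(matrix(0, 9, 9), 4), 4)
  expect_length(partition_blocks(matrix(0, 6, 4), 2), 6)
  b <- partition_blocks(matrix(1:64, 8, 8), 4)
  expect_equal(attr(b[[2]], "block_col"), 2)
  expect_equal(attr(b[[3]], "block_row"), 2)
  expect_equal(b[[1]], matrix(1:64, 8, 8)[1:4, 1:4], ignore_attr = TRUE)
  expect_error(partition_blocks(matrix(0, 3, 3), 4), "exceeds")
  expect_error(partition_blocks(matrix(0, 8, 8), 1), ">= 2")
})

test_that("block mean and population variance match hand computation", {
  b <- matrix(c(0, 2, 4, 6), 2, 2)
  expect_equal(block_mean(b), 3)
  expect_equal(block_variance(b), 5)   # divisor L^2 = 4
  expect_equal(block_mean(matrix(9, 3, 3)), 9)
  expect_equal(block_variance(matrix(9, 3, 3)), 0)
  for (s in 1:3) {
    x <- toy_image(4, 4, seed = s)
    expect_equal(block_mean(x), sum(x) / 16)
    expect_equal(block_variance(x), sum((x - sum(x) / 16)^2) / 16)
  }
})

test_that("GLCM counts match hand enumeration on tiny images", {
  # constant image: all mass at (g, g)
  g <- compute_glcm(matrix(3, 4, 4), d = 1, theta = 0, Ng = 8, quantize = FALSE)
  expect_equal(g$probs[4, 4], 1)
  expect_equal(sum(g$probs), 1)
  # 2x2 image [[0,1],[0,1]] row-wise: the 2 horizontal pairs are both (0,1)
  m <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  g2 <- compute_glcm(m, d = 1, theta = 0, Ng = 2)
  expect_equal(g2$counts, matrix(c(0L, 0L, 2L, 0L), 2, 2))  # counts[1,2] = 2
  expect_equal(g2$probs[1, 2], 1)
  expect_equal(g2$R, 2)
  expect_error(compute_glcm(matrix(0, 1, 2), d = 5, theta = 0, Ng = 2),
               "displacement")
})

test_that("GLCM counts and features match brute-force oracles across settings", {
  for (seed in 1:2) {
    img <- toy_image(8, 8, seed = 100 + seed)
    for (d in c(1, 2)) {
      for (th in c(0, 45, 90, 135)) {
        for (Ng in c(4, 8)) {
          g <- compute_glcm(img, d = d, theta = th, Ng = Ng)
          lvl <- quantize_gray(img, Ng)
          expect_equal(g$counts, oracle_glcm_counts(lvl, d, th, Ng))
          expect_equal(sum(g$probs), 1, tolerance = 1e-12)
          o <- oracle_glcm_features(g$probs)
          expect_equal(glcm_contrast(g), o$con, tolerance = 1e-10)
          expect_equal(glcm_entropy(g), o$ent, tolerance = 1e-10)
          expect_equal(glcm_energy(g), o$eng, tolerance = 1e-10)
          if (!is.na(o$cor)) {
            expect_equal(glcm_correlation(g), o$cor, tolerance = 1e-9)
            expect_lte(abs(glcm_correlation(g)), 1 + 1e-9)
          }
        }
      }
    }
  }
})

test_that("contrast, entropy and energy agree with closed-form toy cases", {
  p01 <- structure(list(probs = matrix(c(0, 0, 1, 0), 2, 2), Ng = 2L),
                   class = "glcm")
  expect_equal(glcm_contrast(p01), 1)           # all mass at (0,1)
  expect_equal(glcm_entropy(p01), 0)
  expect_equal(glcm_energy(p01), 1)
  punif4 <- structure(list(probs = matrix(0.25, 2, 2), Ng = 2L), class = "glcm")
  expect_equal(glcm_entropy(punif4), 2)         # uniform over 4 cells: 2 bits
  expect_equal(glcm_energy(punif4), 0.25)       # 1/Ng^2
  expect_equal(glcm_energy(punif4, paper_literal = TRUE), -0.25)
})

test_that("correlation hits +/-1 for perfectly dependent matrices and errors when undefined", {
  pp <- structure(list(probs = matrix(c(0.5, 0, 0, 0.5), 2, 2), Ng = 2L),
                  class = "glcm")
  pm <- structure(list(probs = matrix(c(0, 0.5, 0.5, 0), 2, 2), Ng = 2L),
                  class = "glcm")
  expect_equal(glcm_correlation(pp), 1)
  expect_equal(glcm_correlation(pm), -1)
  gconst <- compute_glcm(matrix(5, 4, 4), Ng = 8, quantize = FALSE)
  expect_error(glcm_correlation(gconst), class = "sonovas_undefined_correlation")
})

test_that("checkerboard at d = 1, theta = 0 gives CON 1 and ENG 0.5", {
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  g <- compute_glcm(cb, d = 1, theta = 0, Ng = 2)
  # ordered pairs split evenly between (0,1) and (1,0)
  expect_equal(glcm_contrast(g), 1)
  expect_equal(glcm_energy(g), 0.5)
  expect_equal(glcm_entropy(g), 1)
})

test_that("concentrating a uniform GLCM decreases entropy and increases energy", {
  Ng <- 4
  u <- matrix(1 / Ng^2, Ng, Ng)
  for (lambda in c(0.2, 0.5, 0.9)) {
    conc <- (1 - lambda) * u
    conc[1, 1] <- conc[1, 1] + lambda   # move mass into one cell
    gu <- structure(list(probs = u, Ng = Ng), class = "glcm")
    gc <- structure(list(probs = conc, Ng = Ng), class = "glcm")
    expect_lt(glcm_entropy(gc), glcm_entropy(gu))
    expect_gt(glcm_energy(gc), glcm_energy(gu))
  }
})

test_that("feature table covers blocks x angles and handles constant blocks", {
  img <- matrix(50, 8, 8)
  f <- extract_features(img, L = 4, d = 1, thetas = c(0, 90), Ng = 8)
  expect_equal(nrow(f), 4 * 2)
  expect_true(all(f$mean == 50) && all(f$variance == 0))
  expect_true(all(f$con == 0) && all(f$ent == 0) && all(f$eng == 1))
  expect_true(all(is.na(f$cor)))
  # averaging over angles gives one row per block
  f2 <- extract_features(toy_image(8, 8, seed = 31), L = 4, Ng = 4,
                         average_thetas = TRUE)
  expect_equal(nrow(f2), 4)
  # determinism
  img3 <- toy_image(16, 16, seed = 32)
  expect_identical(extract_features(img3, L = 8), extract_features(img3, L = 8))
})

test_that("features are invariant to rescaling that preserves bin assignment", {
  Ng <- 4
  lvl <- toy_image(8, 8, seed = 33, max_gray = Ng - 1)  # levels 0..3
  # map level k to the centre of bin k on the 0..255 scale
  img <- (lvl + 0.5) * (256 / Ng)
  f1 <- extract_features(lvl, L = 4, Ng = Ng, quantize = FALSE)
  f2 <- extract_features(img, L = 4, Ng = Ng, quantize = TRUE)
  expect_equal(f1[, c("con", "ent", "cor", "eng")],
               f2[, c("con", "ent", "cor", "eng")])
})
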