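test_that("quantisation bins the 8-bit range uniformly", {
  expect_equal(quantize_levels(matrix(0L, 1, 1), 8)[1, 1], 0L)
  expect_equal(quantize_levels(matrix(255L, 1, 1), 8)[1, 1], 7L)
  expect_equal(quantize_levels(matrix(128L, 1, 1), 4)[1, 1], 2L)  # floor(128*4/256)
  v <- matrix(0:255, 16, 16)
  expect_identical(quantize_levels(v, 256), matrix(0:255, 16, 16))
})

test_that("co-occurrence counts match pair enumeration", {
  hs <- toy_level_matrix("hstripes")
  M <- compute_glcm(hs, 1, 0, 2)
  expect_equal(M[1, 2], 2)           # (0,1) twice
  expect_equal(sum(M), 2)            # only two horizontal pairs, no symmetry
  # the 4-level fixture counts pair (3,0) exactly four times at d=1, 0 deg
  f6 <- toy_level_matrix("fig6-like")
  M6 <- compute_glcm(f6, 1, 0, 4)
  expect_equal(M6[4, 1], 4)
  # constant image: all mass on one diagonal entry
  Mc <- compute_glcm(toy_level_matrix("constant4"), 1, 45, 4)
  expect_equal(Mc[3, 3], sum(Mc))
  expect_error(compute_glcm(hs, 5, 0, 2), "no pixel pairs")
  # all four offsets against the brute-force enumerator
  set.seed(8)
  lev <- matrix(sample(0:3, 100, TRUE), 10, 10)
  for (a in c(0, 45, 90, 135))
    expect_equal(compute_glcm(lev, 2, a, 4), oracle_glcm(lev, 2, a, 4))
})

test_that("Haralick features hit their closed forms on atomic GLCMs", {
  # single-atom distribution (constant image)
  one <- matrix(0, 3, 3); one[2, 2] <- 5
  f <- haralick13(glcm_profile(one))
  expect_equal(unname(f["F1"]), 1)
  expect_equal(unname(f["F2"]), 0)
  expect_equal(unname(f["F9"]), 0)
  # all mass on (0,1): contrast = 1
  od <- matrix(0, 2, 2); od[1, 2] <- 3
  expect_equal(unname(haralick13(glcm_profile(od))["F2"]), 1)
  # uniform 2x2: F1 = 0.25, entropy = ln 4 (natural-log convention)
  u <- matrix(1, 2, 2)
  fu <- haralick13(glcm_profile(u))
  expect_equal(unname(fu["F1"]), 0.25)
  expect_equal(unname(fu["F9"]), log(4))
  expect_error(glcm_profile(matrix(0, 2, 2)), "all-zero")
})

test_that("haralick13 equals the brute-force oracle on random images", {
  set.seed(42)
  for (rep in 1:6) {
    lev <- matrix(sample(0:3, 64, TRUE), 8, 8)
    M <- compute_glcm(lev, 1, sample(c(0, 45, 90, 135), 1), 4)
    prof <- glcm_profile(M)
    expect_equal(sum(prof$p), 1, tolerance = 1e-12)
    expect_equal(unname(haralick13(prof)), oracle_haralick(M),
                 tolerance = 1e-10)
  }
})

test_that("Haralick ranges hold on random non-degenerate GLCMs", {
  set.seed(7)
  for (rep in 1:10) {
    M <- matrix(rpois(16, 3), 4, 4) + 1
    f <- haralick13(glcm_profile(M))
    expect_gt(f["F1"], 0); expect_lte(f["F1"], 1)
    expect_gte(f["F9"], 0)
    expect_gte(f["F3"], -1); expect_lte(f["F3"], 1)
  }
})

test_that("direction-averaged GLCM vector has 13 features and rotates cleanly", {
  set.seed(3)
  img <- image8(matrix(sample(0:255, 64^2, TRUE), 64, 64))
  v <- glcm_feature_vector(img)
  expect_length(v, 13)
  # 90-degree rotation permutes the angle set (two directions reverse, and
  # every feature is transpose-invariant), so the average is unchanged
  rot <- image8(t(matrix(as.numeric(img), 64, 64))[64:1, ])
  expect_equal(glcm_feature_vector(rot), v, tolerance = 1e-10)
  # constant image: zero contrast and variance components
  vc <- glcm_feature_vector(image8(matrix(100L, 64, 64)))
  expect_equal(unname(vc["F2"]), 0)
  expect_equal(unname(vc["F4"]), 0)
})

test_that("HOG descriptor has length 36 with the tuned parameters", {
  img <- image8(matrix(sample(0:255, 64^2, TRUE), 64, 64))
  expect_length(hog_feature_vector(img), 36)
  expect_error(hog_feature_vector(image8(matrix(0L, 60, 60))),
               "divisible")
})

test_that("HOG of a constant image is identically zero", {
  v <- hog_feature_vector(image8(matrix(123L, 64, 64)))
  expect_true(all(v == 0))
})

test_that("HOG is shift-invariant and scale-stable", {
  set.seed(9)
  base <- matrix(sample(40:180, 64^2, TRUE), 64, 64)
  v1 <- hog_feature_vector(image8(base))
  v2 <- hog_feature_vector(image8(base + 30))   # gradients unchanged
  expect_equal(v1, v2, tolerance = 1e-12)
  # global intensity scaling only rescales magnitudes; after block
  # normalisation the descriptor is recovered up to the epsilon constant
  half <- hog_feature_vector(image8(round(base / 2)))
  expect_lt(max(abs(half - v1)), 0.02)
})

test_that("a vertical step edge concentrates HOG mass at 0/180 degrees", {
  img <- matrix(0, 64, 64); img[, 33:64] <- 200
  v <- hog_feature_vector(image8(img))
  hist9 <- matrix(v, nrow = 9)          # 4 cell histograms in the block
  mass <- rowSums(hist9)
  # horizontal gradient -> orientation 0 deg, shared by the two bins
  # adjacent to the 0/180 wrap under linear bin interpolation
  expect_gt((mass[1] + mass[9]) / sum(mass), 0.999)
  # independent brute-force oracle: Sobel + soft binning by explicit loops
  oracle_hog_cells <- function(x, nb = 9, cell = 32) {
    h <- nrow(x); w <- ncol(x)
    xp <- x[c(1, 1:h, h), c(1, 1:w, w)]
    hist_ <- array(0, c(nb, h / cell, w / cell))
    for (r in 1:h) for (c in 1:w) {
      gx <- sum(xp[r:(r + 2), c + 2] * c(1, 2, 1)) -
        sum(xp[r:(r + 2), c] * c(1, 2, 1))
      gy <- sum(xp[r + 2, c:(c + 2)] * c(1, 2, 1)) -
        sum(xp[r, c:(c + 2)] * c(1, 2, 1))
      m <- sqrt(gx^2 + gy^2)
      if (m == 0) next
      a <- (atan2(gy, gx) * 180 / pi) %% 180
      pos <- a / (180 / nb) - 0.5
      lo <- floor(pos); fr <- pos - lo
      b1 <- (lo %% nb) + 1; b2 <- ((lo + 1) %% nb) + 1
      ci <- (r - 1) %/% cell + 1; cj <- (c - 1) %/% cell + 1
      hist_[b1, ci, cj] <- hist_[b1, ci, cj] + m * (1 - fr)
      hist_[b2, ci, cj] <- hist_[b2, ci, cj] + m * fr
    }
    hist_
  }
  oh <- oracle_hog_cells(img)
  raw <- c(oh[, 1, 1], oh[, 2, 1], oh[, 1, 2], oh[, 2, 2])
  expect_equal(v, raw / sqrt(sum(raw^2) + 1e-12), tolerance = 1e-10)
})

test_that("LBP codes follow the inclusive threshold and bit order", {
  const <- matrix(50, 11, 11)
  expect_equal(lbp_code(const, 6, 6, lbp_config(p = 8, r = 1)), 255)
  expect_equal(lbp_code(const, 6, 6, lbp_config(p = 8, r = 5)), 255)
  m <- matrix(0, 11, 11); m[6, 6] <- 255
  expect_equal(lbp_code(m, 6, 6, lbp_config(p = 8, r = 1)), 0)
  # single raised neighbour: right -> bit 0, up -> bit 2 (counter-clockwise);
  # the centre is high enough that bilinearly contaminated diagonal samples
  # stay below it
  m2 <- matrix(0, 11, 11); m2[6, 6] <- 100; m2[6, 7] <- 200
  expect_equal(lbp_code(m2, 6, 6, lbp_config(p = 8, r = 1)), 1)
  m3 <- matrix(0, 11, 11); m3[6, 6] <- 100; m3[5, 6] <- 200
  expect_equal(lbp_code(m3, 6, 6, lbp_config(p = 8, r = 1)), 4)
  expect_error(lbp_code(m3, 1, 1, lbp_config(p = 8, r = 1)), "border")
})

test_that("uniform-LBP bin counts reproduce the p(p-1)+3 series", {
  expect_equal(lbp_bin_count(8), 59)
  expect_equal(lbp_bin_count(12), 135)
  expect_equal(vapply(7:12, lbp_bin_count, integer(1)),
               c(45L, 59L, 75L, 93L, 113L, 135L))
  expect_length(lbp_feature_vector(image8(matrix(sample(0:255, 4096, TRUE),
                                                 64, 64))), 59)
})

test_that("LBP histogram is normalised and a constant image is all-ones code", {
  h <- lbp_feature_vector(image8(matrix(77L, 64, 64)))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  tab <- mgmtfuse:::lbp_code_table(8)
  expect_equal(h[tab[256]], 1)   # code 255 (all ones) is uniform
  expect_error(lbp_feature_vector(image8(matrix(0L, 8, 8)),
                                  lbp_config(p = 8, r = 5)), "smaller")
})

test_that("LBP is invariant to monotone intensity transforms", {
  set.seed(21)
  img <- matrix(sample(0:255, 32^2, TRUE), 32, 32)
  # affine positive maps commute with bilinear sampling: exact at any p, r
  # (the descriptor accepts any numeric matrix, so no re-rounding here)
  h0 <- lbp_feature_vector(img)
  h1 <- lbp_feature_vector(img * 0.7 + 30)
  expect_equal(h0, h1, tolerance = 1e-12)
  # arbitrary strictly monotone maps: exact when the sampling geometry is
  # integer-valued (p = 4 places all neighbours on the pixel grid)
  cfg4 <- lbp_config(p = 4, r = 2)
  for (rep in 1:5) {
    lut <- cumsum(runif(256, 0.01, 1))
    mono <- matrix(lut[img + 1], 32, 32)
    expect_equal(lbp_feature_vector(img, cfg4),
                 lbp_feature_vector(mono, cfg4), tolerance = 1e-12)
  }
})
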