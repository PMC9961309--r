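# Shared fixtures built in code at test time.

# A small separable two-class image set: class 0 carries a bright left
# half, class 1 a bright right half, plus mild noise.
make_separable_images <- function(n_per_class, side = 16L, seed = 99L) {
  set.seed(seed)
  n <- 2L * n_per_class
  images <- matrix(0, n, side^2)
  labels <- integer(n)
  for (i in seq_len(n)) {
    cls <- as.integer(i > n_per_class)
    base <- matrix(40, side, side)
    if (cls == 0L) base[, seq_len(side %/% 2)] <- 200
    else base[, (side %/% 2 + 1L):side] <- 200
    img <- pmin(pmax(base + matrix(rnorm(side^2, sd = 10), side), 0), 255)
    images[i, ] <- as.numeric(img)
    labels[i] <- cls
  }
  list(images = images, labels = labels, side = side)
}

# Write a tiny two-class PNG tree for directory-level tests.
write_png_dataset <- function(root, n0 = 3L, n1 = 2L, side = 8L,
                              n_blank0 = 0L, seed = 5L) {
  set.seed(seed)
  for (cls in c("0", "1")) dir.create(file.path(root, cls), recursive = TRUE,
                                      showWarnings = FALSE)
  mk <- function(blank) {
    if (blank) matrix(0, side, side)
    else matrix(sample(0:255, side^2, replace = TRUE) / 255, side, side)
  }
  for (i in seq_len(n0))
    png::writePNG(mk(i <= n_blank0),
                  file.path(root, "0", sprintf("s%02d.png", i)))
  for (i in seq_len(n1))
    png::writePNG(mk(FALSE), file.path(root, "1", sprintf("s%02d.png", i)))
  root
}

# Independent brute-force Haralick oracle: explicit double loops over the
# feature formulas, no shared code with the implementation.
oracle_haralick <- function(M) {
  p <- M / sum(M)
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- 0; mu_y <- 0
  for (i in 1:ng) mu_x <- mu_x + i * px[i]
  for (j in 1:ng) mu_y <- mu_y + j * py[j]
  sd_x <- sqrt(sum((1:ng - mu_x)^2 * px))
  sd_y <- sqrt(sum((1:ng - mu_y)^2 * py))
  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  lg <- function(x) if (x > 0) log(x) else 0
  F1 <- 0; F2 <- 0; F3n <- 0; F4 <- 0; F5 <- 0; F9 <- 0
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    F1 <- F1 + p[i, j]^2
    F3n <- F3n + i * j * p[i, j]
    F4 <- F4 + ((i - mu_x)^2 + (j - mu_y)^2) / 2 * p[i, j]
    F5 <- F5 + p[i, j] / (1 + (i - j)^2)
    F9 <- F9 - p[i, j] * lg(p[i, j])
    HXY1 <- HXY1 - p[i, j] * lg(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  for (n in 0:(ng - 1)) F2 <- F2 + n^2 * pdif[n + 1]
  F3 <- if (sd_x > 0 && sd_y > 0) (F3n - mu_x * mu_y) / (sd_x * sd_y) else 0
  F6 <- 0; F7 <- 0; F8 <- 0
  for (k in 2:(2 * ng)) F8 <- F8 - psum[k] * lg(psum[k])
  for (k in 2:(2 * ng)) {
    F6 <- F6 + k * psum[k]
    F7 <- F7 + (k - F8)^2 * psum[k]
  }
  mu_d <- 0
  for (n in 0:(ng - 1)) mu_d <- mu_d + n * pdif[n + 1]
  F10 <- 0; F11 <- 0
  for (n in 0:(ng - 1)) {
    F10 <- F10 + (n - mu_d)^2 * pdif[n + 1]
    F11 <- F11 - pdif[n + 1] * lg(pdif[n + 1])
  }
  HX <- 0; HY <- 0
  for (i in 1:ng) HX <- HX - px[i] * lg(px[i])
  for (j in 1:ng) HY <- HY - py[j] * lg(py[j])
  HXY <- F9
  F12 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  F13 <- sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0))
  c(F1, F2, F3, F4, F5, F6, F7, F8, F9, F10, F11, F12, F13)
}

# Brute-force GLCM by pair enumeration.
oracle_glcm <- function(lev, d, angle, ng) {
  off <- switch(as.character(angle), `0` = c(0, d), `45` = c(-d, d),
                `90` = c(-d, 0), `135` = c(-d, -d))
  M <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nrow(lev) && c2 >= 1 && c2 <= ncol(lev))
      M[lev[r, c] + 1, lev[r2, c2] + 1] <- M[lev[r, c] + 1, lev[r2, c2] + 1] + 1
  }
  M
}
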