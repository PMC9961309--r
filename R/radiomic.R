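#' GLCM configuration
#'
#' Co-occurrence statistics at pixel offset distance `d` over the four
#' standard angles (0, 45, 90, 135 degrees), counted once (no symmetric
#' double-counting). Intensities are first quantised to `n_levels` gray
#' levels.
#'
#' @param d offset distance in pixels (default 3, the tuned optimum).
#' @param n_levels number of gray levels (2..256, default 8).
#' @param angles angle set in degrees.
#' @return a `glcm_config` list.
#' @export
glcm_config <- function(d = 3L, n_levels = 8L, angles = c(0, 45, 90, 135)) {
  stopifnot(d >= 1, n_levels >= 2, n_levels <= 256,
            all(angles %in% c(0, 45, 90, 135)))
  structure(list(d = as.integer(d), n_levels = as.integer(n_levels),
                 angles = angles), class = "glcm_config")
}

#' Quantise an 8-bit image to N_g gray levels
#'
#' Uniform binning of \[0, 255\] into levels `0 .. N_g - 1`
#' (`floor(v * N_g / 256)`); `N_g = 256` is the identity.
#'
#' @param img an [image8] (or integer matrix in \[0, 255\]).
#' @param n_levels number of levels N_g.
#' @return integer matrix of levels.
#' @export
quantize_levels <- function(img, n_levels = 8L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop2("quantize_levels: n_levels must be >= 2")
  matrix(pmin(as.integer(floor(as.numeric(img) * n_levels / 256)),
              n_levels - 1L), nrow(img), ncol(img))
}

glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         `0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L),
         `135` = c(-d, -d),
         stop2("compute_glcm: angle must be one of 0, 45, 90, 135"))
}

#' Co-occurrence count matrix at one offset
#'
#' `M(i, j)` counts ordered pairs (level `i` at a pixel, level `j` at the
#' pixel displaced by `(d, theta)`). Pairs falling outside the image are
#' skipped; there is no symmetric double-counting. Offsets in (row, col)
#' terms: 0 deg -> (0, d), 45 -> (-d, d), 90 -> (-d, 0), 135 -> (-d, -d).
#'
#' @param levels integer level matrix from [quantize_levels()].
#' @param d offset distance.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param n_levels matrix size (defaults to `max(levels) + 1`).
#' @return `n_levels` x `n_levels` count matrix.
#' @export
compute_glcm <- function(levels, d, angle, n_levels = max(levels) + 1L) {
  h <- nrow(levels); w <- ncol(levels)
  off <- glcm_offset(angle, as.integer(d))
  rows <- seq_len(h); cols <- seq_len(w)
  r2 <- rows + off[1]; c2 <- cols + off[2]
  rok <- rows[r2 >= 1L & r2 <= h]; cok <- cols[c2 >= 1L & c2 <= w]
  if (length(rok) == 0L || length(cok) == 0L)
    stop2("compute_glcm: offset distance ", d, " leaves no pixel pairs")
  i <- levels[rok, cok, drop = FALSE]
  j <- levels[rok + off[1], cok + off[2], drop = FALSE]
  counts <- tabulate(as.vector(i) * n_levels + as.vector(j) + 1L,
                     nbins = n_levels^2)
  matrix(counts, n_levels, n_levels, byrow = TRUE)
}

#' Normalised GLCM profile
#'
#' Normalises a count matrix by its total so that `sum(p) = 1` and derives
#' the marginals used by the Haralick features: `p_x`, `p_y`, the diagonal
#' sums `p_{x+y}` and difference sums `p_{x-y}`.
#'
#' @param M count matrix from [compute_glcm()].
#' @return a `glcm_profile` list.
#' @export
glcm_profile <- function(M) {
  tot <- sum(M)
  if (tot == 0) stop2("glcm_profile: empty (all-zero) GLCM")
  p <- M / tot
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  pxy_sum <- as.numeric(tapply(as.vector(p), as.vector(i + j), sum))
  pxy_dif <- as.numeric(tapply(as.vector(p), as.vector(abs(i - j)), sum))
  # index supports: i + j in 2..2*ng ; |i - j| in 0..(ng - 1)
  sum_support <- sort(unique(as.vector(i + j)))
  dif_support <- sort(unique(as.vector(abs(i - j))))
  p_sum <- numeric(2 * ng); p_sum[sum_support] <- pxy_sum
  p_dif <- numeric(ng); p_dif[dif_support + 1L] <- pxy_dif
  structure(list(p = p, n_levels = ng,
                 px = rowSums(p), py = colSums(p),
                 p_sum = p_sum,      # indexed 1..2*ng, mass on 2..2*ng
                 p_dif = p_dif),     # indexed 1..ng for |i-j| = 0..ng-1
            class = "glcm_profile")
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)  # 0 log 0 := 0

#' The 13 Haralick features of a GLCM profile
#'
#' Angular second moment, contrast, correlation, variance, inverse
#' difference moment, sum average/variance/entropy, entropy, difference
#' variance/entropy, and the two information measures of correlation.
#' Natural logarithms throughout; `0 * log 0` is treated as 0; the radicand
#' of F13 is clamped at 0 and F12 is defined 0 when `max(HX, HY) = 0`.
#'
#' @param prof a [glcm_profile()].
#' @return named numeric vector `F1 .. F13`.
#' @export
haralick13 <- function(prof) {
  p <- prof$p; ng <- prof$n_levels
  px <- prof$px; py <- prof$py
  p_sum <- prof$p_sum; p_dif <- prof$p_dif
  i <- row(p); j <- col(p)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  F1 <- sum(p^2)
  ndif <- 0:(ng - 1)
  F2 <- sum(ndif^2 * p_dif)
  F3 <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y) else 0
  # dispersion of the gray levels, symmetrised over the two margins so the
  # feature is invariant to transposing the co-occurrence matrix
  F4 <- (sd_x^2 + sd_y^2) / 2
  F5 <- sum(p / (1 + (i - j)^2))
  ks <- 2:(2 * ng)
  F6 <- sum(ks * p_sum[ks])
  F8 <- -sum(xlogx(p_sum[ks]))
  F7 <- sum((ks - F8)^2 * p_sum[ks])
  F9 <- -sum(xlogx(p))
  F10 <- {
    mu_d <- sum(ndif * p_dif)
    sum((ndif - mu_d)^2 * p_dif)
  }
  F11 <- -sum(xlogx(p_dif))
  HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py))
  pxpy <- outer(px, py)
  HXY <- F9
  HXY1 <- -sum(p * ifelse(pxpy > 0, log(pxpy), 0))
  HXY2 <- -sum(xlogx(pxpy))
  F12 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  F13 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  c(F1 = F1, F2 = F2, F3 = F3, F4 = F4, F5 = F5, F6 = F6, F7 = F7,
    F8 = F8, F9 = F9, F10 = F10, F11 = F11, F12 = F12, F13 = F13)
}

#' Direction-averaged GLCM feature vector
#'
#' Computes the 13 Haralick features per direction at distance `d` and
#' arithmetically averages them over the four angles, giving `x_GLCM`
#' (length 13).
#'
#' @param img an [image8].
#' @param cfg a [glcm_config()].
#' @return named 13-vector.
#' @export
glcm_feature_vector <- function(img, cfg = glcm_config()) {
  lev <- quantize_levels(img, cfg$n_levels)
  per_dir <- vapply(cfg$angles, function(a) {
    haralick13(glcm_profile(compute_glcm(lev, cfg$d, a, cfg$n_levels)))
  }, numeric(13))
  rowMeans(per_dir)
}

#' HOG configuration
#'
#' Unsigned orientations (9 bins over 0-180 degrees), 32x32-pixel cells,
#' 2x2-cell blocks with a one-cell stride, L2 block normalisation with
#' constant epsilon. On a 64x64 input this yields exactly one block and a
#' 36-long descriptor.
#'
#' @param bins number of orientation bins.
#' @param cell_side cell side in pixels.
#' @param block_cells block side in cells.
#' @param eps normalisation constant.
#' @return a `hog_config` list.
#' @export
hog_config <- function(bins = 9L, cell_side = 32L, block_cells = 2L,
                       eps = 1e-6) {
  stopifnot(bins >= 2, cell_side >= 2, block_cells >= 1, eps > 0)
  structure(list(bins = as.integer(bins), cell_side = as.integer(cell_side),
                 block_cells = as.integer(block_cells), eps = eps),
            class = "hog_config")
}

sobel_gradients <- function(x) {
  h <- nrow(x); w <- ncol(x)
  # replicate borders so a constant image has identically zero gradients
  xp <- x[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  sub <- function(dr, dc) xp[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  gx <- (sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))
  gy <- (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1))
  list(gx = gx, gy = gy)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Sobel gradients per pixel; magnitude-weighted, linearly interpolated
#' orientation histograms (unsigned, 0-180 degrees) per cell; blocks of
#' cells normalised by `T / sqrt(||T||^2 + eps^2)` and concatenated.
#'
#' @param img an [image8] whose side is divisible by the cell side.
#' @param cfg a [hog_config()].
#' @return numeric descriptor (length 36 on 64x64 defaults).
#' @export
hog_feature_vector <- function(img, cfg = hog_config()) {
  h <- nrow(img); w <- ncol(img)
  if (h %% cfg$cell_side != 0 || w %% cfg$cell_side != 0)
    stop2("hog_feature_vector: image side not divisible by cell side")
  g <- sobel_gradients(matrix(as.numeric(img), h, w))
  mag <- sqrt(g$gx^2 + g$gy^2)
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang <- ang %% 180                       # unsigned orientation in [0, 180)

  nb <- cfg$bins; bw <- 180 / nb
  centers <- (seq_len(nb) - 0.5) * bw
  # soft binning between the two nearest bin centres with circular wrap
  pos <- ang / bw - 0.5
  lo <- floor(pos)
  frac <- pos - lo
  bin_lo <- (lo %% nb) + 1L
  bin_hi <- ((lo + 1) %% nb) + 1L

  cr <- (row(mag) - 1L) %/% cfg$cell_side
  cc <- (col(mag) - 1L) %/% cfg$cell_side
  n_cr <- h %/% cfg$cell_side; n_cc <- w %/% cfg$cell_side
  cell_id <- cr + cc * n_cr               # 0-based, column-major cells

  acc <- function(bin, wgt) {
    key <- cell_id * nb + (bin - 1L) + 1L
    v <- numeric(n_cr * n_cc * nb)
    t <- tapply(wgt, key, sum)
    v[as.integer(names(t))] <- t
    v
  }
  hist_all <- acc(bin_lo, mag * (1 - frac)) + acc(bin_hi, mag * frac)
  cells <- matrix(hist_all, nrow = nb)    # bins x cells (column-major cells)

  bc <- cfg$block_cells
  n_br <- n_cr - bc + 1L; n_bc <- n_cc - bc + 1L
  if (n_br < 1L || n_bc < 1L)
    stop2("hog_feature_vector: block larger than the cell grid")
  out <- numeric(0)
  for (bcj in seq_len(n_bc)) for (bci in seq_len(n_br)) {
    ids <- as.vector(outer((bci - 1L):(bci + bc - 2L),
                           ((bcj - 1L):(bcj + bc - 2L)) * n_cr, `+`)) + 1L
    v <- as.vector(cells[, ids])
    out <- c(out, v / sqrt(sum(v^2) + cfg$eps^2))
  }
  out
}

#' LBP configuration
#'
#' Uniform (u2) local binary patterns with `p` circular neighbours at
#' radius `r`, computed over the whole image (single cell) and normalised.
#' The histogram has `p * (p - 1) + 3` bins: every uniform code (at most
#' two circular 0/1 transitions) gets its own bin plus one bin pooling all
#' non-uniform codes.
#'
#' @param p number of sampling points (default 8).
#' @param r circle radius in pixels (default 5, the tuned optimum).
#' @return an `lbp_config` list.
#' @export
lbp_config <- function(p = 8L, r = 5L) {
  stopifnot(p >= 4, r >= 1)
  structure(list(p = as.integer(p), r = as.integer(r)), class = "lbp_config")
}

#' Number of uniform-LBP histogram bins
#'
#' @param p number of sampling points.
#' @return `p * (p - 1) + 3`.
#' @export
lbp_bin_count <- function(p) p * (p - 1L) + 3L

# Circular bit transitions of a p-bit code.
lbp_transitions <- function(code, p) {
  bits <- as.integer(intToBits(code))[seq_len(p)]
  sum(bits != bits[c(2:p, 1)])
}

# Map each 0..2^p-1 code to a histogram bin: uniform codes in ascending
# order take bins 1..(p(p-1)+2); all non-uniform codes share the last bin.
lbp_code_table <- function(p) {
  codes <- 0:(2^p - 1)
  uni <- vapply(codes, lbp_transitions, integer(1), p = p) <= 2L
  table_ <- integer(2^p)
  table_[uni] <- seq_len(sum(uni))
  table_[!uni] <- sum(uni) + 1L
  table_
}

#' LBP code of one pixel
#'
#' Samples `p` points on the radius-`r` circle around the centre (angular
#' origin at the rightmost point, counter-clockwise; bilinear interpolation
#' at non-integer coordinates), thresholds by `H(G_p - G_c)` with
#' `H(x) = 1` for `x >= 0`, and weights bit `k` by `2^k`.
#'
#' @param img numeric matrix.
#' @param row,col centre coordinates (must be at distance >= r from border).
#' @param cfg an [lbp_config()].
#' @return integer code in `0 .. 2^p - 1`.
#' @export
lbp_code <- function(img, row, col, cfg = lbp_config()) {
  h <- nrow(img); w <- ncol(img)
  if (row - cfg$r < 1 || row + cfg$r > h || col - cfg$r < 1 || col + cfg$r > w)
    stop2("lbp_code: centre closer than r to the border")
  ang <- 2 * pi * (0:(cfg$p - 1)) / cfg$p
  dc <- cfg$r * cos(ang)
  dr <- -cfg$r * sin(ang)   # counter-clockwise with rows growing downward
  gc <- img[row, col]
  val <- vapply(seq_len(cfg$p), function(k) {
    bilinear_at(img, row + dr[k], col + dc[k])
  }, numeric(1))
  sum(as.integer(val - gc >= -1e-9) * 2^(0:(cfg$p - 1)))
}

bilinear_at <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- min(r0 + 1, nrow(img)); c1 <- min(c0 + 1, ncol(img))
  (1 - fr) * (1 - fc) * img[r0, c0] + (1 - fr) * fc * img[r0, c1] +
    fr * (1 - fc) * img[r1, c0] + fr * fc * img[r1, c1]
}

#' Uniform-LBP histogram descriptor
#'
#' Codes are computed for every interior pixel (a border of width `r` is
#' excluded) and pooled into the uniform-pattern histogram, normalised to
#' sum 1. Because the threshold depends only on the sign of intensity
#' differences, the descriptor is invariant to any strictly monotone
#' intensity transform.
#'
#' @param img an [image8] at least `(2r + 1)` on each side.
#' @param cfg an [lbp_config()].
#' @return normalised histogram of length `p * (p - 1) + 3`.
#' @export
lbp_feature_vector <- function(img, cfg = lbp_config()) {
  h <- nrow(img); w <- ncol(img)
  r <- cfg$r; p <- cfg$p
  if (h < 2 * r + 1 || w < 2 * r + 1)
    stop2("lbp_feature_vector: image smaller than (2r+1) x (2r+1)")
  x <- matrix(as.numeric(img), h, w)
  ang <- 2 * pi * (0:(p - 1)) / p
  dc <- r * cos(ang); dr <- -r * sin(ang)
  rows <- (r + 1):(h - r); cols <- (r + 1):(w - r)
  ctr_r <- rep(rows, times = length(cols))
  ctr_c <- rep(cols, each = length(rows))
  gc <- x[cbind(ctr_r, ctr_c)]
  codes <- integer(length(gc))
  for (k in seq_len(p)) {
    rr <- ctr_r + dr[k]; cc <- ctr_c + dc[k]
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
    v <- (1 - fr) * (1 - fc) * x[cbind(r0, c0)] +
      (1 - fr) * fc * x[cbind(r0, c1)] +
      fr * (1 - fc) * x[cbind(r1, c0)] +
      fr * fc * x[cbind(r1, c1)]
    codes <- codes + as.integer(v - gc >= -1e-9) * 2L^(k - 1L)
  }
  tab <- lbp_code_table(p)
  nbin <- lbp_bin_count(p)
  hist_ <- tabulate(tab[codes + 1L], nbins = nbin)
  hist_ / sum(hist_)
}
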