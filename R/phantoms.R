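#' Two-class texture phantom specification
#'
#' Deterministic synthetic slices standing in for real MRI data so the whole
#' pipeline can be exercised without any download. Class 0 is an isotropic
#' Gaussian random field with correlation length `l0`; class 1 is an
#' oriented sinusoidal grating plus a shorter-range field (`l1`), so the
#' grating orientation informs the gradient descriptor, the correlation
#' length the co-occurrence statistics, and the micro-pattern density the
#' binary-pattern histogram. A fixed fraction of all-zero (blank) slices is
#' injected per class to exercise the rejection filter. All randomness flows
#' from `seed` via a per-image counter, so generation is reproducible
#' image-by-image.
#'
#' @param n_per_class images per class (default 200).
#' @param side image side in pixels.
#' @param blank_frac fraction of blank slices per class in \[0, 1).
#' @param l0,l1 Gaussian-field correlation lengths (pixels) for class 0 / 1.
#' @param grating_freq grating frequency, cycles per pixel.
#' @param grating_angle grating orientation in degrees.
#' @param grating_amp grating amplitude in gray levels.
#' @param field_sd field standard deviation in gray levels.
#' @param noise_sd additive white-noise standard deviation.
#' @param mean_level mean gray level of non-blank slices.
#' @param seed master seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(n_per_class = 200L, side = 64L, blank_frac = 0.1,
                         l0 = 6, l1 = 1.5, grating_freq = 0.15,
                         grating_angle = 45, grating_amp = 45,
                         field_sd = 30, noise_sd = 8, mean_level = 120,
                         seed = 1L) {
  stopifnot(n_per_class > 0, blank_frac >= 0, blank_frac < 1, side >= 16)
  structure(list(n_per_class = as.integer(n_per_class),
                 side = as.integer(side), blank_frac = blank_frac,
                 l0 = l0, l1 = l1, grating_freq = grating_freq,
                 grating_angle = grating_angle, grating_amp = grating_amp,
                 field_sd = field_sd, noise_sd = noise_sd,
                 mean_level = mean_level, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Gaussian random field: white noise smoothed by a separable Gaussian,
# restandardised to the requested sd.
gaussian_field <- function(side, corr_len, sd_target) {
  z <- matrix(stats::rnorm(side * side), side, side)
  if (corr_len > 0) {
    z <- gaussian_blur_1d(z, corr_len, "rows")
    z <- gaussian_blur_1d(z, corr_len, "cols")
  }
  s <- stats::sd(as.vector(z))
  if (s == 0) return(matrix(0, side, side))
  (z - mean(z)) / s * sd_target
}

phantom_image_seed <- function(spec, class, i) {
  (spec$seed %% 1000003L) * 2000L + class * 1000L + (i %% 1000L)
}

#' Generate one phantom slice in memory
#'
#' @param spec a [phantom_spec()].
#' @param class 0 or 1.
#' @param i image counter within the class (1-based; drives the per-image
#'   seed).
#' @return an [image8].
#' @export
generate_phantom_image <- function(spec, class, i) {
  set.seed(phantom_image_seed(spec, class, i))
  s <- spec$side
  if (class == 0L) {
    x <- spec$mean_level + gaussian_field(s, spec$l0, spec$field_sd)
  } else {
    a <- spec$grating_angle * pi / 180
    rr <- matrix(rep(seq_len(s), s), s, s)
    cc <- t(rr)
    grating <- spec$grating_amp *
      sin(2 * pi * spec$grating_freq * (cc * cos(a) + rr * sin(a)))
    x <- spec$mean_level + grating + gaussian_field(s, spec$l1, spec$field_sd / 2)
  }
  x <- x + stats::rnorm(s * s, sd = spec$noise_sd)
  image8(pmin(pmax(x, 1), 255))  # floor 1: non-blank slices never sum to 0
}

#' Write a phantom dataset to disk
#'
#' Writes PNGs under `out/0` and `out/1`, injecting exactly
#' `round(blank_frac * n_per_class)` all-zero slices per class (the last
#' indices of each class), and returns the dataset index.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory.
#' @return a `dataset_index` over the written files.
#' @export
generate_phantoms <- function(spec, out_dir) {
  n_blank <- round(spec$blank_frac * spec$n_per_class)
  for (cls in c(0L, 1L)) {
    d <- file.path(out_dir, as.character(cls))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(spec$n_per_class)) {
      img <- if (i > spec$n_per_class - n_blank)
        image8(matrix(0L, spec$side, spec$side))
      else generate_phantom_image(spec, cls, i)
      png::writePNG(unclass(img) / 255,
                    file.path(d, sprintf("phantom_%d_%04d.png", cls, i)))
    }
  }
  index_dataset(out_dir)
}

#' Generate the phantom dataset in memory
#'
#' Same content as [generate_phantoms()] without touching disk: returns the
#' pixel matrix, labels, and the blank-slice indicator.
#'
#' @param spec a [phantom_spec()].
#' @return list with `images` (n x side^2 matrix), `labels`, `blank`.
#' @export
generate_phantom_matrix <- function(spec) {
  n_blank <- round(spec$blank_frac * spec$n_per_class)
  n <- 2L * spec$n_per_class
  images <- matrix(0, n, spec$side^2)
  labels <- integer(n); blank <- logical(n)
  row <- 0L
  for (cls in c(0L, 1L)) for (i in seq_len(spec$n_per_class)) {
    row <- row + 1L
    labels[row] <- cls
    if (i > spec$n_per_class - n_blank) {
      blank[row] <- TRUE
    } else {
      images[row, ] <- as.numeric(generate_phantom_image(spec, cls, i))
    }
  }
  list(images = images, labels = labels, blank = blank)
}

#' Small named fixture matrices for co-occurrence unit tests
#'
#' `"constant4"`: 4x4 of level 2 (GLCM mass on (2,2)). `"hstripes"`: the
#' 2x2 matrix \[\[0,1\],\[0,1\]\] with M(0,1) = 2 at d = 1, 0 degrees.
#' `"fig6-like"`: a 4-level matrix whose d = 1, 0-degree GLCM counts the
#' pair (3, 0) exactly four times.
#'
#' @param name fixture name.
#' @return integer matrix of gray levels.
#' @export
toy_level_matrix <- function(name) {
  switch(name,
    constant4 = matrix(2L, 4, 4),
    hstripes = matrix(c(0L, 0L, 1L, 1L), 2, 2),
    `fig6-like` = matrix(c(3L, 3L, 3L, 3L,
                           0L, 0L, 0L, 0L,
                           1L, 2L, 1L, 2L,
                           2L, 1L, 3L, 2L), 4, 4),
    stop2("toy_level_matrix: unknown fixture '", name, "'")
  )
}
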