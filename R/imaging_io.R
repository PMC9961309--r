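#' 8-bit grayscale image container
#'
#' An `image8` is an integer matrix with values in \[0, 255\], the unit of all
#' downstream computation. Slices are stored height x width (rows x columns).
#'
#' @param pixels numeric or integer matrix with values in \[0, 255\].
#' @return an object of class `image8` (an integer matrix).
#' @export
image8 <- function(pixels) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop2("image8: 'pixels' must be a non-empty matrix")
  if (anyNA(pixels)) stop2("image8: NA pixel values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop2("image8: pixel values outside [0, 255]")
  m <- matrix(as.integer(round_half_up(pixels)), nrow(pixels), ncol(pixels))
  class(m) <- c("image8", "matrix")
  m
}

#' @export
print.image8 <- function(x, ...) {
  cat(sprintf("<image8 %d x %d, range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Rescale an integer raster to 8 bits
#'
#' Full-scale linear map from \[0, 2^bit_depth - 1\] to \[0, 255\] with
#' round-half-up, so intensities remain comparable across slices (not a
#' per-image min-max stretch). 8-bit input is returned unchanged.
#'
#' @param raw matrix of non-negative integers.
#' @param bit_depth source bit depth, one of 8, 12, 16.
#' @return an [image8].
#' @export
rescale_to_8bit <- function(raw, bit_depth = 12L) {
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop2("rescale_to_8bit: bit_depth must be 8, 12 or 16")
  if (min(raw) < 0) stop2("rescale_to_8bit: negative values")
  top <- 2^bit_depth - 1
  if (max(raw) > top)
    stop2("rescale_to_8bit: value ", max(raw), " >= 2^", bit_depth)
  if (bit_depth == 8L) return(image8(raw))
  image8(round_half_up(255 * raw / top))
}

#' Resize a slice to the network input side
#'
#' Bilinear interpolation with anti-aliasing: when downscaling, the image is
#' first smoothed with a separable Gaussian of sigma = (scale - 1) / 2 per
#' axis, then sampled bilinearly at pixel centres. Resizing an image already
#' at the target side is the identity, which makes the operation idempotent.
#'
#' @param img an [image8] (any rectangular size).
#' @param side target side in pixels (output is side x side), default 64.
#' @return an [image8] of dimension side x side.
#' @export
resize_to_input <- function(img, side = 64L) {
  if (side < 8L) stop2("resize_to_input: side must be >= 8")
  if (length(img) == 0L) stop2("resize_to_input: empty image")
  h <- nrow(img); w <- ncol(img)
  if (h == side && w == side) return(image8(unclass(img)))
  x <- matrix(as.numeric(img), h, w)
  sy <- h / side; sx <- w / side
  if (sy > 1) x <- gaussian_blur_1d(x, (sy - 1) / 2, along = "rows")
  if (sx > 1) x <- gaussian_blur_1d(x, (sx - 1) / 2, along = "cols")
  out <- bilinear_sample(x, side, side)
  image8(pmin(pmax(out, 0), 255))
}

# Separable 1-D Gaussian blur with replicate border handling.
gaussian_blur_1d <- function(x, sigma, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (sigma <= 0) return(x)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  if (along == "cols") return(t(gaussian_blur_1d(t(x), sigma, "rows")))
  n <- nrow(x)
  idx <- outer(seq_len(n), (-rad):rad, `+`)
  idx[idx < 1L] <- 1L; idx[idx > n] <- n
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) out <- out + k[j] * x[idx[, j], , drop = FALSE]
  out
}

# Bilinear sampling at output pixel centres (align-centres convention).
bilinear_sample <- function(x, oh, ow) {
  h <- nrow(x); w <- ncol(x)
  ry <- (seq_len(oh) - 0.5) * h / oh - 0.5
  rx <- (seq_len(ow) - 0.5) * w / ow - 0.5
  ry <- pmin(pmax(ry, 0), h - 1); rx <- pmin(pmax(rx, 0), w - 1)
  y0 <- floor(ry); x0 <- floor(rx)
  fy <- ry - y0; fx <- rx - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  a <- x[cbind(rep(y0 + 1, ow), rep(x0 + 1, each = oh))]
  b <- x[cbind(rep(y0 + 1, ow), rep(x1 + 1, each = oh))]
  c_ <- x[cbind(rep(y1 + 1, ow), rep(x0 + 1, each = oh))]
  d <- x[cbind(rep(y1 + 1, ow), rep(x1 + 1, each = oh))]
  wy <- rep(fy, ow); wx <- rep(fx, each = oh)
  v <- (1 - wy) * (1 - wx) * a + (1 - wy) * wx * b +
    wy * (1 - wx) * c_ + wy * wx * d
  matrix(v, oh, ow)
}

#' Load a slice from disk
#'
#' Reads an 8/16-bit PNG, a JPEG, a TIFF, or a single NIfTI slice and returns an
#' [image8]. Multi-channel rasters are converted to grayscale by the
#' unweighted channel mean. 16-bit PNG and integer NIfTI data are mapped by
#' the full-scale linear conversion of [rescale_to_8bit()].
#'
#' @param path file path (.png, .jpg/.jpeg, .nii/.nii.gz).
#' @param bit_depth assumed bit depth for integer NIfTI data (default 12).
#' @return an [image8].
#' @export
load_image <- function(path, bit_depth = 12L) {
  if (!file.exists(path)) stop2("load_image: no such file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  arr <- switch(ext,
    png  = try(png::readPNG(path), silent = TRUE),
    jpg  = ,
    jpeg = try(jpeg::readJPEG(path), silent = TRUE),
    tif  = ,
    tiff = try(tiff::readTIFF(path), silent = TRUE),
    nii  = try(nifti_slice_array(path, bit_depth), silent = TRUE),
    stop2("load_image: unsupported format '", ext, "' for ", path)
  )
  if (inherits(arr, "try-error"))
    stop2("load_image: cannot decode ", path)
  if (length(dim(arr)) == 3L) {
    arr <- apply(arr, c(1, 2), mean)  # luminance by unweighted channel mean
  }
  if (ext %in% c("png", "jpg", "jpeg", "tif", "tiff")) {
    # readPNG/readJPEG scale to [0, 1] regardless of source depth
    return(image8(round_half_up(arr * 255)))
  }
  image8(arr)
}

nifti_slice_array <- function(path, bit_depth) {
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) == 3L) {
    if (d[3] != 1L)
      stop2("load_image: ", path, " is a volume; use slice_volume()")
    vol <- vol[, , 1]
  }
  m <- matrix(as.numeric(vol), nrow(vol), ncol(vol))
  as.matrix(rescale_to_8bit(pmax(m, 0), bit_depth))
}

#' Slice a NIfTI volume into 2-D images
#'
#' Splits a 3-D volume along the last axis, rescales each slice to 8 bits and
#' writes one PNG per slice named `<stem>_z<k>.png`.
#'
#' @param path NIfTI file (.nii/.nii.gz).
#' @param out_dir output directory (created if missing).
#' @param bit_depth source integer bit depth (default 12).
#' @return character vector of written file paths.
#' @export
slice_volume <- function(path, out_dir, bit_depth = 12L) {
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) != 3L) stop2("slice_volume: expected a 3-D volume")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
  out <- character(d[3])
  for (k in seq_len(d[3])) {
    sl <- rescale_to_8bit(pmax(matrix(vol[, , k], d[1], d[2]), 0), bit_depth)
    out[k] <- file.path(out_dir, sprintf("%s_z%d.png", stem, k))
    png::writePNG(unclass(sl) / 255, out[k])
  }
  out
}

#' Index a two-class slice directory
#'
#' Walks `root/0/**` and `root/1/**` recursively (nested patient/modality
#' folders are allowed) and returns a deterministic, lexicographically
#' ordered inventory of image files with their class labels.
#'
#' @param root directory containing class subdirectories "0" and "1".
#' @param extensions file extensions treated as images.
#' @return a `dataset_index`: data.frame with columns `path`, `label`,
#'   `rejected`, and a `class_counts` attribute.
#' @export
index_dataset <- function(root,
                          extensions = c("png", "jpg", "jpeg", "tif",
                                         "tiff", "nii")) {
  for (cls in c("0", "1"))
    if (!dir.exists(file.path(root, cls)))
      stop2("index_dataset: missing class folder '", cls, "' under ", root)
  pat <- paste0("\\.(", paste(extensions, collapse = "|"), ")(\\.gz)?$")
  rec <- lapply(c(0L, 1L), function(cls) {
    files <- list.files(file.path(root, as.character(cls)),
                        pattern = pat, recursive = TRUE,
                        full.names = TRUE, ignore.case = TRUE)
    files <- sort(files, method = "radix")
    if (length(files) == 0L)
      warning("index_dataset: class '", cls, "' is empty", call. = FALSE)
    data.frame(path = files, label = rep(cls, length(files)),
               rejected = logical(length(files)), stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rec)
  rownames(idx) <- NULL
  if (anyDuplicated(idx$path)) stop2("index_dataset: duplicate paths")
  attr(idx, "class_counts") <- c(`0` = nrow(rec[[1]]), `1` = nrow(rec[[2]]))
  class(idx) <- c("dataset_index", "data.frame")
  idx
}

#' @export
print.dataset_index <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat(sprintf("<dataset_index: %d slices (class 0: %d, class 1: %d), %d rejected>\n",
              nrow(x), cc[["0"]], cc[["1"]], sum(x$rejected)))
  invisible(x)
}

#' Write / read a labelled feature table
#'
#' CSV layout is `path,label,<name_1>,...`; the segment map, when present, is
#' stored in a JSON sidecar `<file>.segments.json`.
#'
#' @param features numeric matrix (rows = slices) with column names.
#' @param path,label row metadata vectors.
#' @param file output CSV path.
#' @param segment_map optional [segment_map()] to record alongside.
#' @return `file`, invisibly.
#' @export
write_feature_table <- function(features, path, label, file,
                                segment_map = NULL) {
  stopifnot(nrow(features) == length(path), length(path) == length(label))
  df <- data.frame(path = path, label = label, features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(segment_map))
    jsonlite::write_json(segment_map, paste0(file, ".segments.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- as.matrix(df[, setdiff(names(df), c("path", "label")), drop = FALSE])
  list(features = feats, path = df$path, label = as.integer(df$label))
}
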