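#' Segment map of the hybrid feature set
#'
#' Ordered, contiguous segments of the fused vector: FC1 (512), FC2 (64),
#' GLCM (13), HOG (36), LBP (59) — 684 features in total. Percentage shares
#' are `100 * length / total`.
#'
#' @param lengths named integer vector of segment lengths in order.
#' @return a `segment_map` data.frame with `name`, `offset` (0-based),
#'   `length`, `share_pct`.
#' @export
segment_map <- function(lengths = c(FC1 = 512L, FC2 = 64L, GLCM = 13L,
                                    HOG = 36L, LBP = 59L)) {
  total <- sum(lengths)
  sm <- data.frame(name = names(lengths),
                   offset = cumsum(c(0L, unname(lengths[-length(lengths)]))),
                   length = as.integer(unname(lengths)),
                   share_pct = round_half_up(100 * unname(lengths) / total, 2),
                   stringsAsFactors = FALSE)
  attr(sm, "total") <- as.integer(total)
  class(sm) <- c("segment_map", "data.frame")
  sm
}

segment_cols <- function(sm, name) {
  row <- sm[sm$name == name, ]
  if (nrow(row) != 1L) stop2("unknown segment '", name, "'")
  (row$offset + 1L):(row$offset + row$length)
}

#' Assemble the hybrid feature vector
#'
#' Concatenates the five feature families in the fixed order
#' FC1 || FC2 || GLCM || HOG || LBP and attaches the segment map. Length
#' mismatches fail naming the offending segment.
#'
#' @param latent list with `fc1` (512) and `fc2` (64), as returned by
#'   [extract_latent()].
#' @param glcm 13-vector from [glcm_feature_vector()].
#' @param hog 36-vector from [hog_feature_vector()].
#' @param lbp 59-vector from [lbp_feature_vector()].
#' @param map expected [segment_map()].
#' @return numeric vector of length 684 with the map as an attribute.
#' @export
assemble_hfs <- function(latent, glcm, hog, lbp, map = segment_map()) {
  parts <- list(FC1 = latent$fc1, FC2 = latent$fc2, GLCM = glcm,
                HOG = hog, LBP = lbp)
  for (nm in map$name) {
    want <- map$length[map$name == nm]
    if (length(parts[[nm]]) != want)
      stop2("assemble_hfs: segment ", nm, " has length ",
            length(parts[[nm]]), ", expected ", want)
    if (any(!is.finite(parts[[nm]])))
      stop2("assemble_hfs: non-finite values in segment ", nm)
  }
  v <- unlist(parts[map$name], use.names = FALSE)
  names(v) <- unlist(lapply(map$name, function(nm)
    paste0(tolower(nm), "_", seq_len(map$length[map$name == nm]))))
  attr(v, "segment_map") <- map
  v
}

#' Select segments from a hybrid feature matrix
#'
#' Any sub-hybrid (e.g. FC1-GLCM-HOG) is a column subset; order and
#' within-segment layout are preserved.
#'
#' @param features matrix whose columns follow `map`.
#' @param segments character vector of segment names to keep.
#' @param map the [segment_map()] describing the columns.
#' @return column-subset matrix.
#' @export
select_segments <- function(features, segments, map = segment_map()) {
  cols <- unlist(lapply(segments, segment_cols, sm = map))
  features[, cols, drop = FALSE]
}

#' Min-max normalisation fitted on training data
#'
#' Per-feature linear map to \[0, 1\] using the training minima/maxima.
#' Constant features map to 0 everywhere; values outside the training range
#' (in test folds) are clipped to \[0, 1\].
#'
#' @param train numeric matrix of training vectors (rows = instances).
#' @return a `minmax_model`.
#' @export
fit_minmax <- function(train) {
  if (!is.matrix(train) || nrow(train) < 2L)
    stop2("fit_minmax: need at least 2 training vectors")
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  structure(list(min = mins, range = maxs - mins), class = "minmax_model")
}

#' @rdname fit_minmax
#' @param model a fitted `minmax_model`.
#' @param x matrix (or vector) to normalise.
#' @return normalised matrix with values in \[0, 1\].
#' @export
apply_minmax <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- nrow(x)
  rng <- model$range
  scaled <- (x - rep(model$min, each = n)) /
    rep(ifelse(rng > 0, rng, 1), each = n)
  scaled[, rng == 0] <- 0   # constant-feature convention
  pmin(pmax(scaled, 0), 1)
}
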