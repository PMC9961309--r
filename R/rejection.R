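#' Rejection-filter configuration
#'
#' The rejection algorithm (RA) drops slices whose pixel-value sum is at or
#' below a threshold `T_h`. With non-negative 8-bit pixels and the default
#' `T_h = 0` this removes exactly the all-zero (blank) slices, which carry no
#' discriminative content.
#'
#' @param threshold non-negative integer sum-of-pixels threshold `T_h`.
#' @return a `rejection_config` list.
#' @export
rejection_config <- function(threshold = 0L) {
  if (threshold < 0) stop2("rejection_config: threshold must be >= 0")
  structure(list(threshold = as.numeric(threshold)),
            class = "rejection_config")
}

#' Sum of pixel values
#'
#' @param img an [image8].
#' @return exact integer sum of all pixel values (as double to avoid
#'   integer overflow on large images).
#' @export
pixel_sum <- function(img) sum(as.numeric(img))

#' Apply the rejection algorithm to an indexed dataset
#'
#' Scans every record, flags those with `pixel_sum <= T_h` as rejected, and
#' reports per-class bookkeeping. Unreadable files are logged and counted as
#' rejected-with-error rather than silently dropped. Labels are never
#' altered, and re-applying the filter to its own output changes nothing.
#'
#' @param index a [index_dataset()] result.
#' @param cfg a [rejection_config()].
#' @param reader function mapping a path to an [image8] (default
#'   [load_image()]); injectable for testing.
#' @return list with elements `index` (rejected flags updated) and `report`
#'   (a `rejection_report`).
#' @export
apply_rejection <- function(index, cfg = rejection_config(),
                            reader = load_image) {
  if (nrow(index) == 0L) stop2("apply_rejection: empty index")
  errs <- character(0)
  rejected <- vapply(seq_len(nrow(index)), function(i) {
    s <- try(pixel_sum(reader(index$path[i])), silent = TRUE)
    if (inherits(s, "try-error")) {
      errs <<- c(errs, index$path[i])
      return(TRUE)
    }
    s <= cfg$threshold
  }, logical(1))
  index$rejected <- rejected
  report <- rejection_report_from_index(index, cfg, errs)
  list(index = index, report = report)
}

rejection_report_from_index <- function(index, cfg, errors = character(0)) {
  per_class <- lapply(c("0", "1"), function(cls) {
    sub <- index[index$label == as.integer(cls), , drop = FALSE]
    rejection_class_counts(nrow(sub), sum(sub$rejected))
  })
  names(per_class) <- c("0", "1")
  structure(list(threshold = cfg$threshold,
                 per_class = per_class,
                 rejected_files = index$path[index$rejected],
                 read_errors = errors),
            class = "rejection_report")
}

#' Per-class rejection bookkeeping
#'
#' The count identity holds by construction: the original class size equals
#' the rejected count plus the kept (improved) class size. The reduction is
#' `100 * rejected / total`, rounded half-up to 2 decimals.
#'
#' @param total original number of instances in the class.
#' @param rejected number of rejected instances.
#' @return list with `total`, `rejected`, `kept`, `reduction_pct`.
#' @export
rejection_class_counts <- function(total, rejected) {
  stopifnot(rejected <= total)
  list(total = total, rejected = rejected, kept = total - rejected,
       reduction_pct = reduction_pct(rejected, total))
}

#' @rdname rejection_class_counts
#' @export
reduction_pct <- function(rejected, total) {
  if (total == 0) return(0)
  round_half_up(100 * rejected / total, 2)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report T_h = %g>\n", x$threshold))
  for (cls in names(x$per_class)) {
    p <- x$per_class[[cls]]
    cat(sprintf("  class %s: kept %d / %d (rejected %d, %.2f%% reduction)\n",
                cls, p$kept, p$total, p$rejected, p$reduction_pct))
  }
  if (length(x$read_errors))
    cat("  read errors:", length(x$read_errors), "\n")
  invisible(x)
}

#' Keep only non-rejected records
#'
#' @param index a `dataset_index` with rejection flags set.
#' @return the filtered `dataset_index`.
#' @export
kept_records <- function(index) {
  out <- index[!index$rejected, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_counts") <- c(`0` = sum(out$label == 0L),
                                 `1` = sum(out$label == 1L))
  class(out) <- c("dataset_index", "data.frame")
  out
}

#' Stratified train/test split counts
#'
#' Per-class training counts are `round(frac * n)` (nearest integer), the
#' remainder goes to the test partition.
#'
#' @param class_sizes named integer vector of per-class sizes.
#' @param frac training fraction (default 0.8).
#' @return data.frame with per-class `train` and `test` counts.
#' @export
split_counts <- function(class_sizes, frac = 0.8) {
  train <- round(frac * class_sizes)
  data.frame(class = names(class_sizes), n = as.integer(class_sizes),
             train = as.integer(train),
             test = as.integer(class_sizes - train),
             stringsAsFactors = FALSE)
}

#' Fixed stratified 80:20 split of an index
#'
#' @param index a `dataset_index` (typically after [kept_records()]).
#' @param frac training fraction.
#' @param seed RNG seed for the within-class shuffle.
#' @return list of two `data.frame`s, `train` and `test`.
#' @export
split_dataset <- function(index, frac = 0.8, seed = 1L) {
  set.seed(seed)
  tr <- logical(nrow(index))
  for (cls in c(0L, 1L)) {
    rows <- which(index$label == cls)
    n_tr <- round(frac * length(rows))
    tr[sample(rows)[seq_len(n_tr)]] <- TRUE
  }
  list(train = index[tr, , drop = FALSE], test = index[!tr, , drop = FALSE])
}
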