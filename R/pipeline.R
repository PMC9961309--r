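#' Radiomic feature matrix for a set of slices
#'
#' Runs the three texture descriptors over each slice and binds them as
#' columns `glcm_F1..glcm_F13, hog_1..hog_36, lbp_1..lbp_59` (lengths per
#' the configurations).
#'
#' @param images n x side^2 pixel matrix (or list of [image8]).
#' @param side slice side (needed when `images` is a matrix).
#' @param glcm,hog,lbp module configurations.
#' @return n x (13 + 36 + 59) feature matrix.
#' @export
extract_radiomic_matrix <- function(images, side = 64L,
                                    glcm = glcm_config(),
                                    hog = hog_config(),
                                    lbp = lbp_config()) {
  if (is.list(images)) images <- images_to_matrix(images)
  n <- nrow(images)
  one <- function(i) {
    img <- image8(matrix(images[i, ], side, side))
    c(glcm_feature_vector(img, glcm), hog_feature_vector(img, hog),
      lbp_feature_vector(img, lbp))
  }
  first <- one(1)
  out <- matrix(0, n, length(first))
  out[1, ] <- first
  if (n > 1) for (i in 2:n) out[i, ] <- one(i)
  n_g <- 13L
  n_h <- length(hog_feature_vector(image8(matrix(0L, side, side)), hog))
  n_l <- lbp_bin_count(lbp$p)
  colnames(out) <- c(paste0("glcm_F", seq_len(n_g)),
                     paste0("hog_", seq_len(n_h)),
                     paste0("lbp_", seq_len(n_l)))
  out
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration with the evaluation protocol. The
#' resolved configuration can be serialised to JSON next to any results.
#'
#' @param rejection a [rejection_config()].
#' @param training a [training_config()].
#' @param glcm,hog,lbp radiomic configurations.
#' @param classifier a [knn_config()] or [svm_config()].
#' @param K number of cross-validation folds.
#' @param segments segment names used for classification (default all
#'   five, i.e. the full hybrid feature set).
#' @param per_fold_net train one network per CV fold (leakage-safe
#'   default) or once globally (`FALSE`).
#' @param seed master seed (folds, weight init, training).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(rejection = rejection_config(),
                            training = training_config(),
                            glcm = glcm_config(), hog = hog_config(),
                            lbp = lbp_config(),
                            classifier = knn_config(),
                            K = 10L,
                            segments = c("FC1", "FC2", "GLCM", "HOG", "LBP"),
                            per_fold_net = TRUE,
                            seed = 1L) {
  structure(list(rejection = rejection, training = training, glcm = glcm,
                 hog = hog, lbp = lbp, classifier = classifier,
                 K = as.integer(K), segments = segments,
                 per_fold_net = per_fold_net, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full two-stage pipeline
#'
#' Rejection -> network training and latent extraction -> radiomic
#' extraction -> fusion -> fold-wise min-max normalisation ->
#' classification -> metrics. With `per_fold_net = TRUE` the network is
#' re-trained on each fold's training images (no leakage); with `FALSE` it
#' is trained once on all kept slices and the cross-validation covers the
#' classifier stage only.
#'
#' @param root dataset directory (`root/0`, `root/1`) — or a pre-built
#'   list from [generate_phantom_matrix()] via the `data` argument.
#' @param config a [pipeline_config()].
#' @param data optional in-memory data: list with `images`, `labels`.
#' @param verbose log per-stage progress.
#' @return list with `rejection_report`, `features`, `labels`,
#'   `segment_map`, `fold_results`, `config`.
#' @export
run_pipeline <- function(root = NULL, config = pipeline_config(),
                         data = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(data)) {
    idx <- index_dataset(root)
    ra <- apply_rejection(idx, config$rejection)
    keep <- kept_records(ra$index)
    say("rejection: kept %d of %d slices", nrow(keep), nrow(idx))
    imgs <- lapply(keep$path, load_image)
    images <- images_to_matrix(imgs)
    labels <- keep$label
    report <- ra$report
  } else {
    sums <- rowSums(data$images)
    rejected <- sums <= config$rejection$threshold
    fake_index <- data.frame(path = sprintf("mem_%d", seq_along(sums)),
                             label = data$labels, rejected = rejected)
    report <- rejection_report_from_index(fake_index, config$rejection)
    images <- data$images[!rejected, , drop = FALSE]
    labels <- data$labels[!rejected]
    say("rejection: kept %d of %d slices", nrow(images), length(sums))
  }
  side <- as.integer(sqrt(ncol(images)))

  say("radiomic extraction on %d slices ...", nrow(images))
  radiomic <- extract_radiomic_matrix(images, side, config$glcm,
                                      config$hog, config$lbp)

  folds <- stratified_folds(labels, config$K, config$seed)
  spec <- network_spec(input_side = side)
  sm <- segment_map(c(FC1 = spec$fc_widths[1], FC2 = spec$fc_widths[2],
                      GLCM = 13L,
                      HOG = as.integer(sum(startsWith(colnames(radiomic), "hog_"))),
                      LBP = lbp_bin_count(config$lbp$p)))

  latent_for <- function(train_rows) {
    net <- build_network(spec, seed = config$seed)
    net <- train_network(net, images[train_rows, , drop = FALSE],
                         labels[train_rows], config$training)
    extract_latent_matrix(net, images)
  }

  if (config$per_fold_net) {
    say("training one network per fold (%d folds) ...", config$K)
    per_fold <- vector("list", length(folds))
    for (k in seq_along(folds)) {
      te <- folds[[k]]; tr <- setdiff(seq_along(labels), te)
      latent <- latent_for(tr)
      feats <- select_segments(cbind(latent, radiomic), config$segments, sm)
      mm <- fit_minmax(feats[tr, , drop = FALSE])
      Xtr <- apply_minmax(mm, feats[tr, , drop = FALSE])
      Xte <- apply_minmax(mm, feats[te, , drop = FALSE])
      pred <- if (inherits(config$classifier, "knn_config"))
        knn_predict(Xtr, labels[tr], Xte, config$classifier)
      else svm_predict(svm_train(Xtr, labels[tr], config$classifier), Xte)
      cm <- confusion_counts(labels[te], pred$label)
      met <- compute_metrics(cm)
      met$AUC <- tryCatch(roc_auc(labels[te], pred$score),
                          error = function(e) NA_real_)
      per_fold[[k]] <- list(fold = k, confusion = cm, metrics = met)
      say("fold %d: A = %.2f", k, met$A)
    }
    results <- aggregate_fold_results(per_fold)
    features <- NULL  # per-fold latent features are fold-specific
  } else {
    say("training one global network ...")
    latent <- latent_for(seq_along(labels))
    features <- cbind(latent, radiomic)
    feats <- select_segments(features, config$segments, sm)
    results <- cross_validate(feats, labels, config$classifier,
                              K = config$K, seed = config$seed,
                              normalize = "fold", folds = folds)
  }
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(rejection_report = report, features = features, labels = labels,
       segment_map = sm, fold_results = results, config = config)
}

#' Write pipeline results as JSON
#'
#' @param result a [run_pipeline()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_results_json <- function(result, file) {
  out <- list(
    aggregate = lapply(result$fold_results$aggregate, function(a)
      list(mean = a$mean, sd = a$sd)),
    folds = lapply(result$fold_results$folds, function(f)
      list(fold = f$fold, confusion = unclass(f$confusion),
           metrics = unclass(f$metrics)[setdiff(names(f$metrics), "flags")]))
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
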