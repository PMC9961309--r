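#' k-NN classifier configuration
#'
#' @param k odd neighbourhood size (1, 3, 5 or 7; default 1).
#' @param distance one of `"euclidean"`, `"minkowski"`,
#'   `"euclidean-printed"` (Euclidean with a 1/k factor inside the radical),
#'   `"chebyshev-as-printed"` (maximum coordinate difference) or
#'   `"mahalanobis"`.
#' @param r Minkowski order (r >= 1).
#' @param vote `"majority"` or `"weighted"` (inverse-distance weights
#'   `1 / d^z`).
#' @param z weighting exponent for the weighted vote.
#' @return a `knn_config` list.
#' @export
knn_config <- function(k = 1L, distance = c("euclidean", "minkowski",
                                            "euclidean-printed",
                                            "chebyshev-as-printed",
                                            "mahalanobis"),
                       r = 2, vote = c("majority", "weighted"), z = 2) {
  distance <- match.arg(distance)
  vote <- match.arg(vote)
  if (k %% 2L == 0L) stop2("knn_config: k must be odd")
  if (r < 1) stop2("knn_config: r must be >= 1")
  structure(list(k = as.integer(k), distance = distance, r = r,
                 vote = vote, z = z), class = "knn_config")
}

#' SVM classifier configuration
#'
#' Soft-margin kernel SVM (backed by e1071). Unstated hyperparameters use
#' conventional defaults: cost 1, RBF scale 1 / (n_features * mean feature
#' variance), polynomial offset 1.
#'
#' @param kernel one of `"linear"`, `"rbf"`, `"poly2"`, `"poly3"`, `"poly4"`.
#' @param cost regularisation strength (> 0).
#' @return an `svm_config` list.
#' @export
svm_config <- function(kernel = c("rbf", "linear", "poly2", "poly3", "poly4"),
                       cost = 1) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop2("svm_config: cost must be > 0")
  structure(list(kernel = kernel, cost = cost), class = "svm_config")
}

#' Minkowski distance
#'
#' `d(q, x) = (sum_i |q_i - x_i|^r)^(1/r)`; r = 2 is Euclidean and the
#' r -> infinity limit is the maximum coordinate difference.
#'
#' @param q,x equal-length numeric vectors.
#' @param r order (>= 1).
#' @return non-negative distance.
#' @export
minkowski_distance <- function(q, x, r = 2) {
  if (length(q) != length(x))
    stop2("minkowski_distance: length mismatch")
  if (r < 1) stop2("minkowski_distance: r must be >= 1")
  sum(abs(q - x)^r)^(1 / r)
}

# Distance matrix between test rows (Q) and training rows (X).
knn_dist_matrix <- function(Q, X, cfg) {
  switch(cfg$distance,
    euclidean = euclid_dist(Q, X),
    `euclidean-printed` = euclid_dist(Q, X) / sqrt(ncol(Q)),
    minkowski = slow_dist(Q, X, function(q, x)
      minkowski_distance(q, x, cfg$r)),
    `chebyshev-as-printed` = slow_dist(Q, X, function(q, x)
      max(abs(q - x))),
    mahalanobis = {
      S <- stats::cov(X) + diag(1e-6, ncol(X))
      Sinv <- solve(S)
      t(apply(Q, 1, function(q) {
        D <- sweep(X, 2, q)
        sqrt(pmax(rowSums((D %*% Sinv) * D), 0))
      }))
    }
  )
}

euclid_dist <- function(Q, X) {
  qq <- rowSums(Q^2); xx <- rowSums(X^2)
  d2 <- outer(qq, xx, `+`) - 2 * tcrossprod(Q, X)
  sqrt(pmax(d2, 0))
}

slow_dist <- function(Q, X, f) {
  out <- matrix(0, nrow(Q), nrow(X))
  for (i in seq_len(nrow(Q))) out[i, ] <- apply(X, 1, f, q = Q[i, ])
  out
}

#' k-NN prediction
#'
#' Majority vote over the k nearest training points (ties broken by the
#' nearer neighbour), or inverse-distance-weighted voting
#' `V(y) = sum 1/d^z` over matching neighbours. A zero-distance neighbour
#' under weighted voting wins outright (infinite-weight convention). The
#' score is the positive-class vote share, usable for ROC analysis.
#'
#' @param train numeric matrix of training vectors.
#' @param labels integer labels in \{0, 1\} for `train` rows.
#' @param q query vector or matrix of queries (rows).
#' @param cfg a [knn_config()].
#' @return data.frame with `label` and `score` per query.
#' @export
knn_predict <- function(train, labels, q, cfg = knn_config()) {
  if (!is.matrix(q)) q <- matrix(q, nrow = 1)
  if (cfg$k > nrow(train)) stop2("knn_predict: k exceeds training size")
  labels <- as.integer(labels)
  D <- knn_dist_matrix(q, train, cfg)
  out <- data.frame(label = integer(nrow(q)), score = numeric(nrow(q)))
  for (i in seq_len(nrow(q))) {
    ord <- order(D[i, ])[seq_len(cfg$k)]
    dd <- D[i, ord]; yy <- labels[ord]
    if (cfg$vote == "majority") {
      v1 <- sum(yy == 1L); v0 <- cfg$k - v1
      if (v1 != v0) lab <- as.integer(v1 > v0)
      else lab <- yy[1L]                    # tie -> nearer neighbour
      score <- v1 / cfg$k
    } else {
      if (any(dd == 0)) {
        lab <- yy[which(dd == 0)[1L]]
        score <- as.numeric(lab)
      } else {
        w <- 1 / dd^cfg$z
        v1 <- sum(w[yy == 1L]); v0 <- sum(w[yy == 0L])
        lab <- if (v1 == v0) yy[1L] else as.integer(v1 > v0)
        score <- v1 / (v0 + v1)
      }
    }
    out$label[i] <- lab; out$score[i] <- score
  }
  out
}

#' Train / apply a soft-margin kernel SVM
#'
#' Thin wrappers around [e1071::svm()] exposing the kernels used here
#' (linear, RBF, polynomial of order 2-4). The prediction score is the
#' signed decision value `g(x)`, oriented so larger means class 1.
#'
#' @param train numeric matrix; `labels` integer vector in \{0, 1\} with
#'   both classes present.
#' @param labels class labels for `train` rows.
#' @param cfg an [svm_config()].
#' @return an `svm_model` wrapper.
#' @export
svm_train <- function(train, labels, cfg = svm_config()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop2("svm_train: both classes must be present")
  args <- list(x = train, y = factor(labels, levels = c(0, 1)),
               cost = cfg$cost, scale = FALSE)
  args <- c(args, switch(cfg$kernel,
    linear = list(kernel = "linear"),
    rbf = list(kernel = "radial",
               gamma = 1 / (ncol(train) * max(mean(apply(train, 2,
                                                         stats::var)),
                                              .Machine$double.eps))),
    poly2 = list(kernel = "polynomial", degree = 2, coef0 = 1, gamma = 1),
    poly3 = list(kernel = "polynomial", degree = 3, coef0 = 1, gamma = 1),
    poly4 = list(kernel = "polynomial", degree = 4, coef0 = 1, gamma = 1)))
  fit <- do.call(e1071::svm, args)
  structure(list(fit = fit), class = "svm_model")
}

#' @rdname svm_train
#' @param model an `svm_model`.
#' @param q query matrix (or vector).
#' @export
svm_predict <- function(model, q) {
  if (!is.matrix(q)) q <- matrix(q, nrow = 1)
  pred <- stats::predict(model$fit, q, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 orients the decision value toward the first factor level (0)
  score <- if (grepl("^0", colnames(dv)[1])) -dv[, 1] else dv[, 1]
  data.frame(label = as.integer(as.character(pred)), score = score)
}

#' Stratified K-fold plan
#'
#' Seeded shuffle within each class followed by round-robin assignment, so
#' per-class fold counts differ by at most one and folds partition the
#' data exactly.
#'
#' @param labels integer class labels in \{0, 1\}.
#' @param K number of folds (default 10).
#' @param seed RNG seed.
#' @return list of K integer index vectors (test folds).
#' @export
stratified_folds <- function(labels, K = 10L, seed = 1L) {
  labels <- as.integer(labels)
  for (cls in unique(labels))
    if (sum(labels == cls) < K)
      stop2("stratified_folds: class ", cls, " has fewer than K = ",
            K, " members")
  set.seed(seed)
  folds <- vector("list", K)
  for (cls in sort(unique(labels))) {
    rows <- sample(which(labels == cls))
    f <- rep_len(seq_len(K), length(rows))
    for (k in seq_len(K)) folds[[k]] <- c(folds[[k]], rows[f == k])
  }
  lapply(folds, sort)
}

#' Cross-validated evaluation of a classifier on a feature matrix
#'
#' For each fold: fit min-max normalisation on the training folds (unless
#' `normalize = "none"` or `"global"`), train the classifier, evaluate on
#' the held-out fold. Accuracies are aggregated as mean +/- sample standard
#' deviation (K - 1 denominator).
#'
#' @param features numeric matrix (rows = instances).
#' @param labels integer labels in \{0, 1\}.
#' @param classifier a [knn_config()] or [svm_config()].
#' @param K number of folds.
#' @param seed seed for the fold plan.
#' @param normalize `"fold"` (fit on training folds; default), `"global"`
#'   (fit once on everything) or `"none"`.
#' @param folds optional pre-computed fold plan.
#' @return a `fold_results` list: per-fold confusion + metrics, and the
#'   aggregate mean/sd per metric.
#' @export
cross_validate <- function(features, labels, classifier = knn_config(),
                           K = 10L, seed = 1L,
                           normalize = c("fold", "global", "none"),
                           folds = NULL) {
  normalize <- match.arg(normalize)
  labels <- as.integer(labels)
  if (is.null(folds)) folds <- stratified_folds(labels, K, seed)
  K <- length(folds)
  if (normalize == "global")
    features <- apply_minmax(fit_minmax(features), features)
  per_fold <- vector("list", K)
  for (k in seq_len(K)) {
    te <- folds[[k]]; tr <- setdiff(seq_along(labels), te)
    Xtr <- features[tr, , drop = FALSE]; Xte <- features[te, , drop = FALSE]
    if (normalize == "fold") {
      mm <- fit_minmax(Xtr)
      Xtr <- apply_minmax(mm, Xtr); Xte <- apply_minmax(mm, Xte)
    }
    pred <- if (inherits(classifier, "knn_config")) {
      knn_predict(Xtr, labels[tr], Xte, classifier)
    } else if (inherits(classifier, "svm_config")) {
      svm_predict(svm_train(Xtr, labels[tr], classifier), Xte)
    } else if (is.function(classifier)) {
      classifier(Xtr, labels[tr], Xte)
    } else stop2("cross_validate: unsupported classifier")
    cm <- confusion_counts(labels[te], pred$label)
    met <- compute_metrics(cm)
    met$AUC <- tryCatch(roc_auc(labels[te], pred$score),
                        error = function(e) NA_real_)
    per_fold[[k]] <- list(fold = k, confusion = cm, metrics = met)
  }
  aggregate_fold_results(per_fold)
}

#' Aggregate per-fold metrics as mean +/- sample sd
#'
#' @param per_fold list of per-fold results (confusion + metrics).
#' @return a `fold_results` list with `folds` and `aggregate`.
#' @export
aggregate_fold_results <- function(per_fold) {
  metric_names <- names(per_fold[[1]]$metrics)
  metric_names <- setdiff(metric_names, "flags")
  agg <- lapply(metric_names, function(m) {
    v <- vapply(per_fold, function(f) f$metrics[[m]], numeric(1))
    list(mean = mean(v, na.rm = TRUE),
         sd = if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  })
  names(agg) <- metric_names
  structure(list(folds = per_fold, aggregate = agg), class = "fold_results")
}

#' @export
print.fold_results <- function(x, ...) {
  cat(sprintf("<fold_results: %d folds>\n", length(x$folds)))
  for (m in c("A", "S_n", "S_p", "F1", "MCC", "AUC")) {
    if (is.null(x$aggregate[[m]])) next
    a <- x$aggregate[[m]]
    cat(sprintf("  %-4s %.2f +/- %.2f\n", m, a$mean, a$sd))
  }
  invisible(x)
}
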