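test_that("Minkowski distance matches closed forms and reduces properly", {
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 2), 5)
  expect_equal(minkowski_distance(c(1, 2, 3), c(1, 2, 3), 2), 0)
  expect_equal(minkowski_distance(c(0, 0), c(1, 1), 1), 2)
  expect_error(minkowski_distance(1:3, 1:4), "length mismatch")
  expect_error(minkowski_distance(1:3, 4:6, r = 0.5), ">= 1")
})

test_that("Minkowski distance satisfies the metric axioms for r >= 1", {
  set.seed(15)
  for (r in c(1, 1.5, 2, 3)) {
    for (rep in 1:20) {
      a <- rnorm(6); b <- rnorm(6); c_ <- rnorm(6)
      dab <- minkowski_distance(a, b, r)
      expect_equal(dab, minkowski_distance(b, a, r))            # symmetry
      expect_equal(minkowski_distance(a, a, r), 0)              # identity
      expect_lte(dab,
                 minkowski_distance(a, c_, r) +
                   minkowski_distance(c_, b, r) + 1e-12)        # triangle
    }
  }
})

test_that("k-NN voting follows majority, tie-break and inverse-distance weighting", {
  train <- rbind(c(0, 0), c(1, 0), c(4, 0))
  labels <- c(0L, 1L, 1L)
  # query on a training point with k = 1 returns that label
  p <- knn_predict(train, labels, c(1, 0), knn_config(k = 1))
  expect_equal(p$label, 1L)
  # majority with neighbour labels {1, 1, 0}
  p3 <- knn_predict(train, labels, c(2, 0), knn_config(k = 3))
  expect_equal(p3$label, 1L)
  expect_equal(p3$score, 2 / 3)
  # inverse-distance weighting at distances (1, 2, 3), labels (0, 1, 1),
  # z = 2: V(0) = 1 beats V(1) = 1/4 + 1/9 although the majority is 1
  tw <- rbind(c(1, 0), c(2, 0), c(3, 0))
  pw <- knn_predict(tw, c(0L, 1L, 1L), c(0, 0),
                    knn_config(k = 3, vote = "weighted", z = 2))
  expect_equal(pw$label, 0L)
  expect_equal(pw$score, (1 / 4 + 1 / 9) / (1 + 1 / 4 + 1 / 9))
  # zero distance under weighted voting: that neighbour wins outright
  pz <- knn_predict(tw, c(0L, 1L, 1L), c(1, 0),
                    knn_config(k = 3, vote = "weighted"))
  expect_equal(pz$label, 0L)
  expect_error(knn_config(k = 2), "odd")
})

test_that("the weighting exponent z can flip a weighted vote", {
  # distances (1, 1.1, 1.1): two class-1 votes outweigh the nearer class-0
  # neighbour at small z but not at large z
  train <- rbind(c(1, 0), c(1.1, 0), c(-1.1, 0))
  labs <- c(0L, 1L, 1L)
  lo <- knn_predict(train, labs, c(0, 0),
                    knn_config(k = 3, vote = "weighted", z = 1))
  hi <- knn_predict(train, labs, c(0, 0),
                    knn_config(k = 3, vote = "weighted", z = 25))
  expect_equal(lo$label, 1L)   # 2/1.1 > 1
  expect_equal(hi$label, 0L)   # 1 > 2/1.1^25
})

test_that("1-NN is perfect on its own training set (leave-in property)", {
  set.seed(31)
  X <- matrix(rnorm(40 * 5), 40)
  y <- rep(c(0L, 1L), each = 20)
  pred <- knn_predict(X, y, X, knn_config(k = 1))
  expect_identical(pred$label, y)
})

test_that("all configured distances produce valid predictions", {
  set.seed(32)
  X <- rbind(matrix(rnorm(30, 0), 15), matrix(rnorm(30, 4), 15))
  y <- rep(c(0L, 1L), each = 15)
  q <- rbind(c(0, 0.2), c(4, 4.1))
  for (d in c("euclidean", "minkowski", "euclidean-printed",
              "chebyshev-as-printed", "mahalanobis")) {
    p <- knn_predict(X, y, q, knn_config(k = 3, distance = d, r = 3))
    expect_identical(p$label, c(0L, 1L))
  }
})

test_that("SVM separates separable clusters and RBF beats linear on XOR", {
  set.seed(41)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 3, 0.3), 20))
  y <- rep(c(0L, 1L), each = 20)
  m <- svm_train(X, y, svm_config("linear"))
  expect_identical(svm_predict(m, X)$label, y)
  # XOR: four clusters, diagonal classes agree
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  Xx <- do.call(rbind, lapply(1:4, function(i)
    matrix(rnorm(40, 0, 0.08), 20) + rep(centers[i, ], each = 20)))
  yx <- rep(c(0L, 0L, 1L, 1L), each = 20)
  acc <- function(cfg) {
    mean(svm_predict(svm_train(Xx, yx, cfg), Xx)$label == yx)
  }
  expect_gt(acc(svm_config("rbf")), acc(svm_config("linear")))
  expect_gt(acc(svm_config("rbf")), 0.9)
  expect_lte(acc(svm_config("linear")), 0.8)
  expect_error(svm_train(X, rep(0L, 40)), "both classes")
  # conflicting duplicate labels still train under the soft margin
  Xd <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 0))
  expect_error(svm_train(Xd, c(0L, 1L, 1L, 0L), svm_config("linear")), NA)
})

test_that("stratified folds partition the data with balanced classes", {
  y <- rep(c(0L, 1L), times = c(60, 40))
  folds <- stratified_folds(y, K = 10, seed = 2)
  expect_length(folds, 10)
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(y))          # exact partition
  for (f in folds) {
    expect_equal(sum(y[f] == 0L), 6)
    expect_equal(sum(y[f] == 1L), 4)
  }
  # same seed -> same plan
  expect_identical(stratified_folds(y, 10, seed = 2), folds)
  # 101/100: per-class fold counts within 1 of each other
  y2 <- rep(c(0L, 1L), times = c(101, 100))
  f2 <- stratified_folds(y2, K = 10, seed = 3)
  for (cls in 0:1) {
    n <- vapply(f2, function(f) sum(y2[f] == cls), integer(1))
    expect_lte(max(n) - min(n), 1)
  }
  expect_error(stratified_folds(rep(c(0L, 1L), times = c(5, 50)), K = 10),
               "fewer than K")
})

test_that("cross-validation aggregates accuracy as mean +/- sample sd", {
  # an oracle feature (the label itself) makes 1-NN perfect: 100.00 +/- 0.00
  set.seed(5)
  y <- rep(c(0L, 1L), each = 30)
  X <- cbind(as.numeric(y), rnorm(60))
  res <- cross_validate(X, y, knn_config(k = 1), K = 10, seed = 1)
  expect_equal(res$aggregate$A$mean, 100)
  expect_equal(res$aggregate$A$sd, 0)
  # K = 2 with fold accuracies 80 and 90 -> 85 +/- 7.07
  fake <- list(list(fold = 1, confusion = NULL, metrics = list(A = 80)),
               list(fold = 2, confusion = NULL, metrics = list(A = 90)))
  agg <- aggregate_fold_results(fake)
  expect_equal(agg$aggregate$A$mean, 85)
  expect_equal(agg$aggregate$A$sd, sqrt(2 * 25 / 1), tolerance = 1e-12)
  expect_equal(round(agg$aggregate$A$sd, 2), 7.07)
})

test_that("a label-blind classifier scores near chance on balanced data", {
  set.seed(6)
  y <- rep(c(0L, 1L), each = 50)
  X <- matrix(rnorm(100 * 3), 100)
  flip <- function(Xtr, ytr, Xte) {
    set.seed(nrow(Xte))   # deterministic pseudo-coin
    lab <- sample(c(0L, 1L), nrow(Xte), TRUE)
    data.frame(label = lab, score = lab)
  }
  res <- cross_validate(X, y, flip, K = 10, seed = 4)
  # binomial sd at fold size 10 is ~15.8; allow 3 sd around 50
  expect_lt(abs(res$aggregate$A$mean - 50), 15)
})
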