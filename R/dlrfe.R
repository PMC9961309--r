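#' Network architecture specification
#'
#' Describes the three-block CNN used for latent feature extraction: three
#' 3x3 convolution blocks (64/128/256 filters, each conv + ReLU + 2x2 max
#' pool, stride 2), batch normalisation after Block-2 pooling, 20% dropout
#' after Block-3 pooling, then three fully connected layers (512/64/2).
#' Conv-1 and Conv-2 use 'same' zero padding; Conv-3 uses valid padding,
#' which is the only choice consistent with the 16x16 -> 14x14 activation
#' drop and the 512 x 12,544 first FC weight (12,544 = 7*7*256).
#'
#' @param input_side input image side in pixels (default 64).
#' @param conv_filters filter counts for the three blocks.
#' @param fc_widths widths of the two hidden fully connected layers.
#' @param n_classes number of output classes (default 2).
#' @param dropout dropout rate after Block-3 pooling.
#' @return a `network_spec` with the validated shape chain attached.
#' @export
network_spec <- function(input_side = 64L, conv_filters = c(64L, 128L, 256L),
                         fc_widths = c(512L, 64L), n_classes = 2L,
                         dropout = 0.2) {
  spec <- structure(list(input_side = as.integer(input_side),
                         conv_filters = as.integer(conv_filters),
                         fc_widths = as.integer(fc_widths),
                         n_classes = as.integer(n_classes),
                         dropout = dropout),
                    class = "network_spec")
  spec$chain <- shape_chain(spec)
  spec
}

#' Activation shape chain of a network spec
#'
#' Computes the side/channel shape after every layer and fails, naming the
#' first offending layer, if any pooling stage meets an odd side or the
#' valid Conv-3 would underflow.
#'
#' @param spec a [network_spec()].
#' @return list of c(side, channels) entries, plus the flatten length.
#' @export
shape_chain <- function(spec) {
  s <- spec$input_side
  f <- spec$conv_filters
  chain <- list(input = c(s, 1L))
  chain$conv1 <- c(s, f[1])                           # 'same'
  if (s %% 2L != 0L) stop2("architecture error at MaxPool_1: side ", s,
                           " not divisible by 2")
  s <- s %/% 2L; chain$pool1 <- c(s, f[1])
  chain$conv2 <- c(s, f[2])                           # 'same'
  if (s %% 2L != 0L) stop2("architecture error at MaxPool_2: side ", s,
                           " not divisible by 2")
  s <- s %/% 2L; chain$pool2 <- c(s, f[2])
  chain$bn2 <- c(s, f[2])
  if (s < 3L) stop2("architecture error at Conv-3: side ", s,
                    " too small for a valid 3x3 convolution")
  s <- s - 2L; chain$conv3 <- c(s, f[3])              # valid
  if (s %% 2L != 0L) stop2("architecture error at MaxPool_3: side ", s,
                           " not divisible by 2")
  s <- s %/% 2L; chain$pool3 <- c(s, f[3])
  chain$flatten <- s * s * f[3]
  chain$fc1 <- spec$fc_widths[1]
  chain$fc2 <- spec$fc_widths[2]
  chain$fc3 <- spec$n_classes
  chain
}

#' Total learnable parameter count
#'
#' Sums weights and biases over the three conv layers, the batch-norm
#' offset/scale, and the three FC layers.
#'
#' @param spec a [network_spec()].
#' @return integer-valued count (as double).
#' @export
count_learnables <- function(spec) {
  f <- spec$conv_filters; ch <- spec$chain
  conv1 <- 9 * 1 * f[1] + f[1]
  conv2 <- 9 * f[1] * f[2] + f[2]
  bn2 <- 2 * f[2]
  conv3 <- 9 * f[2] * f[3] + f[3]
  fc1 <- ch$flatten * ch$fc1 + ch$fc1
  fc2 <- ch$fc1 * ch$fc2 + ch$fc2
  fc3 <- ch$fc2 * ch$fc3 + ch$fc3
  conv1 + conv2 + bn2 + conv3 + fc1 + fc2 + fc3
}

#' Training hyperparameters
#'
#' Defaults follow the tuned optimisation recipe: SGD with momentum 0.99,
#' initial learning rate 1e-4, mini-batches of 16, L2 regularisation 1e-4,
#' cross-entropy loss, 5 epochs (up to 50 supported).
#'
#' @param epochs number of training epochs (default 5).
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param momentum classical momentum coefficient.
#' @param l2 L2 regularisation strength (applied to weight matrices).
#' @param seed RNG seed controlling shuffling and dropout.
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 5L, batch_size = 16L, lr = 1e-4,
                            momentum = 0.99, l2 = 1e-4, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr > 0, momentum >= 0, l2 >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, l2 = l2,
                 seed = as.integer(seed)),
            class = "training_config")
}

# ---- geometry helpers (im2col / pooling index matrices) --------------------

# 3x3 conv index matrix: row = output position (column-major), col = kernel
# tap in fixed (dr fastest, then dc) order; NA marks zero padding.
make_conv_idx <- function(h, w, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  if (pad == "same") { ro <- seq_len(h); co <- seq_len(w) }
  else { ro <- 2:(h - 1); co <- 2:(w - 1) }
  centers_r <- rep(ro, times = length(co))
  centers_c <- rep(co, each = length(ro))
  idx <- matrix(NA_integer_, length(centers_r), 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    r <- centers_r + dr; c <- centers_c + dc
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    idx[ok, k] <- (c[ok] - 1L) * h + r[ok]
  }
  idx
}

# 2x2/stride-2 pooling index matrix: row = output position, 4 input taps.
make_pool_idx <- function(h, w) {
  ho <- h %/% 2L; wo <- w %/% 2L
  ro <- rep(seq_len(ho), times = wo)
  co <- rep(seq_len(wo), each = ho)
  r0 <- 2L * ro - 1L; c0 <- 2L * co - 1L
  cbind((c0 - 1L) * h + r0, (c0 - 1L) * h + r0 + 1L,
        c0 * h + r0, c0 * h + r0 + 1L)
}

# Expand a per-image index matrix to a batch of B images stacked in rows.
batch_idx <- function(idx, B, p_in, zero_row) {
  p_out <- nrow(idx)
  out <- idx[rep(seq_len(p_out), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * p_in, each = p_out)
  if (anyNA(out)) out[is.na(out)] <- zero_row
  out
}

# ---- layer primitives ------------------------------------------------------

conv_fwd <- function(X, W, b, idxB) {
  Xz <- rbind(X, 0)
  M <- Xz[as.vector(idxB), , drop = FALSE]
  dim(M) <- c(nrow(idxB), 9L * ncol(X))
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, M = M)
}

conv_bwd <- function(dY, M, W, idxB, n_in, n_ch_in) {
  dW <- crossprod(M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  dim(dM) <- c(nrow(idxB) * 9L, n_ch_in)
  S <- rowsum(dM, group = as.vector(idxB))
  rn <- as.integer(rownames(S))
  keep <- rn <= n_in
  dX <- matrix(0, n_in, n_ch_in)
  dX[rn[keep], ] <- S[keep, , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

pool_fwd <- function(X, pidxB) {
  Y <- pmax(X[pidxB[, 1], , drop = FALSE], X[pidxB[, 2], , drop = FALSE],
            X[pidxB[, 3], , drop = FALSE], X[pidxB[, 4], , drop = FALSE])
  Y
}

pool_bwd <- function(dY, Y, X, pidxB) {
  dX <- matrix(0, nrow(X), ncol(X))
  taken <- matrix(FALSE, nrow(Y), ncol(Y))
  for (i in 1:4) {
    Xi <- X[pidxB[, i], , drop = FALSE]
    mi <- (Xi == Y) & !taken
    taken <- taken | mi
    dX[pidxB[, i], ] <- dY * mi
  }
  dX
}

bn_fwd <- function(X, gamma, beta, rmean, rvar, train, eps = 1e-5,
                   bn_momentum = 0.1) {
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    rmean <- (1 - bn_momentum) * rmean + bn_momentum * mu
    rvar <- (1 - bn_momentum) * rvar + bn_momentum * v
  } else {
    mu <- rmean; v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  n <- nrow(X)
  xhat <- (X - rep(mu, each = n)) * rep(invstd, each = n)
  Y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(Y = Y, xhat = xhat, invstd = invstd, rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dY, xhat, invstd, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = n)
  dX <- rep(invstd / n, each = n) *
    (n * dxhat - rep(colSums(dxhat), each = n) -
       xhat * rep(colSums(dxhat * xhat), each = n))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Reorder (B*P x C) block-row layout into per-image flattened rows (B x P*C),
# feature order: position fastest, channel slower.
flatten_fwd <- function(X, B, P) {
  A <- array(X, c(P, B, ncol(X)))
  A <- aperm(A, c(2, 1, 3))
  dim(A) <- c(B, P * ncol(X))
  A
}

flatten_bwd <- function(dXf, B, P, C) {
  A <- array(dXf, c(B, P, C))
  A <- aperm(A, c(2, 1, 3))
  dim(A) <- c(B * P, C)
  A
}

# ---- network construction --------------------------------------------------

glorot <- function(n_in, n_out, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build an (untrained) network
#'
#' Parameters are initialised Glorot-uniform from the given seed; batch-norm
#' scale/offset start at 1/0 with running statistics at 0/1.
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for weight initialisation.
#' @return a `trained_network` (untrained until [train_network()] is run).
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  set.seed(seed)
  f <- spec$conv_filters; ch <- spec$chain
  params <- list(
    conv1 = list(W = glorot(9, f[1], 9 * 1, 9 * f[1]), b = numeric(f[1])),
    conv2 = list(W = glorot(9 * f[1], f[2], 9 * f[1], 9 * f[2]),
                 b = numeric(f[2])),
    bn2 = list(gamma = rep(1, f[2]), beta = numeric(f[2])),
    conv3 = list(W = glorot(9 * f[2], f[3], 9 * f[2], 9 * f[3]),
                 b = numeric(f[3])),
    fc1 = list(W = glorot(ch$flatten, ch$fc1, ch$flatten, ch$fc1),
               b = numeric(ch$fc1)),
    fc2 = list(W = glorot(ch$fc1, ch$fc2, ch$fc1, ch$fc2),
               b = numeric(ch$fc2)),
    fc3 = list(W = glorot(ch$fc2, ch$fc3, ch$fc2, ch$fc3),
               b = numeric(ch$fc3))
  )
  s <- spec$input_side
  geom <- list(
    s1 = s, idx1 = make_conv_idx(s, s, "same"), p1 = make_pool_idx(s, s),
    s2 = s %/% 2L,
    idx2 = make_conv_idx(s %/% 2L, s %/% 2L, "same"),
    p2 = make_pool_idx(s %/% 2L, s %/% 2L),
    s3 = s %/% 4L,
    idx3 = make_conv_idx(s %/% 4L, s %/% 4L, "valid"),
    s3v = s %/% 4L - 2L,
    p3 = make_pool_idx(s %/% 4L - 2L, s %/% 4L - 2L),
    s4 = (s %/% 4L - 2L) %/% 2L
  )
  structure(list(spec = spec, params = params, geom = geom,
                 bn_state = list(rmean = numeric(f[2]), rvar = rep(1, f[2])),
                 zerocenter = NULL,
                 history = data.frame(epoch = integer(0), loss = numeric(0),
                                      accuracy = numeric(0)),
                 init_seed = as.integer(seed)),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf("<trained_network: input %dx%d, %s learnables, %d epoch(s) trained>\n",
              x$spec$input_side, x$spec$input_side,
              format(count_learnables(x$spec), big.mark = ","),
              nrow(x$history)))
  invisible(x)
}

# Full forward pass. X: B x side^2 matrix of raw pixels (column-major image
# vectors). Returns logits, fc1/fc2 activations, and caches when train=TRUE.
forward_pass <- function(net, X, train = FALSE) {
  g <- net$geom; p <- net$params
  B <- nrow(X)
  if (ncol(X) != g$s1^2)
    stop2("forward_pass: expected ", g$s1^2, " pixels per image, got ", ncol(X))
  if (!is.null(net$zerocenter)) X <- X - rep(net$zerocenter, each = B)
  X0 <- matrix(as.vector(t(X)), ncol = 1)

  P1 <- g$s1^2
  i1 <- batch_idx(g$idx1, B, P1, B * P1 + 1L)
  c1 <- conv_fwd(X0, p$conv1$W, p$conv1$b, i1)
  a1 <- pmax(c1$Y, 0)
  pp1 <- batch_idx(g$p1, B, P1, 0L)
  y1 <- pool_fwd(a1, pp1)

  P2 <- g$s2^2
  i2 <- batch_idx(g$idx2, B, P2, B * P2 + 1L)
  c2 <- conv_fwd(y1, p$conv2$W, p$conv2$b, i2)
  a2 <- pmax(c2$Y, 0)
  pp2 <- batch_idx(g$p2, B, P2, 0L)
  y2 <- pool_fwd(a2, pp2)
  bn <- bn_fwd(y2, p$bn2$gamma, p$bn2$beta,
               net$bn_state$rmean, net$bn_state$rvar, train)

  P3 <- g$s3^2
  i3 <- batch_idx(g$idx3, B, P3, B * P3 + 1L)
  c3 <- conv_fwd(bn$Y, p$conv3$W, p$conv3$b, i3)
  a3 <- pmax(c3$Y, 0)
  P3v <- g$s3v^2
  pp3 <- batch_idx(g$p3, B, P3v, 0L)
  y3 <- pool_fwd(a3, pp3)

  if (train && net$spec$dropout > 0) {
    mask <- (matrix(stats::runif(length(y3)), nrow(y3)) >= net$spec$dropout) /
      (1 - net$spec$dropout)
    y3d <- y3 * mask
  } else {
    mask <- NULL
    y3d <- y3
  }

  P4 <- g$s4^2
  xf <- flatten_fwd(y3d, B, P4)
  z1 <- xf %*% p$fc1$W + rep(p$fc1$b, each = B)
  z2 <- z1 %*% p$fc2$W + rep(p$fc2$b, each = B)
  z3 <- z2 %*% p$fc3$W + rep(p$fc3$b, each = B)

  out <- list(logits = z3, fc1 = z1, fc2 = z2, bn_state = bn[c("rmean", "rvar")])
  if (train)
    out$cache <- list(X0 = X0, i1 = i1, c1 = c1, a1 = a1, pp1 = pp1, y1 = y1,
                      i2 = i2, c2 = c2, a2 = a2, pp2 = pp2, y2 = y2, bn = bn,
                      i3 = i3, c3 = c3, a3 = a3, pp3 = pp3, y3 = y3,
                      mask = mask, xf = xf, z1 = z1, z2 = z2, B = B)
  out
}

backward_pass <- function(net, fwd, dlogits) {
  g <- net$geom; p <- net$params; cc <- fwd$cache
  B <- cc$B
  grads <- list()

  grads$fc3 <- list(W = crossprod(cc$z2, dlogits), b = colSums(dlogits))
  dz2 <- tcrossprod(dlogits, p$fc3$W)
  grads$fc2 <- list(W = crossprod(cc$z1, dz2), b = colSums(dz2))
  dz1 <- tcrossprod(dz2, p$fc2$W)
  grads$fc1 <- list(W = crossprod(cc$xf, dz1), b = colSums(dz1))
  dxf <- tcrossprod(dz1, p$fc1$W)

  P4 <- g$s4^2
  dy3d <- flatten_bwd(dxf, B, P4, net$spec$conv_filters[3])
  dy3 <- if (is.null(cc$mask)) dy3d else dy3d * cc$mask

  da3 <- pool_bwd(dy3, cc$y3, cc$a3, cc$pp3)
  dc3 <- da3 * (cc$c3$Y > 0)
  b3 <- conv_bwd(dc3, cc$c3$M, p$conv3$W, cc$i3,
                 B * g$s3^2, net$spec$conv_filters[2])
  grads$conv3 <- list(W = b3$dW, b = b3$db)

  bb <- bn_bwd(b3$dX, cc$bn$xhat, cc$bn$invstd, p$bn2$gamma)
  grads$bn2 <- list(gamma = bb$dgamma, beta = bb$dbeta)

  da2 <- pool_bwd(bb$dX, cc$y2, cc$a2, cc$pp2)
  dc2 <- da2 * (cc$c2$Y > 0)
  b2 <- conv_bwd(dc2, cc$c2$M, p$conv2$W, cc$i2,
                 B * g$s2^2, net$spec$conv_filters[1])
  grads$conv2 <- list(W = b2$dW, b = b2$db)

  da1 <- pool_bwd(b2$dX, cc$y1, cc$a1, cc$pp1)
  dc1 <- da1 * (cc$c1$Y > 0)
  b1 <- conv_bwd(dc1, cc$c1$M, p$conv1$W, cc$i1, B * g$s1^2, 1L)
  grads$conv1 <- list(W = b1$dW, b = b1$db)

  grads
}

# ---- exposed numerical operations ------------------------------------------

#' Softmax class probabilities
#'
#' Normalised exponential `P_k = exp(O_k) / sum_m exp(O_m)`, computed with a
#' max shift for overflow safety. Accepts a vector of logits or a matrix
#' (one row per instance).
#'
#' @param logits numeric vector or matrix of class activations.
#' @return probabilities of the same shape, each (row) summing to 1.
#' @export
softmax_probs <- function(logits) {
  if (is.matrix(logits)) {
    m <- apply(logits, 1, max)
    e <- exp(logits - m)
    return(e / rowSums(e))
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Cross-entropy loss
#'
#' `L(t, p) = -sum_x t(x) log(p(x))` for a one-hot target; the batch cost is
#' the mean negative log-likelihood over instances. Probabilities of exactly
#' zero at the target are clamped to `eps`.
#'
#' @param target one-hot numeric vector.
#' @param predicted probability vector summing to 1.
#' @param eps clamp for zero probabilities.
#' @return non-negative loss value.
#' @export
cross_entropy_loss <- function(target, predicted, eps = 1e-12) {
  stopifnot(length(target) == length(predicted))
  -sum(target * log(pmax(predicted, eps)))
}

#' One SGD-with-momentum update
#'
#' Classical momentum: `v <- mu * v - eta * (grad + lambda * W)`;
#' `W <- W + v`. The L2 term applies to weight matrices (and batch-norm
#' scale is exempt); biases are not decayed.
#'
#' @param state list with `params` and `velocity` (parallel structures).
#' @param gradients structure parallel to `params`.
#' @param cfg a [training_config()].
#' @return updated `state`.
#' @export
sgdm_update <- function(state, gradients, cfg) {
  for (layer in names(gradients)) {
    for (nm in names(gradients[[layer]])) {
      gmat <- gradients[[layer]][[nm]]
      if (any(!is.finite(gmat)))
        stop2("sgdm_update: non-finite gradient in ", layer, "$", nm)
      w <- state$params[[layer]][[nm]]
      decay <- if (nm == "W") cfg$l2 * w else 0
      v <- cfg$momentum * state$velocity[[layer]][[nm]] -
        cfg$lr * (gmat + decay)
      state$velocity[[layer]][[nm]] <- v
      state$params[[layer]][[nm]] <- w + v
    }
  }
  state
}

zero_like <- function(params) lapply(params, function(l) lapply(l, function(x) x * 0))

#' Train the network
#'
#' Epoch-wise stochastic gradient descent over seeded, shuffled mini-batches
#' with cross-entropy loss. Input normalisation is 'zerocenter': the mean
#' training image is subtracted from every input. Per-epoch mean mini-batch
#' loss and training accuracy are recorded in the history.
#'
#' @param net a [build_network()] result.
#' @param images n x side^2 matrix of raw pixels (see [images_to_matrix()]).
#' @param labels integer vector in \{0, 1\}.
#' @param cfg a [training_config()].
#' @return the trained network (history appended).
#' @export
train_network <- function(net, images, labels, cfg = training_config()) {
  if (nrow(images) == 0L) stop2("train_network: empty training set")
  labels <- as.integer(labels)
  if (length(unique(labels)) < net$spec$n_classes)
    stop2("train_network: class-coverage error - training set lacks a class")
  if (is.null(net$zerocenter)) net$zerocenter <- colMeans(images)
  if (cfg$epochs == 0L) return(net)
  set.seed(cfg$seed)
  state <- list(params = net$params, velocity = zero_like(net$params))
  n <- nrow(images)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    correct <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      rows <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- images[rows, , drop = FALSE]
      yb <- labels[rows]
      net$params <- state$params
      fwd <- forward_pass(net, xb, train = TRUE)
      net$bn_state <- fwd$bn_state
      P <- softmax_probs(fwd$logits)
      Tmat <- matrix(0, length(yb), net$spec$n_classes)
      Tmat[cbind(seq_along(yb), yb + 1L)] <- 1
      losses <- c(losses, mean(-log(pmax(P[cbind(seq_along(yb), yb + 1L)],
                                         1e-12))))
      correct <- correct + sum(max.col(P) - 1L == yb)
      dlogits <- (P - Tmat) / length(yb)
      grads <- backward_pass(net, fwd, dlogits)
      state <- sgdm_update(state, grads, cfg)
    }
    net$params <- state$params
    net$history <- rbind(net$history,
                         data.frame(epoch = ep, loss = mean(losses),
                                    accuracy = correct / n))
  }
  net
}

#' Convert a list of slices to a pixel matrix
#'
#' @param imgs list of [image8] objects of a common side.
#' @return n x side^2 numeric matrix (one column-major image per row).
#' @export
images_to_matrix <- function(imgs) {
  do.call(rbind, lapply(imgs, function(im) as.numeric(im)))
}

#' Harvest latent features from the fully connected layers
#'
#' Runs the network forward in inference mode (batch-norm running
#' statistics, dropout off) and returns the raw linear activations of FC1
#' (512) and FC2 (64) together with their concatenation `latent` (576),
#' ordered FC1 then FC2.
#'
#' @param net a trained network.
#' @param img an [image8] at the network's input side.
#' @return list with `fc1`, `fc2`, `latent`.
#' @export
extract_latent <- function(net, img) {
  if (nrow(img) != net$spec$input_side || ncol(img) != net$spec$input_side)
    stop2("extract_latent: expected a ", net$spec$input_side, "x",
          net$spec$input_side, " image")
  fwd <- forward_pass(net, matrix(as.numeric(img), nrow = 1), train = FALSE)
  list(fc1 = as.numeric(fwd$fc1), fc2 = as.numeric(fwd$fc2),
       latent = c(as.numeric(fwd$fc1), as.numeric(fwd$fc2)))
}

#' Latent features for many slices at once
#'
#' @param net a trained network.
#' @param images n x side^2 pixel matrix.
#' @param batch_size forward-pass batch size.
#' @return n x (fc1 + fc2) matrix, columns named `fc1_*`, `fc2_*`.
#' @export
extract_latent_matrix <- function(net, images, batch_size = 32L) {
  n <- nrow(images)
  w <- net$spec$fc_widths
  out <- matrix(0, n, sum(w))
  for (start in seq(1, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n)
    fwd <- forward_pass(net, images[rows, , drop = FALSE], train = FALSE)
    out[rows, ] <- cbind(fwd$fc1, fwd$fc2)
  }
  colnames(out) <- c(paste0("fc1_", seq_len(w[1])),
                     paste0("fc2_", seq_len(w[2])))
  out
}

#' Save / load a network checkpoint
#'
#' @param net a trained network.
#' @param path checkpoint file path.
#' @return `path` (save) or the network (load).
#' @export
save_network <- function(net, path) { saveRDS(net, path); invisible(path) }

#' @rdname save_network
#' @export
load_network <- function(path) readRDS(path)
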