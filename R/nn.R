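# Internal neural-network engine.
#
# Activations for a batch of N images of size H x W with C channels are
# stored as a (H*W*N) x C matrix, rows ordered spatial-position-fastest
# (column-major within an image: p = h + (w-1)*H), then image. 3x3
# same-padding convolutions are computed as nine shifted GEMMs: for each
# kernel offset (dy, dx) the valid output rows accumulate X[shifted rows] %*%
# W[dy,dx]. This keeps all heavy arithmetic inside BLAS and all index
# vectors precomputable per (H, W, N) shape, which is what makes a pure-R
# training loop fast enough for the reduced-scale benchmarks.

.nn_idx_cache <- new.env(parent = emptyenv())

conv_shifts <- expand.grid(dy = -1:1, dx = -1:1)

# Index vectors (input rows, output rows) for each of the 9 kernel offsets.
conv_indices <- function(H, W, N) {
  key <- sprintf("conv_%d_%d_%d", H, W, N)
  cached <- .nn_idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  offs <- (seq_len(N) - 1L) * (H * W)
  out <- lapply(seq_len(9), function(k) {
    dy <- conv_shifts$dy[k]; dx <- conv_shifts$dx[k]
    hs <- max(1L, 1L - dy):min(H, H - dy)
    ws <- max(1L, 1L - dx):min(W, W - dx)
    pos_out <- as.vector(outer(hs, (ws - 1L) * H, "+"))
    pos_in <- pos_out + dy + dx * H
    list(i_in = as.vector(outer(pos_in, offs, "+")),
         i_out = as.vector(outer(pos_out, offs, "+")))
  })
  .nn_idx_cache[[key]] <- out
  out
}

# 2x2 stride-2 max-pool input-row indices (4 taps per output position).
pool_indices <- function(H, W, N) {
  key <- sprintf("pool_%d_%d_%d", H, W, N)
  cached <- .nn_idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  i <- rep(seq_len(Ho), times = Wo)
  j <- rep(seq_len(Wo), each = Ho)
  base <- list((2L * i - 1L) + (2L * j - 2L) * H,
               (2L * i)      + (2L * j - 2L) * H,
               (2L * i - 1L) + (2L * j - 1L) * H,
               (2L * i)      + (2L * j - 1L) * H)
  offs <- (seq_len(N) - 1L) * (H * W)
  out <- list(taps = lapply(base, function(p) as.vector(outer(p, offs, "+"))),
              Ho = Ho, Wo = Wo)
  .nn_idx_cache[[key]] <- out
  out
}

# Gather the nine shifted copies of X into one (H*W*N) x 9C column matrix
# (zero rows where a shift falls outside the image), so a 3x3 convolution
# is a single GEMM against the stacked 9C x F kernel.
conv_im2col <- function(X, idx) {
  C <- ncol(X)
  Xcol <- matrix(0, nrow(X), 9L * C)
  for (k in seq_len(9)) {
    Xcol[idx[[k]]$i_out, ((k - 1L) * C + 1L):(k * C)] <-
      X[idx[[k]]$i_in, , drop = FALSE]
  }
  Xcol
}

conv_forward <- function(X, Wk, idx) {
  Xcol <- conv_im2col(X, idx)
  list(Y = Xcol %*% do.call(rbind, Wk), Xcol = Xcol)
}

conv_backward <- function(dY, Xcol, Wk, idx, n_rows_in) {
  C <- nrow(Wk[[1]])
  dWflat <- crossprod(Xcol, dY)
  dXcol <- dY %*% t(do.call(rbind, Wk))
  dX <- matrix(0, n_rows_in, C)
  for (k in seq_len(9)) {
    ii <- idx[[k]]$i_in
    dX[ii, ] <- dX[ii, ] +
      dXcol[idx[[k]]$i_out, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
  }
  dW <- lapply(seq_len(9), function(k) {
    dWflat[((k - 1L) * C + 1L):(k * C), , drop = FALSE]
  })
  list(dX = dX, dW = dW)
}

# Column-wise (per-channel) arithmetic without sweep()'s aperm overhead.
col_add <- function(X, v) X + rep(v, each = nrow(X))
col_sub <- function(X, v) X - rep(v, each = nrow(X))
col_mul <- function(X, v) X * rep(v, each = nrow(X))

bn_eps <- 1e-5
bn_momentum <- 0.9

# Batch normalisation over columns (channels). In training mode batch
# statistics are used and the running estimates updated; in eval mode the
# frozen running statistics are applied, so prediction-time passes differ
# only through dropout.
bn_forward <- function(X, bn, training) {
  if (training) {
    mu <- .colMeans(X, nrow(X), ncol(X))
    xc <- col_sub(X, mu)
    v <- .colMeans(xc * xc, nrow(X), ncol(X))
    istd <- 1 / sqrt(v + bn_eps)
    xhat <- col_mul(xc, istd)
    Y <- col_add(col_mul(xhat, bn$g), bn$b)
    bn$rm <- bn_momentum * bn$rm + (1 - bn_momentum) * mu
    bn$rv <- bn_momentum * bn$rv + (1 - bn_momentum) * v
    list(Y = Y, cache = list(xhat = xhat, istd = istd), bn = bn)
  } else {
    istd <- 1 / sqrt(bn$rv + bn_eps)
    xhat <- col_mul(col_sub(X, bn$rm), istd)
    list(Y = col_add(col_mul(xhat, bn$g), bn$b), cache = NULL, bn = bn)
  }
}

bn_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- col_mul(dY, g)
  m1 <- .colMeans(dxhat, nrow(dY), ncol(dY))
  m2 <- .colMeans(dxhat * xhat, nrow(dY), ncol(dY))
  dX <- col_mul(col_sub(dxhat, m1) - col_mul(xhat, m2), cache$istd)
  list(dX = dX, dg = dg, db = db)
}

pool_forward <- function(X, idx) {
  taps <- lapply(idx$taps, function(i) X[i, , drop = FALSE])
  Y <- pmax(taps[[1]], taps[[2]], taps[[3]], taps[[4]])
  list(Y = Y, cache = list(taps = taps, Y = Y))
}

pool_backward <- function(dY, cache, idx, n_in) {
  dX <- matrix(0, n_in, ncol(dY))
  assigned <- matrix(FALSE, nrow(dY), ncol(dY))
  for (k in seq_len(4)) {
    sel <- (cache$taps[[k]] == cache$Y) & !assigned
    assigned <- assigned | sel
    ik <- idx$taps[[k]]
    dX[ik, ] <- dX[ik, ] + dY * sel
  }
  dX
}

gap_forward <- function(X, HW, N) {
  Y <- rowsum(X, group = rep(seq_len(N), each = HW), reorder = FALSE) / HW
  dimnames(Y) <- NULL
  Y
}

gap_backward <- function(dY, HW, N) {
  dY[rep(seq_len(N), each = HW), , drop = FALSE] / HW
}

dense_forward <- function(X, lay) col_add(X %*% lay$W, lay$b)

dense_backward <- function(dY, X, lay) {
  list(dX = dY %*% t(lay$W), dW = crossprod(X, dY), db = colSums(dY))
}

relu <- function(X) X * (X > 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- parameter tree utilities -------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map3(f, a[[i]], b[[i]], c[[i]])
    out
  } else f(a, b, c)
}

adam_init <- function(params) {
  zeros <- tree_map(function(x) x * 0, params)
  list(m = zeros, v = tree_map(function(x) x * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map3(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                      params, state$m, state$v)
  list(params = params, state = state)
}

# ---- parameter initialisation -------------------------------------------

init_conv <- function(c_in, c_out) {
  sd <- sqrt(2 / (9 * c_in))
  lapply(seq_len(9), function(k) {
    matrix(stats::rnorm(c_in * c_out, sd = sd), c_in, c_out)
  })
}

init_bn <- function(c_out) {
  list(g = rep(1, c_out), b = rep(0, c_out),
       rm = rep(0, c_out), rv = rep(1, c_out))
}

init_dense <- function(f_in, f_out) {
  list(W = matrix(stats::rnorm(f_in * f_out, sd = sqrt(2 / f_in)), f_in, f_out),
       b = rep(0, f_out))
}

# Softmax heads start near zero so the initial predictive distribution is
# close to uniform (initial loss ~ log M) and early training is stable.
init_head <- function(f_in, f_out) {
  list(W = matrix(stats::rnorm(f_in * f_out, sd = 0.01), f_in, f_out),
       b = rep(0, f_out))
}

init_params <- function(config, seed) {
  with_seed(seed, {
    f <- config$filters
    h <- config$head_hidden_units
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      list(c1 = init_conv(f, f), bn1 = init_bn(f),
           c2 = init_conv(f, f), bn2 = init_bn(f))
    })
    list(stem = list(W = init_conv(3L, f), bn = init_bn(f)),
         blocks = blocks,
         fc1 = init_dense(f, h),
         aux = init_head(h, config$n_classes),
         fc2 = init_dense(h, h),
         fin = init_head(h, config$n_classes))
  })
}

count_params <- function(params) {
  total <- 0
  tree_map(function(x) { total <<- total + length(x); x }, params)
  total
}

# ---- trunk forward/backward ---------------------------------------------

# X: (H*W*N) x 3 matrix of normalised pixels. Returns GAP features (N x F),
# caches for backprop (training mode), and params with updated BN running
# statistics.
trunk_forward <- function(params, X, H, W, N, training) {
  cache <- list()
  idx <- conv_indices(H, W, N)
  cs <- conv_forward(X, params$stem$W, idx)
  bnr <- bn_forward(cs$Y, params$stem$bn, training)
  params$stem$bn <- bnr$bn
  a0 <- relu(bnr$Y)
  spidx <- pool_indices(H, W, N)   # early downsample after the stem
  spf <- pool_forward(a0, spidx)
  a <- spf$Y
  cache$stem <- list(Xcol = if (training) cs$Xcol, bn = bnr$cache,
                     pre = bnr$Y, idx = idx, pidx = spidx, pool = spf$cache,
                     n_rows = nrow(a0))
  h <- H %/% 2L; w <- W %/% 2L
  cache$blocks <- vector("list", length(params$blocks))
  for (b in seq_along(params$blocks)) {
    blk <- params$blocks[[b]]
    idx <- conv_indices(h, w, N)
    c1 <- conv_forward(a, blk$c1, idx)
    bn1 <- bn_forward(c1$Y, blk$bn1, training)
    params$blocks[[b]]$bn1 <- bn1$bn
    a1 <- relu(bn1$Y)
    c2 <- conv_forward(a1, blk$c2, idx)
    bn2 <- bn_forward(c2$Y, blk$bn2, training)
    params$blocks[[b]]$bn2 <- bn2$bn
    s <- bn2$Y + a           # residual connection
    r <- relu(s)
    pidx <- pool_indices(h, w, N)
    pf <- pool_forward(r, pidx)
    cache$blocks[[b]] <- list(
      Xcol1 = if (training) c1$Xcol, Xcol2 = if (training) c2$Xcol,
      bn1 = bn1$cache, pre1 = bn1$Y, bn2 = bn2$cache, s = s,
      pool = pf$cache, idx = idx, pidx = pidx, h = h, w = w)
    a <- pf$Y
    h <- h %/% 2L; w <- w %/% 2L
  }
  feats <- gap_forward(a, h * w, N)
  cache$final_hw <- c(h, w)
  list(feats = feats, cache = if (training) cache else NULL, params = params)
}

trunk_backward <- function(params, cache, dfeats, N) {
  hw <- cache$final_hw
  da <- gap_backward(dfeats, hw[1] * hw[2], N)
  gblocks <- vector("list", length(params$blocks))
  for (b in rev(seq_along(params$blocks))) {
    blk <- params$blocks[[b]]
    cb <- cache$blocks[[b]]
    dr <- pool_backward(da, cb$pool, cb$pidx, nrow(cb$s))
    ds <- dr * (cb$s > 0)
    bb2 <- bn_backward(ds, cb$bn2, blk$bn2$g)
    cv2 <- conv_backward(bb2$dX, cb$Xcol2, blk$c2, cb$idx, nrow(cb$s))
    da1 <- cv2$dX * (cb$pre1 > 0)
    bb1 <- bn_backward(da1, cb$bn1, blk$bn1$g)
    cv1 <- conv_backward(bb1$dX, cb$Xcol1, blk$c1, cb$idx, nrow(cb$s))
    da <- cv1$dX + ds        # gradient through the residual skip
    gblocks[[b]] <- list(
      c1 = cv1$dW, bn1 = list(g = bb1$dg, b = bb1$db,
                              rm = blk$bn1$rm * 0, rv = blk$bn1$rv * 0),
      c2 = cv2$dW, bn2 = list(g = bb2$dg, b = bb2$db,
                              rm = blk$bn2$rm * 0, rv = blk$bn2$rv * 0))
  }
  da0 <- pool_backward(da, cache$stem$pool, cache$stem$pidx,
                       cache$stem$n_rows)
  dstem_a <- da0 * (cache$stem$pre > 0)
  bbs <- bn_backward(dstem_a, cache$stem$bn, params$stem$bn$g)
  cvs <- conv_backward(bbs$dX, cache$stem$Xcol, params$stem$W,
                       cache$stem$idx, nrow(dstem_a))
  list(grads = list(
    stem = list(W = cvs$dW, bn = list(g = bbs$dg, b = bbs$db,
                                      rm = params$stem$bn$rm * 0,
                                      rv = params$stem$bn$rv * 0)),
    blocks = gblocks,
    fc1 = NULL, aux = NULL, fc2 = NULL, fin = NULL))
}

# ---- heads ---------------------------------------------------------------

# Dropout-bearing dual heads over GAP features.
# mode "det":  dropout disabled (deterministic prediction)
# mode "train": per-element inverted dropout masks drawn from the RNG
# mode "mc":  caller-supplied per-unit masks (one weight sample per pass)
head_forward <- function(params, feats, dropout_rate, mode = "det",
                         masks = NULL) {
  n <- nrow(feats)
  h1 <- relu(dense_forward(feats, params$fc1))
  d1mask <- switch(mode,
    det = NULL,
    train = matrix((stats::runif(length(h1)) >= dropout_rate) /
                     (1 - dropout_rate), n, ncol(h1)),
    mc = matrix(masks$m1, n, ncol(h1), byrow = TRUE))
  d1 <- if (is.null(d1mask)) h1 else h1 * d1mask
  za <- dense_forward(d1, params$aux)
  pa <- softmax_rows(za)
  h2 <- relu(dense_forward(d1, params$fc2))
  d2mask <- switch(mode,
    det = NULL,
    train = matrix((stats::runif(length(h2)) >= dropout_rate) /
                     (1 - dropout_rate), n, ncol(h2)),
    mc = matrix(masks$m2, n, ncol(h2), byrow = TRUE))
  d2 <- if (is.null(d2mask)) h2 else h2 * d2mask
  zf <- dense_forward(d2, params$fin)
  pf <- softmax_rows(zf)
  list(final = pf, aux = pa,
       cache = list(feats = feats, h1 = h1, d1 = d1, d1mask = d1mask,
                    h2 = h2, d2 = d2, d2mask = d2mask))
}

head_backward <- function(params, cache, dzf, dza) {
  gfin <- dense_backward(dzf, cache$d2, params$fin)
  dd2 <- gfin$dX
  dh2 <- if (is.null(cache$d2mask)) dd2 else dd2 * cache$d2mask
  dh2 <- dh2 * (cache$h2 > 0)
  gfc2 <- dense_backward(dh2, cache$d1, params$fc2)
  gaux <- dense_backward(dza, cache$d1, params$aux)
  dd1 <- gfc2$dX + gaux$dX
  dh1 <- if (is.null(cache$d1mask)) dd1 else dd1 * cache$d1mask
  dh1 <- dh1 * (cache$h1 > 0)
  gfc1 <- dense_backward(dh1, cache$feats, params$fc1)
  list(grads = list(fc1 = list(W = gfc1$dW, b = gfc1$db),
                    aux = list(W = gaux$dW, b = gaux$db),
                    fc2 = list(W = gfc2$dW, b = gfc2$db),
                    fin = list(W = gfin$dW, b = gfin$db)),
       dfeats = gfc1$dX)
}

# ---- full loss + gradient ------------------------------------------------

cross_entropy_rows <- function(P, y) {
  p <- P[cbind(seq_along(y), y)]
  -log(pmax(p, 1e-12))
}

# Weighted dual-head loss and full parameter gradient for one mini-batch.
# X: (H*W*N) x 3, y: length-N 1-based labels. `mode` as in head_forward.
nn_loss_grads <- function(params, X, y, config, final_weight = 0.9,
                          aux_weight = 0.1, mode = "train", masks = NULL) {
  H <- config$input_size[1]; W <- config$input_size[2]
  N <- length(y)
  tf <- trunk_forward(params, X, H, W, N, training = TRUE)
  params <- tf$params
  hf <- head_forward(params, tf$feats, config$dropout_rate, mode = mode,
                     masks = masks)
  loss <- mean(final_weight * cross_entropy_rows(hf$final, y) +
                 aux_weight * cross_entropy_rows(hf$aux, y))
  Y1 <- matrix(0, N, config$n_classes)
  Y1[cbind(seq_len(N), y)] <- 1
  dzf <- final_weight * (hf$final - Y1) / N
  dza <- aux_weight * (hf$aux - Y1) / N
  hb <- head_backward(params, hf$cache, dzf, dza)
  tb <- trunk_backward(params, tf$cache, hb$dfeats, N)
  grads <- tb$grads
  grads$fc1 <- hb$grads$fc1
  grads$aux <- hb$grads$aux
  grads$fc2 <- hb$grads$fc2
  grads$fin <- hb$grads$fin
  acc <- mean(max.col(hf$final, ties.method = "first") == y)
  list(loss = loss, acc = acc, grads = grads, params = params)
}
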