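# Compact U-Net implementation used by both pipeline stages.
#
# The network is an encoder-decoder with skip connections: each encoder
# level applies two 3x3 convolutions, each followed by batch normalization
# and ReLU, then 2x2 max pooling; the bottleneck adds dropout; each decoder
# level upsamples with a learned 2x2 transposed convolution, concatenates
# the encoder skip feature, and applies two conv+BN+ReLU pairs; a final 1x1
# convolution produces two-class per-pixel scores. Being fully
# convolutional, the same network runs on any input whose spatial
# dimensions are divisible by 2^depth.
#
# Internal tensor layout: a mini-batch of N single- or multi-channel images
# of H x W pixels is a matrix with N*H*W rows (sample-major, then row-major
# pixels) and one column per channel. Convolutions are im2col gathers
# followed by one BLAS matrix product, which is where almost all the
# arithmetic happens.

.idx_cache <- new.env(parent = emptyenv())

# row-index sets for a given (H, W, N): im2col gather indices for a 3x3
# neighbourhood over a zero-padded image, and 2x2 block indices for
# pooling / upsampling
conv_indices <- function(H, W, N) {
  key <- paste(H, W, N, sep = "x")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  R <- N * H * W
  r0 <- seq_len(R) - 1L
  n <- r0 %/% (H * W)
  rem <- r0 %% (H * W)
  i <- rem %/% W + 1L
  j <- rem %% W + 1L
  Hp <- H + 2L; Wp <- W + 2L
  rp <- function(ii, jj) (n * Hp + (ii - 1L)) * Wp + jj  # 1-based via jj
  interior <- rp(i + 1L, j + 1L)
  off <- vector("list", 9L)
  o <- 0L
  for (di in -1L:1L) for (dj in -1L:1L) {
    o <- o + 1L
    off[[o]] <- rp(i + 1L + di, j + 1L + dj)
  }
  out <- list(interior = interior, off = off, Rp = N * Hp * Wp)
  if (H %% 2L == 0L && W %% 2L == 0L) {
    h <- H %/% 2L; w <- W %/% 2L
    Ro <- N * h * w
    q0 <- seq_len(Ro) - 1L
    nn <- q0 %/% (h * w)
    qq <- q0 %% (h * w)
    io <- qq %/% w + 1L
    jo <- qq %% w + 1L
    rfull <- function(ii, jj) (nn * H + (ii - 1L)) * W + jj
    blk <- vector("list", 4L)
    k <- 0L
    for (a in 1:2) for (b in 1:2) {
      k <- k + 1L
      blk[[k]] <- rfull(2L * io - 2L + a, 2L * jo - 2L + b)
    }
    out$block <- blk
  }
  .idx_cache[[key]] <- out
  out
}

im2col <- function(X, H, W, N) {
  ids <- conv_indices(H, W, N)
  C <- ncol(X)
  Xp <- matrix(0, ids$Rp, C)
  Xp[ids$interior, ] <- X
  do.call(cbind, lapply(ids$off, function(ix) Xp[ix, , drop = FALSE]))
}

col2im <- function(dXcol, H, W, N, C) {
  ids <- conv_indices(H, W, N)
  dXp <- matrix(0, ids$Rp, C)
  for (o in 1:9) {
    ix <- ids$off[[o]]
    dXp[ix, ] <- dXp[ix, ] + dXcol[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  }
  dXp[ids$interior, , drop = FALSE]
}

#' U-Net architecture configuration
#'
#' @param depth number of pooling levels (input dims must be divisible by
#'   `2^depth`). The production default is the standard depth 4; the
#'   desk-scale profile uses depth 3.
#' @param base_filters filters at the first encoder level; doubled per
#'   level (standard default 64; desk profile 8).
#' @param dropout_rate dropout probability at the bottleneck, in [0, 1).
#' @param in_channels input channels (1 for grayscale slices).
#' @param n_classes output classes (2: structure vs background).
#' @return object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_filters = 64L, dropout_rate = 0.5,
                        in_channels = 1L, n_classes = 2L) {
  stopifnot(depth >= 1, base_filters >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 dropout_rate = dropout_rate,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes)),
            class = "unet_config")
}

# channel widths per encoder level
level_filters <- function(cfg) cfg$base_filters * 2L^(seq_len(cfg$depth) - 1L)

#' Build an untrained U-Net
#'
#' Initializes all parameters (He-normal convolution weights, unit-gain
#' batch norm) from the given seed.
#'
#' @param cfg a [unet_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `unet_model` with `params`, `stats` (batch norm
#'   running moments) and `cfg`.
#' @export
build_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  set.seed(seed)
  params <- list(); stats <- list()
  he <- function(nin, nout, fan_in) {
    matrix(rnorm(nin * nout, sd = sqrt(2 / fan_in)), nin, nout)
  }
  add_conv <- function(name, cin, cout) {
    params[[paste0(name, ".W")]] <<- he(9L * cin, cout, 9L * cin)
    params[[paste0(name, ".gamma")]] <<- rep(1, cout)
    params[[paste0(name, ".beta")]] <<- rep(0, cout)
    stats[[paste0(name, ".mean")]] <<- rep(0, cout)
    stats[[paste0(name, ".var")]] <<- rep(1, cout)
  }
  f <- level_filters(cfg)
  cin <- cfg$in_channels
  for (l in seq_len(cfg$depth)) {
    add_conv(sprintf("enc%da", l), cin, f[l])
    add_conv(sprintf("enc%db", l), f[l], f[l])
    cin <- f[l]
  }
  fb <- cfg$base_filters * 2L^cfg$depth
  add_conv("bota", cin, fb)
  add_conv("botb", fb, fb)
  deep <- fb
  for (l in rev(seq_len(cfg$depth))) {
    params[[sprintf("up%d.W", l)]] <- he(deep, 4L * f[l], deep)
    params[[sprintf("up%d.b", l)]] <- rep(0, f[l])
    add_conv(sprintf("dec%da", l), 2L * f[l], f[l])
    add_conv(sprintf("dec%db", l), f[l], f[l])
    deep <- f[l]
  }
  params[["out.W"]] <- he(cfg$base_filters, cfg$n_classes, cfg$base_filters)
  params[["out.b"]] <- rep(0, cfg$n_classes)
  structure(list(cfg = cfg, params = params, stats = stats),
            class = "unet_model")
}

# ---- layer primitives -------------------------------------------------

bn_stat_momentum <- 0.1
bn_eps <- 1e-5

conv_bn_relu_fwd <- function(X, params, stats, name, H, W, N, training) {
  Wm <- params[[paste0(name, ".W")]]
  gamma <- params[[paste0(name, ".gamma")]]
  beta <- params[[paste0(name, ".beta")]]
  Y <- im2col(X, H, W, N) %*% Wm
  if (training) {
    mu <- colMeans(Y)
    Yc <- sweep(Y, 2, mu)
    v <- colMeans(Yc * Yc)
    inv_sd <- 1 / sqrt(v + bn_eps)
    xhat <- sweep(Yc, 2, inv_sd, "*")
    stats[[paste0(name, ".mean")]] <-
      (1 - bn_stat_momentum) * stats[[paste0(name, ".mean")]] + bn_stat_momentum * mu
    stats[[paste0(name, ".var")]] <-
      (1 - bn_stat_momentum) * stats[[paste0(name, ".var")]] + bn_stat_momentum * v
  } else {
    mu <- stats[[paste0(name, ".mean")]]
    inv_sd <- 1 / sqrt(stats[[paste0(name, ".var")]] + bn_eps)
    xhat <- sweep(sweep(Y, 2, mu), 2, inv_sd, "*")
  }
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  mask <- out > 0
  out[!mask] <- 0
  cache <- if (training) list(X = X, xhat = xhat, inv_sd = inv_sd,
                              mask = mask, H = H, W = W, N = N) else NULL
  list(out = out, cache = cache, stats = stats)
}

conv_bn_relu_bwd <- function(dOut, params, name, cache) {
  Wm <- params[[paste0(name, ".W")]]
  gamma <- params[[paste0(name, ".gamma")]]
  dY <- dOut
  dY[!cache$mask] <- 0
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dConv <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*"),
                 2, cache$inv_sd, "*")
  Xcol <- im2col(cache$X, cache$H, cache$W, cache$N)
  dW <- crossprod(Xcol, dConv)
  dXcol <- tcrossprod(dConv, Wm)
  dX <- col2im(dXcol, cache$H, cache$W, cache$N, ncol(cache$X))
  grads <- list(dW, dgamma, dbeta)
  names(grads) <- paste0(name, c(".W", ".gamma", ".beta"))
  list(dX = dX, grads = grads)
}

maxpool_fwd <- function(X, H, W, N) {
  ids <- conv_indices(H, W, N)
  A1 <- X[ids$block[[1]], , drop = FALSE]
  out <- A1
  winner <- matrix(1L, nrow(out), ncol(out))
  for (k in 2:4) {
    Ak <- X[ids$block[[k]], , drop = FALSE]
    sel <- Ak > out
    out[sel] <- Ak[sel]
    winner[sel] <- k
  }
  list(out = out, winner = winner)
}

maxpool_bwd <- function(dY, winner, H, W, N, C) {
  ids <- conv_indices(H, W, N)
  dX <- matrix(0, N * H * W, C)
  for (k in 1:4) {
    sel <- winner == k
    if (!any(sel)) next
    tmp <- matrix(0, nrow(dY), C)
    tmp[sel] <- dY[sel]
    ix <- ids$block[[k]]
    dX[ix, ] <- dX[ix, ] + tmp
  }
  dX
}

upconv_fwd <- function(X, Wu, bu, h, w, N) {
  cout <- length(bu)
  Z <- X %*% Wu
  ids <- conv_indices(2L * h, 2L * w, N)
  out <- matrix(0, N * 4L * h * w, cout)
  for (k in 1:4) {
    out[ids$block[[k]], ] <- Z[, ((k - 1L) * cout + 1L):(k * cout), drop = FALSE]
  }
  sweep(out, 2, bu, "+")
}

upconv_bwd <- function(dOut, X, Wu, bu, h, w, N) {
  cout <- length(bu)
  ids <- conv_indices(2L * h, 2L * w, N)
  dZ <- do.call(cbind, lapply(1:4, function(k) {
    dOut[ids$block[[k]], , drop = FALSE]
  }))
  list(dX = tcrossprod(dZ, Wu),
       dW = crossprod(X, dZ),
       db = colSums(dOut))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- full network ------------------------------------------------------

unet_forward <- function(model, X, H, W, N, training = FALSE) {
  cfg <- model$cfg; p <- model$params; st <- model$stats
  if (H %% 2L^cfg$depth != 0L || W %% 2L^cfg$depth != 0L) {
    stop(sprintf(
      "input %d x %d not divisible by 2^depth = %d; the encoder cannot pool it",
      H, W, 2L^cfg$depth))
  }
  caches <- list(); skips <- list(); skip_dims <- list()
  curH <- H; curW <- W
  for (l in seq_len(cfg$depth)) {
    a <- conv_bn_relu_fwd(X, p, st, sprintf("enc%da", l), curH, curW, N, training)
    st <- a$stats
    b <- conv_bn_relu_fwd(a$out, p, st, sprintf("enc%db", l), curH, curW, N, training)
    st <- b$stats
    caches[[sprintf("enc%da", l)]] <- a$cache
    caches[[sprintf("enc%db", l)]] <- b$cache
    skips[[l]] <- b$out; skip_dims[[l]] <- c(curH, curW)
    pl <- maxpool_fwd(b$out, curH, curW, N)
    caches[[sprintf("pool%d", l)]] <- list(winner = pl$winner, H = curH, W = curW)
    X <- pl$out
    curH <- curH %/% 2L; curW <- curW %/% 2L
  }
  a <- conv_bn_relu_fwd(X, p, st, "bota", curH, curW, N, training); st <- a$stats
  b <- conv_bn_relu_fwd(a$out, p, st, "botb", curH, curW, N, training); st <- b$stats
  caches[["bota"]] <- a$cache; caches[["botb"]] <- b$cache
  X <- b$out
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    dmask <- (matrix(runif(length(X)), nrow(X), ncol(X)) < keep) / keep
    X <- X * dmask
    caches[["dropout"]] <- dmask
  }
  for (l in rev(seq_len(cfg$depth))) {
    Wu <- p[[sprintf("up%d.W", l)]]; bu <- p[[sprintf("up%d.b", l)]]
    caches[[sprintf("upin%d", l)]] <- X
    up <- upconv_fwd(X, Wu, bu, curH, curW, N)
    curH <- curH * 2L; curW <- curW * 2L
    X <- cbind(up, skips[[l]])
    a <- conv_bn_relu_fwd(X, p, st, sprintf("dec%da", l), curH, curW, N, training)
    st <- a$stats
    b <- conv_bn_relu_fwd(a$out, p, st, sprintf("dec%db", l), curH, curW, N, training)
    st <- b$stats
    caches[[sprintf("dec%da", l)]] <- a$cache
    caches[[sprintf("dec%db", l)]] <- b$cache
    X <- b$out
  }
  logits <- sweep(X %*% p[["out.W"]], 2, p[["out.b"]], "+")
  caches[["outin"]] <- if (training) X else NULL
  list(logits = logits, caches = caches, stats = st,
       dims = list(H = H, W = W, N = N))
}

# cross-entropy loss and gradient for integer labels in 1..n_classes
softmax_ce <- function(logits, labels) {
  P <- softmax_rows(logits)
  R <- nrow(P)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(R), labels)] + eps))
  dlogits <- P
  dlogits[cbind(seq_len(R), labels)] <- dlogits[cbind(seq_len(R), labels)] - 1
  list(loss = loss, dlogits = dlogits / R, probs = P)
}

unet_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg; p <- model$params; caches <- fwd$caches
  H <- fwd$dims$H; W <- fwd$dims$W; N <- fwd$dims$N
  grads <- list()
  grads[["out.W"]] <- crossprod(caches[["outin"]], dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  dX <- tcrossprod(dlogits, p[["out.W"]])
  f <- level_filters(cfg)
  curH <- H; curW <- W
  dskips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    b <- conv_bn_relu_bwd(dX, p, sprintf("dec%db", l), caches[[sprintf("dec%db", l)]])
    a <- conv_bn_relu_bwd(b$dX, p, sprintf("dec%da", l), caches[[sprintf("dec%da", l)]])
    grads <- c(grads, b$grads, a$grads)
    dconcat <- a$dX
    dup <- dconcat[, seq_len(f[l]), drop = FALSE]
    dskips[[l]] <- dconcat[, f[l] + seq_len(f[l]), drop = FALSE]
    ub <- upconv_bwd(dup, caches[[sprintf("upin%d", l)]],
                     p[[sprintf("up%d.W", l)]], p[[sprintf("up%d.b", l)]],
                     curH %/% 2L, curW %/% 2L, N)
    grads[[sprintf("up%d.W", l)]] <- ub$dW
    grads[[sprintf("up%d.b", l)]] <- ub$db
    dX <- ub$dX
    curH <- curH %/% 2L; curW <- curW %/% 2L
  }
  if (!is.null(caches[["dropout"]])) dX <- dX * caches[["dropout"]]
  b <- conv_bn_relu_bwd(dX, p, "botb", caches[["botb"]])
  a <- conv_bn_relu_bwd(b$dX, p, "bota", caches[["bota"]])
  grads <- c(grads, b$grads, a$grads)
  dX <- a$dX
  for (l in rev(seq_len(cfg$depth))) {
    pc <- caches[[sprintf("pool%d", l)]]
    dX <- maxpool_bwd(dX, pc$winner, pc$H, pc$W, N, ncol(dX))
    dX <- dX + dskips[[l]]
    b <- conv_bn_relu_bwd(dX, p, sprintf("enc%db", l), caches[[sprintf("enc%db", l)]])
    a <- conv_bn_relu_bwd(b$dX, p, sprintf("enc%da", l), caches[[sprintf("enc%da", l)]])
    grads <- c(grads, b$grads, a$grads)
    dX <- a$dX
  }
  grads
}

# stack a list of matrices into the internal (N*H*W) x 1 layout
stack_images <- function(images) {
  matrix(unlist(lapply(images, function(m) as.vector(t(m)))), ncol = 1)
}

stack_labels <- function(masks) {
  as.integer(unlist(lapply(masks, function(m) as.vector(t(m))))) + 1L
}

#' Predict a per-pixel probability map
#'
#' Runs the network in evaluation mode (batch norm running statistics, no
#' dropout) and returns the positive-class probability per pixel. The two
#' class scores are softmax-normalized and sum to one.
#'
#' @param model a `unet_model` or `trained_unet`.
#' @param image numeric matrix whose dimensions are divisible by
#'   `2^depth`.
#' @param backend `"cpp"` (compiled single-precision backend, the default)
#'   or `"r"` (pure-R double-precision reference implementation). The two
#'   implement the same network; the reference path exists for verification
#'   and numerical experiments.
#' @return matrix of positive-class probabilities in [0, 1], same size as
#'   `image`.
#' @export
predict_map <- function(model, image, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  H <- nrow(image); W <- ncol(image)
  X <- stack_images(list(image))
  if (backend == "cpp") {
    cfg <- model$cfg
    p2 <- cpp_unet_predict(model$params, model$stats, as.numeric(X),
                           H, W, 1L, cfg$depth, cfg$base_filters, bn_eps)
    return(matrix(p2, H, W, byrow = TRUE))
  }
  fwd <- unet_forward(model, X, H, W, 1L, training = FALSE)
  P <- softmax_rows(fwd$logits)
  matrix(P[, 2], H, W, byrow = TRUE)
}
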