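#' @useDynLib renodce, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Self-contained 2D CNN engine: 3x3 "same" convolutions, batch normalisation,
# dropout, 2x2 max-pooling, 2x2 stride-2 transposed convolutions, sigmoid
# head, and SGD-with-momentum backprop. Tensors are R arrays (H, W, C, N);
# the convolution/pooling kernels live in src/nn_ops.cpp (im2col + GEMM).
# ---------------------------------------------------------------------------

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

# Batch-norm forward. `stats_env[[key]]` holds running moments; in training
# mode they are updated with momentum 0.1 (biased batch variance, as is
# conventional for small feature-map statistics).
bn_fw <- function(z, gamma, beta, stats_env, key, training, eps = 1e-5) {
  d <- dim(z); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (training) {
    zm <- matrix(z, hw, C * N)
    cm <- colMeans(zm)
    cm2 <- colMeans(zm^2)
    mu <- rowMeans(matrix(cm, C, N))
    var <- rowMeans(matrix(cm2, C, N)) - mu^2
    var <- pmax(var, 0)
    rs <- stats_env[[key]]
    rs$run_mean <- 0.9 * rs$run_mean + 0.1 * mu
    rs$run_var <- 0.9 * rs$run_var + 0.1 * var
    stats_env[[key]] <- rs
  } else {
    rs <- stats_env[[key]]
    mu <- rs$run_mean; var <- rs$run_var
  }
  istd <- 1 / sqrt(var + eps)
  xhat <- channel_affine(z, istd, -mu * istd)
  y <- channel_affine(xhat, gamma, beta)
  list(y = y, xhat = xhat, istd = istd, gamma = gamma)
}

bn_bw <- function(dy, cache) {
  d <- dim(dy); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]; m <- hw * N
  xhat <- cache$xhat
  dym <- matrix(dy, hw, C * N); xm <- matrix(xhat, hw, C * N)
  s1 <- rowSums(matrix(colSums(dym), C, N))            # sum dy per channel
  s2 <- rowSums(matrix(colSums(dym * xm), C, N))       # sum dy*xhat
  dx <- bn_bw_dx(dy, xhat, s1, s2, cache$gamma * cache$istd, m)
  list(dx = dx, dgamma = s2, dbeta = s1)
}

relu_fw <- function(z) relu_fw_cpp(z)

#' Build the U-Net segmentation network
#'
#' Constructs the encoder--decoder convolutional network used for coarse
#' kidney segmentation: `depth` contraction levels of paired 3x3
#' convolution + batch-normalisation layers with ReLU activations and
#' dropout between the two pairs, 2x2 max-pooling between levels, a
#' bottleneck at `base_filters * 2^depth` feature maps, a symmetric expansion
#' path using 2x2 transposed convolutions with skip concatenations, and a
#' final 1x1 convolution with sigmoid output. Weights are initialised with
#' the He scheme scaled by fan-in.
#'
#' @param depth number of down-sampling levels (default 4).
#' @param base_filters feature maps at the first level (default 64; doubles
#'   at each level so the default bottleneck has 1024).
#' @param dropout dropout rate applied between the two conv--BN pairs of
#'   each encoder block (default 0.2); inactive at inference.
#' @param in_channels input image channels (default 1).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `unet` holding parameters, running
#'   batch-norm statistics and the architecture configuration.
#' @examples
#' net <- build_unet(depth = 2, base_filters = 4, seed = 1)
#' @export
build_unet <- function(depth = 4L, base_filters = 64L, dropout = 0.2,
                       in_channels = 1L, seed = 1L) {
  stopifnot(depth >= 1, base_filters >= 1, dropout >= 0, dropout < 1)
  set.seed(seed)
  params <- list()
  state <- new.env(parent = emptyenv())
  filt <- base_filters * 2^(seq_len(depth) - 1)
  cin <- in_channels
  for (l in seq_len(depth)) {
    f <- filt[l]
    params[[paste0("enc", l, ".c1.W")]] <- he_init(3, cin, f)
    params[[paste0("enc", l, ".c1.b")]] <- rep(0, f)
    params[[paste0("enc", l, ".c2.W")]] <- he_init(3, f, f)
    params[[paste0("enc", l, ".c2.b")]] <- rep(0, f)
    for (j in 1:2) {
      bn <- new_bn(f)
      params[[paste0("enc", l, ".bn", j, ".gamma")]] <- bn$gamma
      params[[paste0("enc", l, ".bn", j, ".beta")]] <- bn$beta
      state[[paste0("enc", l, ".bn", j)]] <-
        list(run_mean = bn$run_mean, run_var = bn$run_var)
    }
    cin <- f
  }
  fb <- base_filters * 2^depth
  params[["bot.c1.W"]] <- he_init(3, cin, fb)
  params[["bot.c1.b"]] <- rep(0, fb)
  params[["bot.c2.W"]] <- he_init(3, fb, fb)
  params[["bot.c2.b"]] <- rep(0, fb)
  for (j in 1:2) {
    bn <- new_bn(fb)
    params[[paste0("bot.bn", j, ".gamma")]] <- bn$gamma
    params[[paste0("bot.bn", j, ".beta")]] <- bn$beta
    state[[paste0("bot.bn", j)]] <-
      list(run_mean = bn$run_mean, run_var = bn$run_var)
  }
  cup <- fb
  for (l in rev(seq_len(depth))) {
    f <- filt[l]
    params[[paste0("dec", l, ".up.W")]] <- he_init(2, cup, f)
    params[[paste0("dec", l, ".up.b")]] <- rep(0, f)
    params[[paste0("dec", l, ".c1.W")]] <- he_init(3, 2 * f, f)
    params[[paste0("dec", l, ".c1.b")]] <- rep(0, f)
    params[[paste0("dec", l, ".c2.W")]] <- he_init(3, f, f)
    params[[paste0("dec", l, ".c2.b")]] <- rep(0, f)
    for (j in 1:2) {
      bn <- new_bn(f)
      params[[paste0("dec", l, ".bn", j, ".gamma")]] <- bn$gamma
      params[[paste0("dec", l, ".bn", j, ".beta")]] <- bn$beta
      state[[paste0("dec", l, ".bn", j)]] <-
        list(run_mean = bn$run_mean, run_var = bn$run_var)
    }
    cup <- f
  }
  params[["out.W"]] <- he_init(1, base_filters, 1)
  params[["out.b"]] <- 0
  structure(list(params = params, state = state,
                 config = list(depth = depth, base_filters = base_filters,
                               dropout = dropout, in_channels = in_channels,
                               seed = seed),
                 trained = FALSE),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$params, length, 1L))
  cat("<unet> depth", cfg$depth, "| base filters", cfg$base_filters,
      "| bottleneck", cfg$base_filters * 2^cfg$depth,
      "| dropout", cfg$dropout,
      "|", format(npar, big.mark = ","), "parameters |",
      if (isTRUE(x$trained)) "trained" else "untrained", "\n")
  invisible(x)
}

# One conv -> BN -> ReLU unit. Returns output plus backprop cache.
cbr_fw <- function(x, params, state, pkey, bnkey, training) {
  z <- conv2d_fw(x, params[[paste0(pkey, ".W")]], params[[paste0(pkey, ".b")]])
  bn <- bn_fw(z, params[[paste0(bnkey, ".gamma")]],
              params[[paste0(bnkey, ".beta")]], state, bnkey, training)
  r <- relu_fw(bn$y)
  list(y = r$y, x = x, bn = bn, mask = r$mask)
}

# Full forward pass. x: (H, W, C, N). Returns probabilities and, when
# training, the caches needed for backprop.
unet_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  d <- dim(x)
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0)
    stop("input size (", d[1], "x", d[2],
         ") not divisible by 2^depth = ", 2^cfg$depth, call. = FALSE)
  p <- net$params; st <- net$state
  caches <- list(); skips <- list()
  for (l in seq_len(cfg$depth)) {
    c1 <- cbr_fw(x, p, st, paste0("enc", l, ".c1"), paste0("enc", l, ".bn1"),
                 training)
    h <- c1$y
    dmask <- NULL
    if (training && cfg$dropout > 0) {
      dmask <- (stats::runif(length(h)) >= cfg$dropout) / (1 - cfg$dropout)
      h <- h * dmask
    }
    c2 <- cbr_fw(h, p, st, paste0("enc", l, ".c2"), paste0("enc", l, ".bn2"),
                 training)
    skips[[l]] <- c2$y
    mp <- maxpool2_fw(c2$y)
    caches[[paste0("enc", l)]] <- list(c1 = c1, dmask = dmask, c2 = c2,
                                       mpidx = mp$idx, xdim = dim(c2$y))
    x <- mp$y
  }
  b1 <- cbr_fw(x, p, st, "bot.c1", "bot.bn1", training)
  h <- b1$y
  bdmask <- NULL
  if (training && cfg$dropout > 0) {
    bdmask <- (stats::runif(length(h)) >= cfg$dropout) / (1 - cfg$dropout)
    h <- h * bdmask
  }
  b2 <- cbr_fw(h, p, st, "bot.c2", "bot.bn2", training)
  caches[["bot"]] <- list(c1 = b1, dmask = bdmask, c2 = b2)
  x <- b2$y
  for (l in rev(seq_len(cfg$depth))) {
    u <- upconv2_fw(x, p[[paste0("dec", l, ".up.W")]],
                    p[[paste0("dec", l, ".up.b")]])
    sk <- skips[[l]]
    du <- dim(u)
    cat_x <- array(0, dim = c(du[1], du[2], du[3] + dim(sk)[3], du[4]))
    cat_x[, , seq_len(du[3]), ] <- u
    cat_x[, , du[3] + seq_len(dim(sk)[3]), ] <- sk
    c1 <- cbr_fw(cat_x, p, st, paste0("dec", l, ".c1"),
                 paste0("dec", l, ".bn1"), training)
    c2 <- cbr_fw(c1$y, p, st, paste0("dec", l, ".c2"),
                 paste0("dec", l, ".bn2"), training)
    caches[[paste0("dec", l)]] <- list(upx = x, u = u, nup = du[3],
                                       c1 = c1, c2 = c2)
    x <- c2$y
  }
  logits <- conv2d_fw(x, p[["out.W"]], p[["out.b"]])
  prob <- 1 / (1 + exp(-logits))
  caches[["out"]] <- list(x = x)
  res <- list(prob = prob)
  if (keep_cache) res$caches <- caches
  res
}

# Backward pass from dL/dlogits; returns flat gradient list matching params.
unet_backward <- function(net, dlogits, caches) {
  cfg <- net$config
  p <- net$params
  grads <- list()
  cvb <- conv2d_bw(caches[["out"]]$x, p[["out.W"]], dlogits)
  grads[["out.W"]] <- cvb$dw; grads[["out.b"]] <- cvb$db
  dx <- cvb$dx
  back_cbr <- function(dy, cache, pkey, bnkey) {
    dy <- dy * cache$mask
    bnb <- bn_bw(dy, cache$bn)
    grads[[paste0(bnkey, ".gamma")]] <<- bnb$dgamma
    grads[[paste0(bnkey, ".beta")]] <<- bnb$dbeta
    cvb <- conv2d_bw(cache$x, p[[paste0(pkey, ".W")]], bnb$dx)
    grads[[paste0(pkey, ".W")]] <<- cvb$dw
    grads[[paste0(pkey, ".b")]] <<- cvb$db
    cvb$dx
  }
  dskip <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    ca <- caches[[paste0("dec", l)]]
    dx2 <- back_cbr(dx, ca$c2, paste0("dec", l, ".c2"), paste0("dec", l, ".bn2"))
    dcat <- back_cbr(dx2, ca$c1, paste0("dec", l, ".c1"), paste0("dec", l, ".bn1"))
    nup <- ca$nup
    du <- dcat[, , seq_len(nup), , drop = FALSE]
    dskip[[l]] <- dcat[, , nup + seq_len(dim(dcat)[3] - nup), , drop = FALSE]
    ub <- upconv2_bw(ca$upx, p[[paste0("dec", l, ".up.W")]], du)
    grads[[paste0("dec", l, ".up.W")]] <- ub$dw
    grads[[paste0("dec", l, ".up.b")]] <- ub$db
    dx <- ub$dx
  }
  ca <- caches[["bot"]]
  dx <- back_cbr(dx, ca$c2, "bot.c2", "bot.bn2")
  if (!is.null(ca$dmask)) dx <- dx * ca$dmask
  dx <- back_cbr(dx, ca$c1, "bot.c1", "bot.bn1")
  for (l in rev(seq_len(cfg$depth))) {
    ca <- caches[[paste0("enc", l)]]
    dpool <- maxpool2_bw(ca$mpidx, dx, as.integer(ca$xdim))
    dpool <- dpool + dskip[[l]]
    dx <- back_cbr(dpool, ca$c2, paste0("enc", l, ".c2"),
                   paste0("enc", l, ".bn2"))
    if (!is.null(ca$dmask)) dx <- dx * ca$dmask
    dx <- back_cbr(dx, ca$c1, paste0("enc", l, ".c1"),
                   paste0("enc", l, ".bn1"))
  }
  grads
}

# One SGD-with-momentum step in place on a network; velocity kept in `vel`.
sgd_step <- function(net, grads, vel, lr, momentum) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- if (is.null(vel[[nm]])) 0 else vel[[nm]]
    v <- momentum * v - lr * g
    vel[[nm]] <- v
    net$params[[nm]] <- net$params[[nm]] + v
  }
  list(net = net, vel = vel)
}
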