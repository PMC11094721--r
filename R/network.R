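#' Stage-1 network configuration
#'
#' The structure-location labeling network: two stride-2 convolutions
#' (feature extraction), two residual multi-head self-attention blocks
#' (mutual interactions), two stride-2 transpose convolutions (decoding)
#' and a per-position sigmoid head shared across locations. The reference
#' configuration uses attention dimension 512, 16 heads, position-wise
#' feed-forward dimension 1024 and a 256-wide decoder head; the desk
#' configuration shrinks every channel count so the whole pipeline trains
#' in minutes on one CPU.
#'
#' @param n1,n2 channel counts of the two convolution layers (`n2` is the
#'   attention dimension).
#' @param heads number of attention heads (`n2` must be divisible).
#' @param ff_dim position-wise feed-forward dimension.
#' @param d1,d2 channel counts of the two transpose-convolution layers
#'   (`d2` is the width of the shared head).
#' @param dropout_residual dropout rate applied after each residual sum.
#' @param dropout_conv dropout rate applied after each convolution /
#'   transpose-convolution block.
#' @return object of class `network_config`.
#' @export
network_config <- function(n1 = 256L, n2 = 512L, heads = 16L,
                           ff_dim = 1024L, d1 = 512L, d2 = 256L,
                           dropout_residual = 0.1, dropout_conv = 0.4) {
  if (n2 %% heads != 0L) {
    fb_stop("attention dimension must be divisible by the head count",
            "fb_config_error")
  }
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 heads = as.integer(heads), ff_dim = as.integer(ff_dim),
                 d1 = as.integer(d1), d2 = as.integer(d2),
                 kernel_size = 3L, stride = 2L,
                 dropout_residual = dropout_residual,
                 dropout_conv = dropout_conv,
                 in_channels = 10L),
            class = "network_config")
}

#' Reduced desk-scale network configuration
#'
#' Same architecture, every channel count shrunk by roughly a factor of 16
#' (a few thousand parameters) so training experiments complete in minutes
#' on one CPU. The dropout rates are reduced along with the width: dropping
#' 40% of 32 channels destroys most of the signal a tiny network carries,
#' whereas the reference network has hundreds of redundant channels.
#' @export
desk_network_config <- function() {
  network_config(n1 = 16L, n2 = 32L, heads = 4L, ff_dim = 64L,
                 d1 = 32L, d2 = 16L,
                 dropout_residual = 0.05, dropout_conv = 0.1)
}

# ---- initialization ------------------------------------------------------

kaiming_uniform <- function(fan_in, dims) {
  limit <- sqrt(6 / fan_in)
  array(runif(prod(dims), -limit, limit), dim = dims)
}

xavier_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

init_attention_block <- function(cfg) {
  C <- cfg$n2; hd <- C %/% cfg$heads
  list(Wq = xavier_uniform(C, hd, c(C, hd, cfg$heads)),
       bq = array(0, c(hd, cfg$heads)),
       Wk = xavier_uniform(C, hd, c(C, hd, cfg$heads)),
       bk = array(0, c(hd, cfg$heads)),
       Wv = xavier_uniform(C, hd, c(C, hd, cfg$heads)),
       bv = array(0, c(hd, cfg$heads)),
       W1 = kaiming_uniform(C, c(C, cfg$ff_dim)),
       b1 = numeric(cfg$ff_dim),
       W2 = kaiming_uniform(cfg$ff_dim, c(cfg$ff_dim, C)),
       b2 = numeric(C))
}

#' Initialize Stage-1 parameters
#'
#' Kaiming-uniform for convolution and feed-forward kernels, Xavier for
#' attention projections, zeros for biases and the head bias; batch-norm
#' scale 1 / shift 0. Fully seeded.
#'
#' @param config a `network_config`.
#' @param seed integer seed.
#' @return list with `params` (flat named list of trainable arrays) and
#'   `state` (batch-norm running statistics).
#' @export
init_stage1_params <- function(config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cfg <- config
  params <- list(
    conv1.K = kaiming_uniform(3 * cfg$in_channels,
                              c(3, cfg$in_channels, cfg$n1)),
    bn1.gamma = rep(1, cfg$n1), bn1.beta = numeric(cfg$n1),
    conv2.K = kaiming_uniform(3 * cfg$n1, c(3, cfg$n1, cfg$n2)),
    bn2.gamma = rep(1, cfg$n2), bn2.beta = numeric(cfg$n2),
    tconv1.K = kaiming_uniform(3 * cfg$n2, c(3, cfg$n2, cfg$d1)),
    bn3.gamma = rep(1, cfg$d1), bn3.beta = numeric(cfg$d1),
    tconv2.K = kaiming_uniform(3 * cfg$d1, c(3, cfg$d1, cfg$d2)),
    bn4.gamma = rep(1, cfg$d2), bn4.beta = numeric(cfg$d2),
    head.W5 = xavier_uniform(cfg$d2, 1, c(cfg$d2, 1)),
    head.b5 = 0)
  for (b in 1:2) {
    blk <- init_attention_block(cfg)
    names(blk) <- paste0("attn", b, ".", names(blk))
    params <- c(params, blk)
  }
  state <- list()
  for (nm in c("bn1", "bn2", "bn3", "bn4")) {
    nc <- switch(nm, bn1 = cfg$n1, bn2 = cfg$n2, bn3 = cfg$d1,
                 bn4 = cfg$d2)
    state[[paste0(nm, ".mean")]] <- numeric(nc)
    state[[paste0(nm, ".var")]] <- rep(1, nc)
  }
  list(params = params, state = state)
}

# save/restore global RNG so seeded package internals do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- gather/scatter machinery for strided (transpose) convolutions -------

# stride-2 size-3 convolution: output position i reads input positions
# 2i-1, 2i, 2i+1 (0-based, out-of-range read as zero); length ceil(L/2)
conv_gather_idx <- function(B, L) {
  Lout <- ceiling(L / 2)
  centers <- 2L * (seq_len(Lout) - 1L)            # 0-based
  base <- rep((seq_len(B) - 1L) * L, each = Lout) # row offset per sequence
  idx <- lapply(c(-1L, 0L, 1L), function(off) {
    p <- centers + off
    ok <- p >= 0L & p <= L - 1L
    v <- rep(p + 1L, B) + base                    # 1-based stacked row
    v[!rep(ok, B)] <- 0L
    v
  })
  list(idx = idx, Lout = Lout)
}

# transpose convolution: interleave input rows with zero rows (extension E
# of length 2M), then stride-1 size-3 convolution with zero boundary;
# output position i reads E[i-1], E[i], E[i+1], E[2k] = F[k], E[odd] = 0
tconv_gather_idx <- function(B, M) {
  Lout <- 2L * M
  out_pos <- seq_len(Lout) - 1L                   # 0-based
  base <- rep((seq_len(B) - 1L) * M, each = Lout)
  idx <- lapply(c(-1L, 0L, 1L), function(off) {
    e <- out_pos + off                            # extension index
    ok <- e >= 0L & e <= 2L * M - 1L & e %% 2L == 0L
    f <- e %/% 2L
    v <- rep(f + 1L, B) + base
    v[!rep(ok, B)] <- 0L
    v
  })
  list(idx = idx, Lout = Lout)
}

gather_rows <- function(X, idx) {
  rbind(0, X)[idx + 1L, , drop = FALSE]
}

conv_fwd <- function(X, K, idx) {
  out <- 0
  for (t in 1:3) out <- out + gather_rows(X, idx[[t]]) %*% K[t, , ]
  out
}

conv_bwd <- function(dOut, X, K, idx) {
  dK <- array(0, dim(K))
  dX <- matrix(0, nrow(X), ncol(X))
  for (t in 1:3) {
    Xt <- gather_rows(X, idx[[t]])
    dK[t, , ] <- crossprod(Xt, dOut)
    contrib <- dOut %*% t(K[t, , ])
    ok <- idx[[t]] > 0L
    if (any(ok)) {
      acc <- rowsum(contrib[ok, , drop = FALSE], group = idx[[t]][ok])
      rows <- as.integer(rownames(acc))
      dX[rows, ] <- dX[rows, ] + acc
    }
  }
  list(dX = dX, dK = dK)
}

#' Stride-2 1D convolution
#'
#' Output position `i` (0-based) is the kernel dot-product over input
#' positions `2i-1`, `2i`, `2i+1`, out-of-range positions read as zero;
#' the output has `ceiling(l/2)` positions.
#'
#' @param x l x c input matrix.
#' @param kernels 3 x c x n kernel array.
#' @return ceiling(l/2) x n matrix.
#' @export
conv1d_stride2 <- function(x, kernels) {
  if (dim(kernels)[2] != ncol(x)) {
    fb_stop("kernel depth does not match input channels", "fb_shape_error")
  }
  conv_fwd(x, kernels, conv_gather_idx(1L, nrow(x))$idx)
}

#' Stride-2 1D transpose convolution
#'
#' Interleaves the input rows with zero rows (extension of length `2l`),
#' then applies a stride-1 size-3 convolution with zero boundary; the
#' output has exactly `2l` positions.
#'
#' @param x l x c input matrix.
#' @param kernels 3 x c x n kernel array.
#' @return 2l x n matrix.
#' @export
transpose_conv1d_stride2 <- function(x, kernels) {
  if (dim(kernels)[2] != ncol(x)) {
    fb_stop("kernel depth does not match input channels", "fb_shape_error")
  }
  conv_fwd(x, kernels, tconv_gather_idx(1L, nrow(x))$idx)
}

#' Residual self-attention block (deterministic forward)
#'
#' `X' = X + multihead_self_attention(X)` followed by
#' `A = X' + FF(X')` with the two-layer position-wise feed-forward map;
#' dropout is off in this standalone forward.
#'
#' @param x positions x attention-dim matrix.
#' @param block named list of block parameters (`Wq, bq, Wk, bk, Wv, bv,
#'   W1, b1, W2, b2`), e.g. one entry of [init_stage1_params()].
#' @param config the `network_config`.
#' @return matrix with the same shape as `x`.
#' @export
residual_attention_block <- function(x, block, config) {
  cfg <- config
  cfg$dropout_residual <- 0
  res_block_fwd(x, block, cfg, training = FALSE)$y
}

# ---- batch norm / relu / dropout -----------------------------------------

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2          # biased variance
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, invstd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, cache = list(xhat = xhat, invstd = invstd,
                           training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dY, cache, gamma) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, `*`)
  if (!cache$training) {
    dX <- sweep(dxhat, 2L, cache$invstd, `*`)
  } else {
    N <- nrow(dY)
    t1 <- sweep(dxhat, 2L, colSums(dxhat) / N)
    t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / N, `*`)
    dX <- sweep(t1 - t2, 2L, cache$invstd, `*`)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  list(y = pmax(X, 0), mask = X > 0)
}

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(y = X, mask = NULL))
  keep <- matrix(rbinom(length(X), 1L, 1 - p), nrow(X)) / (1 - p)
  list(y = X * keep, mask = keep)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- attention -----------------------------------------------------------

#' Multi-head scaled dot-product attention
#'
#' Per head: project Q, K and V, softmax the scaled Gram matrix, attend,
#' then concatenate the heads. Self-attention is the call with
#' `Q = K = V`. No positional encoding is added anywhere in the network,
#' so the operation is permutation-equivariant.
#'
#' @param Q,K,V position x channel matrices (equal position counts for K
#'   and V).
#' @param proj list with projection arrays `Wq, bq, Wk, bk, Wv, bv`
#'   (channel x head-dim x heads and head-dim x heads).
#' @param heads number of heads.
#' @return attended matrix with the same shape as `Q`.
#' @export
multihead_attention <- function(Q, K, V, proj, heads) {
  attn_fwd(Q, K, V, proj, heads)$y
}

attn_fwd <- function(Q, K, V, proj, heads) {
  hd <- dim(proj$Wq)[2]
  scale <- 1 / sqrt(hd)
  M <- nrow(Q)
  H <- matrix(0, M, hd * heads)
  cache <- vector("list", heads)
  for (h in seq_len(heads)) {
    Qh <- Q %*% proj$Wq[, , h] + matrix(proj$bq[, h], M, hd, byrow = TRUE)
    Kh <- K %*% proj$Wk[, , h] + matrix(proj$bk[, h], nrow(K), hd,
                                        byrow = TRUE)
    Vh <- V %*% proj$Wv[, , h] + matrix(proj$bv[, h], nrow(V), hd,
                                        byrow = TRUE)
    S <- (Qh %*% t(Kh)) * scale
    S <- sweep(S, 1L, apply(S, 1L, max))   # stabilized softmax
    A <- exp(S)
    A <- A / rowSums(A)
    H[, (h - 1L) * hd + seq_len(hd)] <- A %*% Vh
    cache[[h]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, A = A)
  }
  list(y = H, cache = cache, scale = scale, hd = hd)
}

attn_bwd <- function(dH, fw, Q, K, V, proj, heads) {
  hd <- fw$hd
  scale <- fw$scale
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- matrix(0, nrow(K), ncol(K))
  dV <- matrix(0, nrow(V), ncol(V))
  g <- list(Wq = array(0, dim(proj$Wq)), bq = array(0, dim(proj$bq)),
            Wk = array(0, dim(proj$Wk)), bk = array(0, dim(proj$bk)),
            Wv = array(0, dim(proj$Wv)), bv = array(0, dim(proj$bv)))
  for (h in seq_len(heads)) {
    cc <- fw$cache[[h]]
    dHh <- dH[, (h - 1L) * hd + seq_len(hd), drop = FALSE]
    dA <- dHh %*% t(cc$Vh)
    dVh <- crossprod(cc$A, dHh)
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dQh <- (dS %*% cc$Kh) * scale
    dKh <- crossprod(dS, cc$Qh) * scale
    g$Wq[, , h] <- crossprod(Q, dQh); g$bq[, h] <- colSums(dQh)
    g$Wk[, , h] <- crossprod(K, dKh); g$bk[, h] <- colSums(dKh)
    g$Wv[, , h] <- crossprod(V, dVh); g$bv[, h] <- colSums(dVh)
    dQ <- dQ + dQh %*% t(proj$Wq[, , h])
    dK <- dK + dKh %*% t(proj$Wk[, , h])
    dV <- dV + dVh %*% t(proj$Wv[, , h])
  }
  list(dQ = dQ, dK = dK, dV = dV, grads = g)
}

# residual self-attention block:
#   X1 = dropout(X + multihead_self_attention(X))
#   A  = dropout(X1 + FF(X1)),  FF = relu(X1 W1 + b1) W2 + b2
res_block_fwd <- function(X, blk, cfg, training) {
  at <- attn_fwd(X, X, X, blk, cfg$heads)
  d1 <- dropout_fwd(X + at$y, cfg$dropout_residual, training)
  X1 <- d1$y
  Z <- sweep(X1 %*% blk$W1, 2L, blk$b1, `+`)
  R <- relu_fwd(Z)
  Fo <- sweep(R$y %*% blk$W2, 2L, blk$b2, `+`)
  d2 <- dropout_fwd(X1 + Fo, cfg$dropout_residual, training)
  list(y = d2$y,
       cache = list(X = X, at = at, d1 = d1, X1 = X1, R = R, d2 = d2))
}

res_block_bwd <- function(dA, cache, blk, cfg) {
  dSum2 <- dropout_bwd(dA, cache$d2$mask)
  dX1 <- dSum2
  dFo <- dSum2
  dRy <- dFo %*% t(blk$W2)
  gW2 <- crossprod(cache$R$y, dFo)
  gb2 <- colSums(dFo)
  dZ <- dRy * cache$R$mask
  gW1 <- crossprod(cache$X1, dZ)
  gb1 <- colSums(dZ)
  dX1 <- dX1 + dZ %*% t(blk$W1)
  dSum1 <- dropout_bwd(dX1, cache$d1$mask)
  ab <- attn_bwd(dSum1, cache$at, cache$X, cache$X, cache$X, blk,
                 cfg$heads)
  dX <- dSum1 + ab$dQ + ab$dK + ab$dV
  grads <- c(ab$grads, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
  list(dX = dX, grads = grads)
}

attn_block_params <- function(params, b) {
  pre <- paste0("attn", b, ".")
  nm <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "W1", "b1", "W2", "b2")
  setNames(lapply(nm, function(x) params[[paste0(pre, x)]]), nm)
}

# ---- full network --------------------------------------------------------

# Xlist: list of L x 10 matrices, all the same L (padded in training).
# Returns per-sequence probability vectors of length L (cropped from the
# decoded 4*ceil(ceil(L/2)/2) positions) plus caches for backprop.
net_forward <- function(Xlist, params, config, state, training = FALSE) {
  B <- length(Xlist)
  L <- nrow(Xlist[[1]])
  if (L < 4L) fb_stop("input too short: need l >= 4", "fb_length_error")
  cfg <- config
  X0 <- do.call(rbind, Xlist)
  cache <- list(B = B, L = L)

  run_bn <- function(X, nm) {
    r <- bn_fwd(X, params[[paste0(nm, ".gamma")]],
                params[[paste0(nm, ".beta")]],
                state[[paste0(nm, ".mean")]], state[[paste0(nm, ".var")]],
                training)
    state[[paste0(nm, ".mean")]] <<- r$run_mean
    state[[paste0(nm, ".var")]] <<- r$run_var
    r
  }

  # conv block 1
  g1 <- conv_gather_idx(B, L)
  C1 <- conv_fwd(X0, params$conv1.K, g1$idx)
  R1 <- relu_fwd(C1)
  B1 <- run_bn(R1$y, "bn1")
  D1 <- dropout_fwd(B1$y, cfg$dropout_conv, training)
  # conv block 2
  g2 <- conv_gather_idx(B, g1$Lout)
  C2 <- conv_fwd(D1$y, params$conv2.K, g2$idx)
  R2 <- relu_fwd(C2)
  B2 <- run_bn(R2$y, "bn2")
  D2 <- dropout_fwd(B2$y, cfg$dropout_conv, training)
  M <- g2$Lout

  # residual self-attention blocks, per sequence
  X <- D2$y
  attn_caches <- vector("list", 2L)
  for (b in 1:2) {
    blk <- attn_block_params(params, b)
    percfg <- vector("list", B)
    Y <- matrix(0, nrow(X), ncol(X))
    for (s in seq_len(B)) {
      rows <- (s - 1L) * M + seq_len(M)
      r <- res_block_fwd(X[rows, , drop = FALSE], blk, cfg, training)
      Y[rows, ] <- r$y
      percfg[[s]] <- r$cache
    }
    attn_caches[[b]] <- percfg
    X <- Y
  }

  # decoder
  t1 <- tconv_gather_idx(B, M)
  T1 <- conv_fwd(X, params$tconv1.K, t1$idx)
  R3 <- relu_fwd(T1)
  B3 <- run_bn(R3$y, "bn3")
  D3 <- dropout_fwd(B3$y, cfg$dropout_conv, training)
  t2 <- tconv_gather_idx(B, t1$Lout)
  T2 <- conv_fwd(D3$y, params$tconv2.K, t2$idx)
  R4 <- relu_fwd(T2)
  B4 <- run_bn(R4$y, "bn4")
  D4 <- dropout_fwd(B4$y, cfg$dropout_conv, training)

  # shared sigmoid head, then crop each decoded signal to L positions
  Z <- drop(D4$y %*% params$head.W5) + params$head.b5
  Yp <- 1 / (1 + exp(-Z))
  Ldec <- t2$Lout
  ylist <- lapply(seq_len(B), function(s)
    Yp[(s - 1L) * Ldec + seq_len(L)])

  cache <- c(cache, list(
    X0 = X0, g1 = g1, C1 = C1, R1 = R1, B1 = B1, D1 = D1,
    g2 = g2, C2 = C2, R2 = R2, B2 = B2, D2 = D2, M = M,
    attn = attn_caches, Xattn = X,
    t1 = t1, T1 = T1, R3 = R3, B3 = B3, D3 = D3,
    t2 = t2, T2 = T2, R4 = R4, B4 = B4, D4 = D4,
    Z = Z, Yp = Yp, Ldec = Ldec))
  list(y = ylist, cache = cache, state = state)
}

# dYlist: per-sequence gradients w.r.t. the cropped probability outputs
net_backward <- function(dYlist, cache, params, config) {
  cfg <- config
  B <- cache$B; L <- cache$L; M <- cache$M; Ldec <- cache$Ldec
  grads <- list()

  dYfull <- numeric(B * Ldec)
  for (s in seq_len(B)) {
    dYfull[(s - 1L) * Ldec + seq_len(L)] <- dYlist[[s]]
  }
  dZ <- dYfull * cache$Yp * (1 - cache$Yp)
  grads$head.W5 <- crossprod(cache$D4$y, matrix(dZ, ncol = 1L))
  grads$head.b5 <- sum(dZ)
  dD4 <- matrix(dZ, ncol = 1L) %*% t(params$head.W5)

  bwd_bn_relu_drop <- function(dOut, Dc, Bc, Rc, nm) {
    d <- dropout_bwd(dOut, Dc$mask)
    bb <- bn_bwd(d, Bc$cache, params[[paste0(nm, ".gamma")]])
    grads[[paste0(nm, ".gamma")]] <<- bb$dgamma
    grads[[paste0(nm, ".beta")]] <<- bb$dbeta
    bb$dX * Rc$mask
  }

  dT2 <- bwd_bn_relu_drop(dD4, cache$D4, cache$B4, cache$R4, "bn4")
  cb2 <- conv_bwd(dT2, cache$D3$y, params$tconv2.K, cache$t2$idx)
  grads$tconv2.K <- cb2$dK
  dT1 <- bwd_bn_relu_drop(cb2$dX, cache$D3, cache$B3, cache$R3, "bn3")
  cb1 <- conv_bwd(dT1, cache$Xattn, params$tconv1.K, cache$t1$idx)
  grads$tconv1.K <- cb1$dK
  dX <- cb1$dX

  for (b in 2:1) {
    blk <- attn_block_params(params, b)
    acc <- lapply(blk, function(a) a * 0)   # zero gradients, same shapes
    dXn <- matrix(0, nrow(dX), ncol(dX))
    for (s in seq_len(B)) {
      rows <- (s - 1L) * M + seq_len(M)
      r <- res_block_bwd(dX[rows, , drop = FALSE], cache$attn[[b]][[s]],
                         blk, cfg)
      dXn[rows, ] <- r$dX
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + r$grads[[nm]]
    }
    for (nm in names(acc)) grads[[paste0("attn", b, ".", nm)]] <- acc[[nm]]
    dX <- dXn
  }

  dC2o <- bwd_bn_relu_drop(dX, cache$D2, cache$B2, cache$R2, "bn2")
  cv2 <- conv_bwd(dC2o, cache$D1$y, params$conv2.K, cache$g2$idx)
  grads$conv2.K <- cv2$dK
  dC1o <- bwd_bn_relu_drop(cv2$dX, cache$D1, cache$B1, cache$R1, "bn1")
  cv1 <- conv_bwd(dC1o, cache$X0, params$conv1.K, cache$g1$idx)
  grads$conv1.K <- cv1$dK
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the Stage-1 network on input tensors
#'
#' In `eval` mode the network is deterministic: dropout is off and batch
#' norm uses its running statistics; each sequence is processed at its
#' native length and the decoded signal is cropped to `true_length`. In
#' `train` mode the tensors must already be padded to a common length.
#'
#' @param tensors one `input_tensor` or a list of them.
#' @param params flat parameter list from [init_stage1_params()] or a
#'   checkpoint.
#' @param config the matching `network_config`.
#' @param state batch-norm running statistics.
#' @param mode "eval" or "train".
#' @return list of numeric vectors of pairing probabilities (one per
#'   tensor, length `true_length`), or a single vector when a single
#'   tensor was supplied.
#' @export
stage1_forward <- function(tensors, params, config, state,
                           mode = c("eval", "train")) {
  mode <- match.arg(mode)
  single <- inherits(tensors, "input_tensor")
  if (single) tensors <- list(tensors)
  if (mode == "eval") {
    out <- lapply(tensors, function(tt) {
      r <- net_forward(list(tt$values[seq_len(tt$true_length), ,
                                      drop = FALSE]),
                       params, config, state, training = FALSE)
      r$y[[1L]][seq_len(tt$true_length)]
    })
  } else {
    lens <- vapply(tensors, function(t) nrow(t$values), 1L)
    if (length(unique(lens)) != 1L) {
      fb_stop("train mode needs a padded batch of equal lengths",
              "fb_length_error")
    }
    r <- net_forward(lapply(tensors, `[[`, "values"), params, config,
                     state, training = TRUE)
    out <- r$y
  }
  if (single) out[[1L]] else out
}

# ---- checkpoints ---------------------------------------------------------

#' Save a Stage-1 checkpoint
#'
#' A single archive holding the network configuration, the frozen ensemble
#' member order, all trainable parameters and the batch-norm running
#' statistics, with a versioned header.
#'
#' @param params,state trained parameters and batch-norm state.
#' @param config the `network_config`.
#' @param member_order character vector of panel member names.
#' @param path output path.
#' @export
save_checkpoint <- function(params, state, config, member_order, path) {
  saveRDS(list(format = "foldboost-checkpoint", version = 1L,
               config = config, member_order = member_order,
               params = params, state = state), path)
  invisible(path)
}

#' Load a Stage-1 checkpoint
#' @param path checkpoint path.
#' @return list with `params`, `state`, `config`, `member_order`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "foldboost-checkpoint")) {
    fb_stop("not a foldboost checkpoint", "fb_format_error")
  }
  ck
}
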