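test_that("stride-2 convolution follows the stated index rule", {
  K <- array(1, c(3, 1, 1))
  out <- conv1d_stride2(matrix(c(1, 2, 3, 4), ncol = 1), K)
  expect_equal(as.numeric(out), c(3, 9))     # (0+1+2, 2+3+4)
  expect_equal(nrow(conv1d_stride2(matrix(0, 5, 1), K)), 3L)  # ceil(5/2)
  expect_equal(conv1d_stride2(matrix(1:8, 4, 2), array(0, c(3, 2, 3))),
               matrix(0, 2, 3))
  expect_error(conv1d_stride2(matrix(0, 4, 2), array(0, c(3, 1, 1))),
               class = "fb_shape_error")
})

test_that("transpose convolution builds and convolves the extension", {
  K <- array(1, c(3, 1, 1))
  out <- transpose_conv1d_stride2(matrix(c(1, 2), ncol = 1), K)
  expect_equal(as.numeric(out), c(1, 3, 2, 2))
  expect_equal(nrow(transpose_conv1d_stride2(matrix(0, 5, 2),
                                             array(0, c(3, 2, 1)))), 10L)
})

test_that("layer forwards agree with naive loop oracles", {
  set.seed(31)
  for (k in 1:20) {
    L <- sample(2:9, 1); cin <- sample(1:4, 1); n <- sample(1:4, 1)
    X <- matrix(rnorm(L * cin), L, cin)
    K <- array(rnorm(3 * cin * n), c(3, cin, n))
    expect_equal(conv1d_stride2(X, K), oracle_conv(X, K),
                 tolerance = 1e-6)
    expect_equal(transpose_conv1d_stride2(X, K), oracle_tconv(X, K),
                 tolerance = 1e-6)
  }
})

test_that("multi-head attention matches a hand-rolled oracle", {
  set.seed(32)
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 6, d1 = 8,
                        d2 = 4)
  prm <- init_stage1_params(cfg, seed = 5)$params
  proj <- list(Wq = prm$attn1.Wq, bq = prm$attn1.bq,
               Wk = prm$attn1.Wk, bk = prm$attn1.bk,
               Wv = prm$attn1.Wv, bv = prm$attn1.bv)
  for (k in 1:10) {
    M <- sample(1:6, 1)
    X <- matrix(rnorm(M * 8), M, 8)
    expect_equal(multihead_attention(X, X, X, proj, 2),
                 oracle_attention(X, X, X, proj, 2), tolerance = 1e-6)
  }
  # single position: softmax over one key is 1, output = projected V
  x1 <- matrix(rnorm(8), 1, 8)
  got <- multihead_attention(x1, x1, x1, proj, 2)
  exp1 <- cbind(x1 %*% proj$Wv[, , 1] + proj$bv[, 1],
                x1 %*% proj$Wv[, , 2] + proj$bv[, 2])
  expect_equal(got, exp1, tolerance = 1e-10)
})

test_that("the attention stack is permutation-equivariant", {
  set.seed(33)
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 6, d1 = 8,
                        d2 = 4)
  prm <- init_stage1_params(cfg, seed = 6)$params
  blk <- foldboost:::attn_block_params(prm, 1)
  X <- matrix(rnorm(7 * 8), 7, 8)
  A <- residual_attention_block(X, blk, cfg)
  perm <- sample(7)
  expect_equal(residual_attention_block(X[perm, ], blk, cfg), A[perm, ],
               tolerance = 1e-10)
})

test_that("zeroed sublayers reduce the residual block to identity", {
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 6, d1 = 8,
                        d2 = 4)
  prm <- init_stage1_params(cfg, seed = 7)$params
  blk <- foldboost:::attn_block_params(prm, 1)
  for (nm in names(blk)) blk[[nm]] <- blk[[nm]] * 0
  X <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(residual_attention_block(X, blk, cfg), X)
})

test_that("a zero head weight emits probability one half everywhere", {
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 6, d1 = 8,
                        d2 = 4)
  ini <- init_stage1_params(cfg, seed = 8)
  ini$params$head.W5 <- ini$params$head.W5 * 0
  ini$params$head.b5 <- 0
  tt <- build_input(rna_sequence("GGGAAACCC"),
                    lapply(1:6, function(k) integer(9)))
  y <- stage1_forward(tt, ini$params, cfg, ini$state, mode = "eval")
  expect_equal(y, rep(0.5, 9))
})

test_that("the network emits exactly l probabilities for any l >= 4", {
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 6, d1 = 8,
                        d2 = 4)
  ini <- init_stage1_params(cfg, seed = 9)
  for (l in c(4L, 5L, 7L, 16L, 37L, 63L)) {
    seq <- random_rna(l)
    tt <- build_input(seq, lapply(1:6, function(k) integer(l)))
    y <- stage1_forward(tt, ini$params, cfg, ini$state, mode = "eval")
    expect_length(y, l)
    expect_true(all(y > 0 & y < 1))
  }
  tt3 <- build_input(rna_sequence("ACG"), lapply(1:6, function(k)
    integer(3)))
  expect_error(stage1_forward(tt3, ini$params, cfg, ini$state,
                              mode = "eval"), class = "fb_length_error")
})

test_that("eval mode is deterministic", {
  cfg <- desk_network_config()
  ini <- init_stage1_params(cfg, seed = 10)
  tt <- build_input(random_rna(20), lapply(1:6, function(k)
    rep(c(0L, 1L), 10)))
  y1 <- stage1_forward(tt, ini$params, cfg, ini$state, mode = "eval")
  y2 <- stage1_forward(tt, ini$params, cfg, ini$state, mode = "eval")
  expect_identical(y1, y2)
})

test_that("analytic gradients match finite differences", {
  cfg <- network_config(n1 = 3, n2 = 4, heads = 2, ff_dim = 5, d1 = 4,
                        d2 = 3, dropout_residual = 0, dropout_conv = 0)
  ini <- init_stage1_params(cfg, seed = 3)
  set.seed(11)
  L <- 8; B <- 2
  Xs <- lapply(1:B, function(b) matrix(runif(L * 10), L, 10))
  tg <- lapply(1:B, function(b) rbinom(L, 1, 0.5))
  mk <- lapply(1:B, function(b) c(rep(1, 6), 0, 0))
  lossfn <- function(params) {
    fw <- foldboost:::net_forward(Xs, params, cfg, ini$state,
                                  training = TRUE)
    sum(vapply(1:B, function(k)
      masked_bce_loss(fw$y[[k]], tg[[k]], mk[[k]]), 1.0))
  }
  fw <- foldboost:::net_forward(Xs, ini$params, cfg, ini$state,
                                training = TRUE)
  dY <- lapply(1:B, function(k)
    foldboost:::masked_bce_grad(fw$y[[k]], tg[[k]], mk[[k]], 1.8))
  gr <- foldboost:::net_backward(dY, fw$cache, ini$params, cfg)
  eps <- 1e-5
  for (nm in names(ini$params)) {
    p <- ini$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- ini$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- ini$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad of %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip losslessly", {
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 6, d1 = 8,
                        d2 = 4)
  ini <- init_stage1_params(cfg, seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ini$params, ini$state, cfg,
                  vapply(default_panel(), `[[`, "", "name"), path)
  ck <- load_checkpoint(path)
  expect_identical(ck$params, ini$params)
  expect_identical(ck$state, ini$state)
  expect_equal(ck$member_order[1], "nussinov")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), class = "fb_format_error")
})

test_that("network config enforces the head divisibility constraint", {
  expect_error(network_config(n2 = 10, heads = 4), class = "fb_config_error")
  cfg <- network_config()
  expect_equal(cfg$n2, 512L)
  expect_equal(cfg$heads, 16L)
  expect_equal(cfg$ff_dim, 1024L)
  expect_equal(cfg$d2, 256L)
})
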