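test_that("masked BCE matches hand evaluation and ignores padding", {
  # y = 0.5 against targets (1, 0): 1.8*ln2 + ln2
  expect_equal(masked_bce_loss(c(0.5, 0.5), c(1, 0), c(1, 1), 1.8),
               2.8 * log(2), tolerance = 1e-12)
  # perfect (clamped) predictions give ~0 loss, never an error
  expect_lt(masked_bce_loss(c(1, 0), c(1, 0)), 1e-5)
  # appending padded positions with arbitrary y leaves the loss unchanged
  l1 <- masked_bce_loss(c(0.3, 0.8), c(0, 1), c(1, 1))
  l2 <- masked_bce_loss(c(0.3, 0.8, 0.99, 0.01), c(0, 1, 0, 1),
                        c(1, 1, 0, 0))
  expect_identical(l1, l2)
})

test_that("padded positions carry exactly zero loss gradient", {
  g <- foldboost:::masked_bce_grad(c(0.3, 0.8, 0.6), c(0, 1, 1),
                                   c(1, 1, 0), 1.8)
  expect_identical(g[3], 0)
  # through the network: finite-difference of the loss w.r.t. a padded
  # output is zero by the masking contract
  f <- function(y) masked_bce_loss(y, c(1, 0, 0), c(1, 1, 0))
  y <- c(0.4, 0.6, 0.5)
  for (d in c(-0.2, 0.2)) {
    y2 <- y; y2[3] <- y2[3] + d
    expect_identical(f(y), f(y2))
  }
})

test_that("the learning-rate schedule hits its anchors and decays", {
  tc <- training_config("paper")
  expect_equal(lr_at(0, tc), tc$base_lr)
  expect_equal(lr_at(226, tc), 1e-13)
  lrs <- vapply(0:249, lr_at, 1.0, config = tc)
  expect_true(all(diff(lrs) <= 1e-20))
  expect_equal(lrs[228], 1e-13 * 1e-10)
  expect_error(lr_at(250, tc), class = "fb_range_error")
  expect_error(lr_at(-1, tc), class = "fb_range_error")
})

test_that("training config enforces the epoch split", {
  expect_error(training_config("desk", epochs = 31L),
               class = "fb_config_error")
  tc <- training_config("paper")
  expect_equal(tc$epochs, 250L)
  expect_equal(tc$cosine_epochs, 227L)
  expect_equal(tc$exp_epochs, 23L)
  expect_equal(tc$batch_size, 512L)
  expect_equal(tc$pad_target, 512L)
  expect_equal(tc$pos_weight, 1.8)
})

test_that("fold assignment is family-atomic and seeded", {
  nm <- sprintf("fam%02d", 1:25)
  a <- assign_folds(nm, k = 25, seed = 4)
  expect_equal(sort(unique(a)), 0:24)
  expect_equal(as.vector(table(a)), rep(1L, 25))
  expect_identical(a, assign_folds(nm, k = 25, seed = 4))
  expect_false(identical(a, assign_folds(nm, k = 25, seed = 5)))
  b <- assign_folds(sprintf("f%02d", 1:10), k = 3, seed = 1)
  expect_true(all(b %in% 0:2))
})

test_that("a short training run returns curves and learns capacity", {
  fams <- lapply(1:2, function(k) toy_family(paste0("t", k), 24L, 900 + k))
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 8, d1 = 8,
                        d2 = 4, dropout_residual = 0, dropout_conv = 0)
  tc <- training_config("desk", epochs = 1L, cosine_epochs = 1L,
                        exp_epochs = 0L, batch_size = 4L, pad_target = 32L,
                        seed = 2)
  res <- train_fold(fams[1], fams[2], cfg, tc)
  expect_equal(nrow(res$curves), 1L)
  expect_true(all(c("train_loss", "val_loss", "train_pf1", "val_pf1")
                  %in% names(res$curves)))
  expect_equal(res$member_order[1], "nussinov")
  expect_error(train_fold(list(), fams, cfg, tc),
               class = "fb_config_error")
})

test_that("zero learning rate leaves parameters untouched", {
  fams <- list(toy_family("z", 24L, 911))
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 8, d1 = 8,
                        d2 = 4)
  tc <- training_config("desk", epochs = 1L, cosine_epochs = 1L,
                        exp_epochs = 0L, batch_size = 4L, pad_target = 32L,
                        base_lr = 0, min_lr = 0, seed = 2)
  res <- train_fold(fams, list(), cfg, tc)
  ini <- init_stage1_params(cfg, seed = tc$seed)
  expect_equal(res$params, ini$params)
})

test_that("training is reproducible from the seed", {
  fams <- lapply(1:2, function(k) toy_family(paste0("r", k), 24L, 920 + k))
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 8, d1 = 8,
                        d2 = 4)
  tc <- training_config("desk", epochs = 2L, cosine_epochs = 2L,
                        exp_epochs = 0L, batch_size = 4L, pad_target = 32L,
                        seed = 3)
  r1 <- train_fold(fams[1], fams[2], cfg, tc)
  r2 <- train_fold(fams[1], fams[2], cfg, tc)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$curves, r2$curves)
})

test_that("the network can overfit a single repeated example", {
  fam <- toy_family("cap", 24L, 931)
  fam$members <- rep(fam$members[1], 8L)   # one example, repeated
  cfg <- network_config(n1 = 8, n2 = 16, heads = 2, ff_dim = 16, d1 = 16,
                        d2 = 8, dropout_residual = 0, dropout_conv = 0)
  tc <- training_config("desk", epochs = 30L, cosine_epochs = 28L,
                        exp_epochs = 2L, batch_size = 1L, pad_target = 24L,
                        base_lr = 0.02, seed = 4)
  res <- train_fold(list(fam), list(), cfg, tc)
  expect_lt(tail(res$curves$train_loss, 1),
            0.25 * res$curves$train_loss[1])
  expect_gt(tail(res$curves$train_pf1, 1), 0.9)
})

test_that("cross-validated training trains one model per fold", {
  fams <- lapply(1:4, function(k) toy_family(paste0("cv", k), 24L, 940 + k))
  cfg <- network_config(n1 = 4, n2 = 8, heads = 2, ff_dim = 8, d1 = 8,
                        d2 = 4)
  tc <- training_config("desk", epochs = 1L, cosine_epochs = 1L,
                        exp_epochs = 0L, batch_size = 4L, pad_target = 32L,
                        folds = 2L, seed = 5)
  out <- train_cv(fams, cfg, tc, folds = 2L)
  expect_length(out, 2L)
})
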