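# U-Net: shape contracts, gradient correctness, backend agreement,
# checkpoint rule, determinism, and learning sanity on phantom tasks.

test_that("output shape follows the input and divisibility is enforced", {
  m3 <- build_unet(unet_config(depth = 3, base_filters = 2), seed = 1)
  p <- predict_map(m3, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(p), c(64L, 64L))
  expect_true(all(p >= 0 & p <= 1))
  m4 <- build_unet(unet_config(depth = 4, base_filters = 2), seed = 1)
  p4 <- predict_map(m4, matrix(runif(128 * 128), 128, 128))
  expect_equal(dim(p4), c(128L, 128L))
  expect_error(predict_map(m4, matrix(0, 100, 100)), "divisible")
  expect_error(predict_map(m4, matrix(0, 100, 100), backend = "r"), "divisible")
})

test_that("class scores are normalized probabilities", {
  m <- build_unet(unet_config(depth = 2, base_filters = 2), seed = 3)
  img <- matrix(runif(32 * 32), 32, 32)
  X <- orbitseg:::stack_images(list(img))
  fwd <- orbitseg:::unet_forward(m, X, 32L, 32L, 1L, training = FALSE)
  P <- orbitseg:::softmax_rows(fwd$logits)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_equal(as.vector(t(predict_map(m, img, backend = "r"))), P[, 2],
               tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- unet_config(depth = 2, base_filters = 2, dropout_rate = 0)
  m <- build_unet(cfg, seed = 7)
  H <- 8L; W <- 8L; N <- 2L
  set.seed(42)
  X <- matrix(rnorm(H * W * N), ncol = 1)
  y <- sample(1:2, H * W * N, replace = TRUE)
  fwd <- orbitseg:::unet_forward(m, X, H, W, N, training = TRUE)
  ce <- orbitseg:::softmax_ce(fwd$logits, y)
  g <- orbitseg:::unet_backward(m, fwd, ce$dlogits)
  loss_at <- function(model) {
    f <- orbitseg:::unet_forward(model, X, H, W, N, training = TRUE)
    orbitseg:::softmax_ce(f$logits, y)$loss
  }
  eps <- 1e-5
  set.seed(8)
  for (nm in c("enc1a.W", "enc2b.gamma", "bota.W", "up1.W", "dec2a.beta",
               "out.W", "out.b")) {
    i <- sample(length(m$params[[nm]]), 1)
    up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(as.numeric(g[[nm]][i]), num, tolerance = 1e-5)
  }
})

test_that("the compiled backend reproduces the reference implementation", {
  cfg <- unet_config(depth = 3, base_filters = 4, dropout_rate = 0)
  m <- build_unet(cfg, seed = 5)
  set.seed(2)
  H <- 32L; W <- 32L; N <- 3L
  imgs <- lapply(1:N, function(i) matrix(rnorm(H * W), H, W))
  msks <- lapply(1:N, function(i) matrix(rbinom(H * W, 1, 0.3), H, W))
  X <- orbitseg:::stack_images(imgs)
  y <- orbitseg:::stack_labels(msks)
  fwd <- orbitseg:::unet_forward(m, X, H, W, N, training = TRUE)
  ce <- orbitseg:::softmax_ce(fwd$logits, y)
  gR <- orbitseg:::unet_backward(m, fwd, ce$dlogits)
  res <- orbitseg:::cpp_unet_train_batch(
    m$params, m$stats, as.numeric(X), y, H, W, N, cfg$depth, cfg$base_filters,
    0, numeric(0), orbitseg:::bn_stat_momentum, orbitseg:::bn_eps)
  expect_equal(res$loss, ce$loss, tolerance = 1e-5)
  for (nm in names(gR)) {
    a <- as.numeric(gR[[nm]]); b <- as.numeric(res$grads[[nm]])
    expect_equal(b, a, tolerance = 1e-2)   # single vs double precision
  }
  for (nm in names(fwd$stats)) {
    expect_equal(as.numeric(res$stats[[nm]]), as.numeric(fwd$stats[[nm]]),
                 tolerance = 1e-4)
  }
  p1 <- predict_map(m, imgs[[1]], backend = "r")
  p2 <- predict_map(m, imgs[[1]], backend = "cpp")
  expect_lt(max(abs(p1 - p2)), 1e-4)
})

test_that("the checkpoint keeps the epoch with maximal validation accuracy", {
  log <- c(0.5, 0.8, 0.75, 0.8, 0.6)
  expect_equal(orbitseg:::select_checkpoint(log), 4)  # later epoch wins ties
  expect_equal(orbitseg:::select_checkpoint(c(0.2, 0.9, 0.3)), 2)
  # end to end: a 2-epoch run checkpoints the argmax epoch
  set.seed(9)
  imgs <- lapply(1:4, function(i) matrix(runif(16 * 16), 16, 16))
  msks <- lapply(1:4, function(i) make_disk(c(16, 16), c(8, 8), 4))
  cfg <- train_config("adam", epochs = 2, batch_size = 4, seed = 1)
  m <- build_unet(unet_config(depth = 2, base_filters = 2), seed = 1)
  fit <- train_unet(m, imgs, msks, imgs[1], msks[1], cfg)
  expect_equal(nrow(fit$log), 2)
  expect_equal(fit$best_epoch,
               orbitseg:::select_checkpoint(fit$log$val_accuracy))
  expect_error(train_unet(m, imgs, msks, list(), list(), cfg), "validation")
})

test_that("training is reproducible and learns a phantom region task", {
  vols <- generate_dataset(2, tiny_ct_params(seed = 1, center_jitter = 1),
                           seed = 31)
  imgs <- list(); msks <- list()
  for (v in vols) for (s in seq_along(v$intensities)) {
    imgs[[length(imgs) + 1]] <- normalize_minmax(v$intensities[[s]])
    msks[[length(msks) + 1]] <- v$region_masks[[s]]
  }
  cfg <- train_config("adam", learning_rate = 1e-3, epochs = 8,
                      batch_size = 8, seed = 4)
  m <- build_unet(unet_config(depth = 3, base_filters = 8), seed = 4)
  fit1 <- train_unet(m, imgs[1:8], msks[1:8], imgs[9:10], msks[9:10], cfg)
  fit2 <- train_unet(m, imgs[1:8], msks[1:8], imgs[9:10], msks[9:10], cfg)
  expect_identical(fit1$log$val_accuracy, fit2$log$val_accuracy)
  expect_lt(fit1$log$train_loss[8], fit1$log$train_loss[1])
})

test_that("a trained boundary network ranks true boundary pixels higher", {
  vols <- generate_dataset(3, tiny_ct_params(seed = 2, center_jitter = 1),
                           seed = 32)
  imgs <- list(); rings <- list()
  for (v in vols) for (s in seq_along(v$intensities)) {
    imgs[[length(imgs) + 1]] <- normalize_minmax(v$intensities[[s]])
    rings[[length(rings) + 1]] <-
      orbitseg:::dilate3(orbitseg:::mask_boundary(v$region_masks[[s]]), 1)
  }
  cfg <- train_config("sgd_momentum", learning_rate = 1e-2, epochs = 25,
                      batch_size = 8, seed = 6)
  m <- build_unet(unet_config(depth = 3, base_filters = 8), seed = 6)
  fit <- train_unet(m, imgs[1:12], rings[1:12], imgs[13:15], rings[13:15], cfg)
  pm <- predict_map(fit, imgs[[13]])
  on_b <- mean(pm[rings[[13]] > 0])
  off_b <- mean(pm[rings[[13]] == 0])
  expect_gt(on_b, off_b)
})
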