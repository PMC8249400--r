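# Training recipes for the two pipeline stages. Stage 1 (global region
# network): Adam, initial learning rate 0.001, 100 epochs. Stage 2 (local
# boundary network): SGD with momentum, initial learning rate 0.01, 500
# epochs. Both: cross-entropy loss, mini-batch 128, data shuffled each
# epoch, no learning-rate schedule, and the epoch with the best validation
# accuracy kept as the final network. The desk-scale profile shortens the
# schedules (30 / 60 epochs) on the same optimizers and rates.

#' Training configuration
#'
#' @param optimizer `"adam"` (stage-1 recipe) or `"sgd_momentum"` (stage-2
#'   recipe).
#' @param learning_rate initial learning rate, held constant.
#' @param momentum momentum coefficient (SGD only; conventional 0.9).
#' @param epochs training epochs.
#' @param batch_size mini-batch size (128 in the full recipes; training
#'   sets smaller than the batch form a single batch).
#' @param shuffle_each_epoch reshuffle the training order every epoch.
#' @param augment an [augment_config()] applied on the fly, or `NULL`.
#' @param seed integer seed covering initialization-independent training
#'   randomness (shuffling, augmentation draws, dropout).
#' @return object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd_momentum"),
                         learning_rate = 0.001,
                         momentum = 0.9,
                         epochs = 100L,
                         batch_size = 128L,
                         shuffle_each_epoch = TRUE,
                         augment = NULL,
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Stage-specific default training configurations
#'
#' `stage1_train_config()` is the global-network recipe (Adam, 0.001);
#' `stage2_train_config()` the local-network recipe (SGD momentum, 0.01).
#' `profile = "desk"` shortens the epoch counts (30 / 60) for small phantom
#' experiments while keeping optimizers and learning rates.
#'
#' @param profile `"full"` or `"desk"`.
#' @param ... overrides passed to [train_config()].
#' @return a `train_config`.
#' @export
stage1_train_config <- function(profile = c("full", "desk"), ...) {
  profile <- match.arg(profile)
  defaults <- list(optimizer = "adam", learning_rate = 0.001,
                   epochs = if (profile == "full") 100L else 30L,
                   batch_size = 128L)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

#' @rdname stage1_train_config
#' @export
stage2_train_config <- function(profile = c("full", "desk"), ...) {
  profile <- match.arg(profile)
  defaults <- list(optimizer = "sgd_momentum", learning_rate = 0.01,
                   epochs = if (profile == "full") 500L else 60L,
                   batch_size = 128L)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

# Index of the checkpointed epoch: the maximum of validation accuracy,
# ties broken toward the later epoch. Under heavy class imbalance the
# per-pixel accuracy often plateaus at the majority-class rate for many
# epochs; among equally accurate epochs the longer-trained weights are
# preferred.
select_checkpoint <- function(val_accuracy) {
  n <- length(val_accuracy)
  n + 1L - which.max(rev(val_accuracy))
}

make_optimizer <- function(cfg, param_names) {
  state <- new.env(parent = emptyenv())
  state$t <- 0
  if (cfg$optimizer == "adam") {
    state$m <- list(); state$v <- list()
    function(params, grads) {
      state$t <- state$t + 1
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (nm in names(grads)) {
        g <- grads[[nm]]
        m <- state$m[[nm]] %||% (g * 0)
        v <- state$v[[nm]] %||% (g * 0)
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g * g
        state$m[[nm]] <- m; state$v[[nm]] <- v
        mh <- m / (1 - b1^state$t)
        vh <- v / (1 - b2^state$t)
        params[[nm]] <- params[[nm]] - cfg$learning_rate * mh / (sqrt(vh) + eps)
      }
      params
    }
  } else {
    state$u <- list()
    function(params, grads) {
      for (nm in names(grads)) {
        u <- state$u[[nm]] %||% (grads[[nm]] * 0)
        u <- cfg$momentum * u - cfg$learning_rate * grads[[nm]]
        state$u[[nm]] <- u
        params[[nm]] <- params[[nm]] + u
      }
      params
    }
  }
}

# per-pixel accuracy of eval-mode predictions over an image/mask list
pixel_accuracy <- function(model, images, masks, backend = "cpp") {
  correct <- 0; total <- 0
  for (i in seq_along(images)) {
    pm <- predict_map(model, images[[i]], backend = backend)
    pred <- pm >= 0.5
    correct <- correct + sum(pred == (masks[[i]] > 0))
    total <- total + length(pm)
  }
  correct / total
}

#' Train a U-Net on paired images and masks
#'
#' Mini-batch training with the configured optimizer, cross-entropy loss
#' over per-pixel two-class labels, per-epoch shuffling, optional on-the-fly
#' augmentation, and best-validation-accuracy checkpointing: the returned
#' model carries the parameters of the epoch whose validation pixel accuracy
#' was maximal (first maximum on ties). Fully reproducible for a fixed seed
#' on one device.
#'
#' @param model an untrained or pre-trained `unet_model`.
#' @param train_images,train_masks lists of congruent matrices (masks
#'   binary).
#' @param val_images,val_masks non-empty validation lists; the checkpoint
#'   rule is undefined without validation data, so empty validation is an
#'   error.
#' @param cfg a [train_config()].
#' @param backend `"cpp"` (compiled single-precision backend, default) or
#'   `"r"` (pure-R double-precision reference); see [predict_map()].
#' @param verbose print one line per epoch.
#' @return object of class `trained_unet`: `cfg`, `params`, `stats` (the
#'   checkpointed weights), `log` (per-epoch train loss / accuracy and
#'   validation accuracy), `best_epoch`, `train_cfg`.
#' @export
train_unet <- function(model, train_images, train_masks,
                       val_images, val_masks, cfg,
                       backend = c("cpp", "r"), verbose = FALSE) {
  backend <- match.arg(backend)
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  n <- length(train_images)
  if (n == 0) stop("training set is empty")
  if (length(val_images) == 0) {
    stop("validation set is empty: the best-validation checkpoint rule is undefined")
  }
  stopifnot(length(train_masks) == n, length(val_images) == length(val_masks))
  set.seed(cfg$seed)
  opt <- make_optimizer(cfg, names(model$params))
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    train_accuracy = numeric(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, params = NULL, stats = NULL, epoch = NA_integer_)
  H <- nrow(train_images[[1]]); W <- ncol(train_images[[1]])
  for (ep in seq_len(cfg$epochs)) {
    ord <- if (cfg$shuffle_each_epoch) sample.int(n) else seq_len(n)
    losses <- c(); accs <- c()
    for (start in seq.int(1L, n, by = cfg$batch_size)) {
      take <- ord[start:min(start + cfg$batch_size - 1L, n)]
      imgs <- train_images[take]; msks <- train_masks[take]
      if (!is.null(cfg$augment)) {
        for (k in seq_along(imgs)) {
          aug <- augment_pair(imgs[[k]], msks[[k]], cfg$augment)
          imgs[[k]] <- aug$image; msks[[k]] <- aug$mask
        }
      }
      X <- stack_images(imgs)
      y <- stack_labels(msks)
      Nb <- length(take)
      if (backend == "cpp") {
        ucfg <- model$cfg
        n_bot <- Nb * (H %/% 2L^ucfg$depth) * (W %/% 2L^ucfg$depth) *
          ucfg$base_filters * 2L^ucfg$depth
        du <- if (ucfg$dropout_rate > 0) runif(n_bot) else numeric(0)
        res <- cpp_unet_train_batch(model$params, model$stats,
                                    as.numeric(X), y, H, W, Nb,
                                    ucfg$depth, ucfg$base_filters,
                                    ucfg$dropout_rate, du,
                                    bn_stat_momentum, bn_eps)
        model$stats <- res$stats
        model$params <- opt(model$params, res$grads)
        losses <- c(losses, res$loss)
        accs <- c(accs, res$accuracy)
      } else {
        fwd <- unet_forward(model, X, H, W, Nb, training = TRUE)
        model$stats <- fwd$stats
        ce <- softmax_ce(fwd$logits, y)
        grads <- unet_backward(model, fwd, ce$dlogits)
        model$params <- opt(model$params, grads)
        losses <- c(losses, ce$loss)
        accs <- c(accs, mean(max.col(ce$probs) == y))
      }
    }
    val_acc <- pixel_accuracy(model, val_images, val_masks, backend = backend)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                 train_accuracy = mean(accs),
                                 val_accuracy = val_acc))
    if (val_acc >= best$acc) {   # ties resolve to the later epoch
      best <- list(acc = val_acc, params = model$params,
                   stats = model$stats, epoch = ep)
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train acc %.4f  val acc %.4f",
                      ep, mean(losses), mean(accs), val_acc))
    }
  }
  structure(list(cfg = model$cfg, params = best$params, stats = best$stats,
                 log = log, best_epoch = best$epoch, train_cfg = cfg,
                 backend = backend),
            class = c("trained_unet", "unet_model"))
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf("<trained_unet> depth %d, base %d; %s lr %g, %d epochs\n",
              x$cfg$depth, x$cfg$base_filters, x$train_cfg$optimizer,
              x$train_cfg$learning_rate, x$train_cfg$epochs))
  cat(sprintf("  checkpoint: epoch %d, validation accuracy %.4f\n",
              x$best_epoch, x$log$val_accuracy[x$best_epoch]))
  invisible(x)
}
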