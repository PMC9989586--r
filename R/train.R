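# Training and evaluation: SGD with momentum and weight decay, a step
# learning-rate schedule, best-checkpoint selection by validation mDice,
# and deterministic end-to-end runs from a single seed.

#' Training configuration
#'
#' Defaults follow the standard protocol for this architecture: SGD with
#' momentum 0.9 and weight decay 0.001, initial learning rate 5e-3
#' decaying by a factor of 10 every 40 epochs, 300 epochs, batch size 4.
#'
#' @param lr0 Initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty applied to convolution/linear weights
#'   only (not biases or normalisation parameters).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param decay_every Epochs between learning-rate decays.
#' @param decay_factor Multiplicative decay (0.1 = divide by 10).
#' @param seed Integer seed covering shuffling and any augmentation.
#' @param loss A [loss_config()].
#' @param augment Logical; augment training samples each epoch
#'   (validation data is never augmented).
#' @param threshold Decision threshold for Dice monitoring.
#' @param eval_every Evaluate (and consider for the best snapshot) every
#'   this many epochs; the final epoch is always evaluated.
#' @return List of class `gu_train_config`.
#' @export
train_config <- function(lr0 = 5e-3, momentum = 0.9, weight_decay = 0.001,
                         epochs = 300L, batch_size = 4L, decay_every = 40L,
                         decay_factor = 0.1, seed = 1L,
                         loss = loss_config(), augment = FALSE,
                         threshold = 0.5, eval_every = 1L) {
  stopifnot(lr0 > 0, epochs >= 1, decay_every >= 1, batch_size >= 1,
            eval_every >= 1)
  structure(list(lr0 = lr0, momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor, seed = as.integer(seed),
                 loss = loss, augment = isTRUE(augment),
                 threshold = threshold, eval_every = as.integer(eval_every)),
            class = "gu_train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule `lr0 * decay_factor^floor(epoch / decay_every)`;
#' epochs count from 0.
#'
#' @param epoch Epoch index (0-based).
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_at <- function(epoch, cfg = train_config()) {
  stopifnot(all(epoch >= 0))
  cfg$lr0 * cfg$decay_factor^floor(epoch / cfg$decay_every)
}

sgd_step <- function(params, lr, momentum, weight_decay) {
  for (p in params) {
    g <- p$grad
    if (weight_decay > 0 && isTRUE(p$decay)) g <- g + weight_decay * p$value
    p$vel <- momentum * p$vel + g
    p$value <- p$value - lr * p$vel
  }
  invisible(NULL)
}

samples_to_batch <- function(samples) {
  imgs <- lapply(samples, `[[`, "image")
  msks <- lapply(samples, `[[`, "mask")
  d <- dim(imgs[[1]])
  list(x = array(unlist(imgs), c(d, length(imgs))),
       y = array(unlist(msks), c(d[1], d[2], 1L, length(msks))))
}

#' Train the segmentation network
#'
#' Runs mini-batch SGD with momentum on the combined BCE + Dice loss.
#' Every epoch the training set is reshuffled (deterministically from the
#' seed), the scheduled learning rate is applied, and training loss plus
#' validation mDice are recorded; the best parameter snapshot by
#' validation mDice (training mDice when no validation set is given) is
#' kept. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model A `guided_unet` from [build_model()], or a
#'   [model_config()] to build one.
#' @param train_samples Non-empty list of [seg_sample()] objects whose
#'   size matches the model's `input_size`.
#' @param val_samples Optional validation list.
#' @param cfg A [train_config()].
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return Object of class `gu_run`: epoch history (`history` data
#'   frame with loss, learning rate, train/val mDice), the trained
#'   `model`, `best` snapshot info and the configs.
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        cfg = train_config(), verbose = 0L) {
  if (inherits(model, "gu_config")) model <- build_model(model)
  if (!length(train_samples)) stop("train_model: empty training set")
  set.seed(cfg$seed)
  n <- length(train_samples)
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                     train_dice = numeric(), val_dice = numeric())
  best <- list(dice = -Inf, values = NULL, epoch = NA_integer_)
  step <- 0L
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at(epoch, cfg)
    perm <- sample.int(n)
    ep_samples <- train_samples[perm]
    if (cfg$augment)
      ep_samples <- lapply(seq_along(ep_samples), function(i)
        augment_sample(ep_samples[[i]],
                       seed = cfg$seed + 1000L * epoch + i))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- start:min(start + cfg$batch_size - 1L, n)
      batch <- samples_to_batch(ep_samples[idx])
      gu_zero_grads(model$params)
      prob <- forward_net(model, n_const(batch$x), training = TRUE)
      loss <- n_seg_loss(prob, batch$y, cfg$loss)
      if (!is.finite(loss$value))
        stop("train_model: non-finite loss at epoch ", epoch,
             " (step ", step, "); try a lower learning rate")
      gu_backward(loss)
      sgd_step(model$params, lr, cfg$momentum, cfg$weight_decay)
      ep_loss <- ep_loss + loss$value * length(idx)
      nb <- nb + length(idx)
      step <- step + 1L
    }
    ep_loss <- ep_loss / nb
    do_eval <- (epoch %% cfg$eval_every == 0L) || (epoch == cfg$epochs - 1L)
    tr_dice <- if (do_eval)
      evaluate_model(model, train_samples, threshold = cfg$threshold)$mean["dice"]
    else NA_real_
    va_dice <- if (do_eval && !is.null(val_samples))
      evaluate_model(model, val_samples, threshold = cfg$threshold)$mean["dice"]
    else NA_real_
    sel <- if (!is.null(val_samples)) va_dice else tr_dice
    if (do_eval && sel > best$dice) {
      best <- list(dice = sel,
                   values = lapply(model$params, function(p) p$value),
                   bn = lapply(model$bn_states, as.list),
                   epoch = epoch)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss, lr = lr,
                                   train_dice = unname(tr_dice),
                                   val_dice = unname(va_dice)))
    if (verbose > 0L && (epoch %% verbose == 0L))
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  train mDice %.4f%s",
                      epoch, lr, ep_loss, tr_dice,
                      if (is.na(va_dice)) ""
                      else sprintf("  val mDice %.4f", va_dice)))
  }
  structure(list(history = hist, model = model, best = best,
                 train_config = cfg, model_config = model$config),
            class = "gu_run")
}

#' Restore the best-epoch parameters into the run's model
#'
#' @param run A `gu_run`.
#' @return The run's model with the best snapshot loaded.
#' @export
restore_best <- function(run) {
  if (is.null(run$best$values)) return(run$model)
  for (i in seq_along(run$model$params))
    run$model$params[[i]]$value <- run$best$values[[i]]
  for (i in seq_along(run$model$bn_states)) {
    run$model$bn_states[[i]]$running_mean <- run$best$bn[[i]]$running_mean
    run$model$bn_states[[i]]$running_var <- run$best$bn[[i]]$running_var
  }
  run$model
}

#' Evaluate a model on a sample list
#'
#' Deterministic evaluation mode: batch-norm uses running statistics.
#' Metrics are computed per image from thresholded confusion counts and
#' then averaged (mDice, mIoU).
#'
#' @param model A `guided_unet` or a `gu_run`.
#' @param samples List of [seg_sample()] objects.
#' @param threshold Decision threshold.
#' @return List with `per_image` (data frame: id, dice, iou, precision,
#'   recall) and `mean` (named numeric vector of the four averages).
#' @export
evaluate_model <- function(model, samples, threshold = 0.5) {
  if (inherits(model, "gu_run")) model <- model$model
  rows <- lapply(samples, function(s) {
    p <- predict(model, s)
    m <- seg_metrics(confusion(p, s$mask, threshold))
    data.frame(id = s$id, dice = m$dice, iou = m$iou,
               precision = m$precision, recall = m$recall)
  })
  per <- do.call(rbind, rows)
  list(per_image = per,
       mean = c(dice = mean(per$dice), iou = mean(per$iou),
                precision = mean(per$precision), recall = mean(per$recall)))
}

#' Save / load checkpoints
#'
#' A checkpoint stores the model configuration, every parameter tensor
#' and the batch-norm running statistics; loading rebuilds the model and
#' restores them, so saved and reloaded models evaluate identically.
#'
#' @param model A `guided_unet` (or `gu_run`, whose current model is
#'   saved).
#' @param path File path (.rds).
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   restored `guided_unet`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "gu_run")) model <- model$model
  saveRDS(list(config = model$config,
               values = lapply(model$params, function(p) p$value),
               bn = lapply(model$bn_states, as.list)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  for (i in seq_along(model$params)) model$params[[i]]$value <- ck$values[[i]]
  for (i in seq_along(model$bn_states)) {
    model$bn_states[[i]]$running_mean <- ck$bn[[i]]$running_mean
    model$bn_states[[i]]$running_var <- ck$bn[[i]]$running_var
  }
  model
}

#' @export
print.gu_run <- function(x, ...) {
  h <- x$history
  cat(sprintf("<gu_run: %d epochs, final loss %.4f, best mDice %.4f (epoch %d)>\n",
              nrow(h), h$loss[nrow(h)], x$best$dice, x$best$epoch))
  invisible(x)
}

#' @export
summary.gu_run <- function(object, ...) {
  print(object)
  h <- object$history
  show <- h[unique(pmax(1, round(seq(1, nrow(h), length.out = 6)))), ]
  print(show, row.names = FALSE)
  invisible(object)
}

#' @export
predict.gu_run <- function(object, x, ...) predict(object$model, x, ...)

#' Plot training history
#'
#' @param x A `gu_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gu_run <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (any(!is.na(h$val_dice))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_dice, type = "l", col = 2, axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4, col.axis = 2)
    graphics::mtext("val mDice", 4, col = 2, line = 2)
  }
  invisible(x)
}
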