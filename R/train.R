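#' Learning-rate schedule
#'
#' Step decay: the initial rate is decreased by 10% (multiplied by `decay`)
#' every `every` epochs, i.e. `base * decay^floor(epoch / every)`.
#'
#' @param epoch Epoch number (0-based; epoch 0..99 use `base`).
#' @param base Initial learning rate (default 3e-4).
#' @param decay Multiplier per step (default 0.9).
#' @param every Epochs per step (default 100).
#' @return Learning rate.
#' @examples
#' lr_schedule(0)    # 3e-4
#' lr_schedule(100)  # 2.7e-4
#' @export
lr_schedule <- function(epoch, base = 3e-4, decay = 0.9, every = 100) {
  base * decay^(epoch %/% every)
}

#' Train the gated-fusion transformer
#'
#' Seeded Adam training on paired (normalized low-quality input, ground
#' truth) images with the hybrid loss. Defaults follow the reference recipe:
#' Adam with beta1 = 0.5, beta2 = 0.999, weight decay 5e-5, batch size 24
#' (capped at the dataset size), initial learning rate 3e-4 decayed by 10%
#' every 100 epochs. Training aborts with diagnostics if the loss becomes
#' non-finite.
#'
#' @param pairs List of pairs `list(input = matrix, target = matrix)` with
#'   values in \[0,1\] (inputs already normalized by `2^b`), or a manifest
#'   path / list from [build_dataset()] (measurement as input, HR as target).
#' @param config A [network_config()]; `sr_scale` must match the pair shapes.
#' @param loss A [loss_config()].
#' @param seed Seed for initialization, shuffling and batching.
#' @param steps Total optimization steps (overrides `epochs` when given).
#' @param epochs Passes over the data (used when `steps` is `NULL`).
#' @param batch_size Images per step.
#' @param lr,lr_decay,lr_decay_every Learning-rate schedule (see
#'   [lr_schedule()]).
#' @param beta1,beta2,weight_decay Adam hyperparameters.
#' @param verbose Print a line every `verbose` steps (0 = silent).
#' @return A trained `spad_gft` with a `log` data.frame (step, epoch, lr,
#'   loss and unweighted loss terms).
#' @export
train_gft <- function(pairs, config = network_config(), loss = loss_config(),
                      seed = 1, steps = NULL, epochs = 1,
                      batch_size = 24, lr = 3e-4, lr_decay = 0.9,
                      lr_decay_every = 100, beta1 = 0.5, beta2 = 0.999,
                      weight_decay = 5e-5, verbose = 0) {
  pairs <- .as_pairs(pairs)
  if (!length(pairs)) stop("no training pairs", call. = FALSE)
  stopifnot(inherits(config, "spad_net_config"),
            inherits(loss, "spad_loss_config"))
  model <- gft_init(config, seed = seed)
  n <- length(pairs)
  batch_size <- min(batch_size, n)
  steps_per_epoch <- max(1L, n %/% batch_size)
  if (is.null(steps)) steps <- epochs * steps_per_epoch

  opt <- new.env(parent = emptyenv())
  opt$m <- lapply(model$params, function(p) array(0, dim(p$value) %||% length(p$value)))
  opt$v <- opt$m
  opt$t <- 0L

  log_rows <- vector("list", steps)
  with_seed(seed + 1L, {
    order_idx <- sample.int(n)
    pos <- 1L
    for (step in seq_len(steps)) {
      if (pos + batch_size - 1L > n) {
        order_idx <- sample.int(n)
        pos <- 1L
      }
      idx <- order_idx[pos:(pos + batch_size - 1L)]
      pos <- pos + batch_size
      epoch <- (step - 1L) %/% steps_per_epoch
      cur_lr <- lr_schedule(epoch, lr, lr_decay, lr_decay_every)

      xb <- .stack_batch(lapply(pairs[idx], `[[`, "input"))
      yb <- .stack_batch(lapply(pairs[idx], `[[`, "target"))
      ag_zero_grad(model$params)
      fwd <- .gft_forward_nodes(model, ag_const(xb), training = TRUE)
      lres <- .hybrid_loss_nodes(fwd$output, ag_const(yb), loss)
      lval <- lres$total$value
      if (!is.finite(lval)) {
        stop(sprintf(
          "non-finite loss at step %d (l1=%g, per=%g, ssim=%g): try a lower learning rate",
          step, lres$l1$value, lres$per$value, lres$ssim_term$value
        ), call. = FALSE)
      }
      ag_backward(lres$total)
      .adam_step(model$params, opt, cur_lr, beta1, beta2, weight_decay)

      log_rows[[step]] <- data.frame(
        step = step, epoch = epoch, lr = cur_lr, loss = lval,
        l1 = lres$l1$value, perceptual = lres$per$value,
        ssim_term = lres$ssim_term$value
      )
      if (verbose > 0 && step %% verbose == 0) {
        message(sprintf("step %d/%d  loss %.5g", step, steps, lval))
      }
    }
  })
  model$log <- do.call(rbind, log_rows)
  model$loss_config <- loss
  model
}

.adam_step <- function(params, opt, lr, beta1, beta2, weight_decay,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + eps)
  }
}

.stack_batch <- function(mats) {
  d <- dim(mats[[1]])
  out <- array(0, c(length(mats), d[1], d[2], 1))
  for (i in seq_along(mats)) out[i, , , 1] <- mats[[i]]
  out
}

.as_pairs <- function(pairs) {
  if (is.character(pairs)) {
    pairs <- jsonlite::read_json(pairs, simplifyVector = FALSE)
  }
  if (is.list(pairs) && !is.null(pairs$pairs)) {
    root <- pairs$root %||% "."
    pairs <- lapply(pairs$pairs, function(e) {
      list(input = tiff::readTIFF(file.path(root, e$measurement)),
           target = tiff::readTIFF(file.path(root, e$hr)))
    })
  }
  pairs
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the architecture configuration, all parameter values,
#' the batch-norm running statistics and the training log; reloading restores
#' a model whose eval-mode outputs are bit-identical to the saved one. A JSON
#' echo of the configuration is written next to the checkpoint for
#' provenance.
#'
#' @param model A `spad_gft`.
#' @param path Checkpoint path (.rds).
#' @return `path` invisibly (for `save_checkpoint`); the model (for
#'   `load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "spad_gft"))
  saveRDS(list(
    config = model$config,
    values = lapply(model$params, function(p) p$value),
    running_mean = model$state$running_mean,
    running_var = model$state$running_var,
    log = model$log,
    seed = model$seed,
    version = as.character(utils::packageVersion("spadkit"))
  ), path)
  jsonlite::write_json(
    c(unclass(model$config),
      list(version = as.character(utils::packageVersion("spadkit")),
           seed = model$seed)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- gft_init(ck$config, seed = ck$seed %||% 1L)
  for (nm in names(ck$values)) model$params[[nm]]$value <- ck$values[[nm]]
  model$state$running_mean <- ck$running_mean
  model$state$running_var <- ck$running_var
  model$log <- ck$log
  model
}
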