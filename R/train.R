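#' Training configuration
#'
#' Defaults follow the published protocol: RMSprop, initial learning rate
#' 1e-5, 40 epochs, batch size 2, a 7:1:2 case split, and a conditional
#' learning-rate trigger that multiplies the rate by `lr_factor` when the
#' best validation loss has not improved for `patience_epochs` consecutive
#' epochs.
#'
#' @param lr0 Initial learning rate (> 0).
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Slices per mini-batch (>= 1).
#' @param optimizer Only `"rmsprop"` is implemented.
#' @param loss `"dice_bce"` (default), `"dice"`, or `"bce"`.
#' @param lr_factor Multiplier applied when the trigger fires (default 0.1).
#' @param patience_epochs Stalled epochs before the trigger fires (default 2).
#' @param seed Seed for shuffling and any stochastic behaviour.
#' @param split_ratios Train/validation/test ratios (default `c(7, 1, 2)`).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-5, epochs = 40L, batch_size = 2L,
                         optimizer = "rmsprop",
                         loss = c("dice_bce", "dice", "bce"),
                         lr_factor = 0.1, patience_epochs = 2L,
                         seed = 1L, split_ratios = c(7, 1, 2)) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer, "rmsprop")
  if (lr0 <= 0) stop("`lr0` must be positive.")
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("`epochs` must be at least 1.")
  if (batch_size < 1L) stop("`batch_size` must be at least 1.")
  if (any(split_ratios <= 0)) stop("Split ratios must be positive.")
  structure(
    list(lr0 = lr0, epochs = epochs, batch_size = as.integer(batch_size),
         optimizer = optimizer, loss = loss, lr_factor = lr_factor,
         patience_epochs = as.integer(patience_epochs),
         seed = as.integer(seed), split_ratios = split_ratios),
    class = "train_config"
  )
}

#' Split case IDs into train / validation / test partitions
#'
#' Cases are randomly permuted by `seed`, then the first `floor(0.7 n)` go
#' to training, the next `floor(0.1 n)` to validation, and the remainder to
#' test (for the default 7:1:2 ratios; general ratios are normalized the
#' same way with the remainder in test). The split is by case, never by
#' slice, so no patient contributes slices to two partitions.
#'
#' @param case_ids Character or integer vector of case identifiers
#'   (>= 3 cases).
#' @param ratios Length-3 positive ratios (default `c(7, 1, 2)`).
#' @param seed Integer seed.
#' @return Named list with `train`, `val`, `test` vectors.
#' @export
split_cases <- function(case_ids, ratios = c(7, 1, 2), seed = 1L) {
  if (length(case_ids) == 0) stop("`case_ids` is empty.")
  if (length(case_ids) < 3) stop("Need at least 3 cases to split.")
  if (anyDuplicated(case_ids)) stop("`case_ids` contains duplicates.")
  fr <- ratios / sum(ratios)
  n <- length(case_ids)
  n_train <- floor(fr[1] * n)
  n_val <- floor(fr[2] * n)
  perm <- with_seed(seed, sample(case_ids))
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[(n_train + n_val + 1):n])
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

soft_dice_loss <- function(pred, target, smooth = 1) {
  num <- 2 * sum(pred * target) + smooth
  den <- sum(pred) + sum(target) + smooth
  1 - num / den
}

#' Segmentation loss between a probability map and a binary target
#'
#' `dice_bce` is the sum of the soft-Dice loss
#' `1 - (2 sum(p t) + s) / (sum(p) + sum(t) + s)` (smoothing `s = 1`) and
#' the mean binary cross-entropy, each averaged over the batch. The loss is
#' non-negative and tends to 0 as the prediction approaches the target
#' pointwise.
#'
#' @param pred Numeric array of probabilities in `[0, 1]`.
#' @param target Binary array of the same shape.
#' @param type `"dice_bce"`, `"dice"`, or `"bce"`.
#' @return Non-negative scalar loss.
#' @export
loss_fn <- function(pred, target, type = c("dice_bce", "dice", "bce")) {
  type <- match.arg(type)
  if (!identical(dim(pred), dim(target)) &&
      length(pred) != length(target)) {
    stop("`pred` and `target` shapes differ.")
  }
  if (any(pred < 0 | pred > 1)) stop("`pred` must lie in [0, 1].")
  p <- clamp_prob(pred)
  t <- as.numeric(target)
  dice <- soft_dice_loss(p, t)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  switch(type, dice_bce = dice + bce, dice = dice, bce = bce)
}

# Batch objective used by the trainer: mean BCE over every voxel of the
# batch, plus soft dice averaged over the slices that contain lesion.
# On an empty-target slice the dice ratio is degenerate (0/0 up to
# smoothing) and acts as a pure shrinkage penalty, so it is skipped there
# and absence is learned through the BCE term alone. The single-slice
# loss_fn() contract is untouched. Returns list(loss, dlogits per slice).
batch_loss_grad <- function(probs, targets, type, smooth = 1) {
  p <- lapply(probs, clamp_prob)
  t <- lapply(targets, as.numeric)
  has_fg <- vapply(t, function(x) sum(x) > 0, TRUE)
  n_dice <- max(1L, sum(has_fg))
  n_vox <- sum(lengths(p))
  dice <- 0
  bce <- 0
  dl_dice <- vector("list", length(p))
  for (i in seq_along(p)) {
    if (has_fg[i]) {
      num <- 2 * sum(p[[i]] * t[[i]]) + smooth
      den <- sum(p[[i]]) + sum(t[[i]]) + smooth
      dice <- dice + (1 - num / den) / n_dice
      dl_dice[[i]] <- (-(2 * t[[i]] * den - num) / den^2) *
        p[[i]] * (1 - p[[i]]) / n_dice
    } else {
      dl_dice[[i]] <- 0
    }
    bce <- bce - sum(t[[i]] * log(p[[i]]) +
                       (1 - t[[i]]) * log(1 - p[[i]])) / n_vox
  }
  loss <- switch(type, dice_bce = dice + bce, dice = dice, bce = bce)
  dlogits <- lapply(seq_along(p), function(i) {
    dl_bce <- (p[[i]] - t[[i]]) / n_vox
    dl <- switch(type, dice_bce = dl_dice[[i]] + dl_bce,
                 dice = dl_dice[[i]] * (has_fg[i] * 1), bce = dl_bce)
    array(dl, dim(probs[[i]]))
  })
  list(loss = loss, dlogits = dlogits)
}

# Gradient of the loss with respect to the pre-sigmoid logits, for one
# slice. Returns list(loss, dlogits).
loss_grad_logits <- function(prob, target, type, smooth = 1) {
  p <- clamp_prob(prob)
  t <- as.numeric(target)
  n <- length(p)
  dice_num <- 2 * sum(p * t) + smooth
  dice_den <- sum(p) + sum(t) + smooth
  dice <- 1 - dice_num / dice_den
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  dp_dice <- -(2 * t * dice_den - dice_num) / dice_den^2
  # d(bce)/d(logit) has the closed form (p - t)/n through the sigmoid
  dl_bce <- (p - t) / n
  dl_dice <- dp_dice * p * (1 - p)
  loss <- switch(type, dice_bce = dice + bce, dice = dice, bce = bce)
  dlogits <- switch(type,
                    dice_bce = dl_dice + dl_bce,
                    dice = dl_dice,
                    bce = dl_bce)
  list(loss = loss, dlogits = array(dlogits, dim(prob)))
}

#' Conditional learning-rate trigger
#'
#' Replays a validation-loss history under the stalled-best rule: whenever
#' the best validation loss seen so far fails to improve strictly for
#' `patience` consecutive completed epochs, the learning rate is multiplied
#' by `factor` and the stall counter resets. Returns the learning rate in
#' force after the last recorded epoch.
#'
#' @param val_history Numeric vector of per-epoch validation losses
#'   (non-empty).
#' @param lr0 Learning rate at epoch 1.
#' @param factor Multiplier applied on trigger (default 0.1).
#' @param patience Consecutive stalled epochs required (default 2).
#' @return The current learning rate.
#' @export
lr_step <- function(val_history, lr0, factor = 0.1, patience = 2L) {
  if (length(val_history) == 0) stop("`val_history` is empty.")
  lr <- lr0
  best <- Inf
  stall <- 0L
  for (v in val_history) {
    if (v < best) {
      best <- v
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        lr <- lr * factor
        stall <- 0L
      }
    }
  }
  lr
}

# ---- parameter-tree utilities ---------------------------------------------

is_leaf <- function(x) is.list(x) && !is.null(x$W)

tree_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is_leaf(a)) return(f(a, b))
  out <- a
  for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
  out
}

zeros_like_tree <- function(p) {
  tree_map2(p, p, function(a, b) list(W = a$W * 0, b = a$b * 0))
}

add_grads <- function(acc, g) {
  tree_map2(acc, g, function(a, b) list(W = a$W + b$W, b = a$b + b$b))
}

scale_grads <- function(g, s) {
  tree_map2(g, g, function(a, b) list(W = a$W * s, b = a$b * s))
}

rmsprop_update <- function(params, grads, state, lr, rho = 0.99, eps = 1e-8) {
  new_state <- tree_map2(state, grads, function(s, g) {
    list(W = rho * s$W + (1 - rho) * g$W^2,
         b = rho * s$b + (1 - rho) * g$b^2)
  })
  st <- new_state
  new_params <- local({
    upd <- function(p, g, s) list(W = p$W - lr * g$W / (sqrt(s$W) + eps),
                                  b = p$b - lr * g$b / (sqrt(s$b) + eps))
    rec <- function(p, g, s) {
      if (is.null(p)) return(NULL)
      if (is_leaf(p)) return(upd(p, g, s))
      out <- p
      for (i in seq_along(p)) out[[i]] <- rec(p[[i]], g[[i]], s[[i]])
      out
    }
    rec(params, grads, st)
  })
  list(params = new_params, state = new_state)
}

# ---- data handling ---------------------------------------------------------

# Load a manifest (tibble with image_path/mask_path) or a list of
# generate_phantom() results into normalized in-memory cases.
load_training_cases <- function(data, window = c(-60, 140)) {
  if (inherits(data, "data.frame")) {
    ids <- data$case_id
    cases <- purrr::pmap(data, function(case_id, image_path, mask_path, ...) {
      vol <- read_case(image_path, case_id = case_id)
      list(volume = window_normalize(vol, window[1], window[2]),
           mask = read_mask(mask_path, case_id = case_id))
    })
    names(cases) <- ids
    return(cases)
  }
  if (is.list(data)) {
    cases <- lapply(data, function(cs) {
      vol <- cs$volume
      if (vol$units == "HU") vol <- window_normalize(vol, window[1], window[2])
      list(volume = vol, mask = cs$mask)
    })
    ids <- vapply(cases, function(cs) cs$volume$case_id, "")
    names(cases) <- ids
    return(cases)
  }
  stop("`data` must be a manifest data frame or a list of phantom cases.")
}

case_dice <- function(pred_mask, gt_mask) {
  cc <- confusion_counts(pred_mask, gt_mask)
  overlap_metrics(cc)$dice
}

eval_partition <- function(model, cases, ids, loss_type, threshold = 0.5) {
  losses <- c()
  dices <- c()
  for (id in ids) {
    cs <- cases[[id]]
    d <- dim(cs$volume$voxels)
    pred_lab <- array(0L, d)
    for (k in seq_len(d[3])) {
      pr <- net_forward(model, cs$volume$voxels[, , k, drop = FALSE])$prob
      losses <- c(losses, loss_fn(pr, cs$mask$labels[, , k, drop = FALSE],
                                  type = loss_type))
      pred_lab[, , k] <- as.integer(pr >= threshold)
    }
    pm <- ich_mask(pred_lab, cs$volume$spacing_mm)
    dices <- c(dices, case_dice(pm, cs$mask))
  }
  list(loss = mean(losses), dice = mean(dices))
}

#' Train a segmentation network on phantom or clinical cases
#'
#' Mini-batch RMSprop training over the axial slices of the training cases
#' (slices pooled across cases and reshuffled every epoch; slices with
#' empty masks are kept so the network learns absence). After each epoch
#' the validation loss and validation Dice are logged and the
#' learning-rate trigger [lr_step()] is applied (watching the validation
#' loss; when it fires, training resumes from the best checkpoint at the
#' reduced rate). The returned model is the checkpoint with the best
#' validation Dice.
#'
#' @param model An `attfocusnet_model` to train.
#' @param data A cohort manifest tibble (from [generate_cohort()]) or a
#'   list of in-memory cases (each a list with `volume` and `mask`).
#' @param cfg A [train_config].
#' @param split Optional list with `train`/`val` (and optionally `test`)
#'   case IDs; computed with [split_cases()] when `NULL`.
#' @return A list of class `hemseg_fit`: `model` (best checkpoint), `last`
#'   (final-epoch model), `log` (tibble: epoch, lr, train_loss, val_loss,
#'   val_dice), `split`, and `config`.
#' @export
train <- function(model, data, cfg = train_config(), split = NULL) {
  stopifnot(inherits(model, "attfocusnet_model"),
            inherits(cfg, "train_config"))
  cases <- load_training_cases(data)
  if (is.null(split)) {
    split <- split_cases(names(cases), ratios = cfg$split_ratios,
                         seed = cfg$seed)
  }
  if (length(split$train) == 0 || length(split$val) == 0) {
    stop("Training and validation partitions must be non-empty.")
  }
  slice_index <- do.call(rbind, lapply(split$train, function(id) {
    data.frame(id = id, k = seq_len(dim(cases[[id]]$volume$voxels)[3]))
  }))
  params <- model$params
  state <- zeros_like_tree(params)
  lr <- cfg$lr0
  log_rows <- vector("list", cfg$epochs)
  best_val_dice <- -Inf
  best_params <- params
  val_hist <- c()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(nrow(slice_index))
      epoch_losses <- c()
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
        i <- i + cfg$batch_size
        m <- list(params = params, cfg = model$cfg)
        class(m) <- "attfocusnet_model"
        # forward every slice of the batch, then differentiate the pooled
        # batch objective: soft dice over the pooled batch voxels (so
        # empty slices only enter the denominator) plus per-voxel BCE
        fws <- list(); targets <- list()
        for (bi in seq_along(batch)) {
          j <- batch[bi]
          cs <- cases[[slice_index$id[j]]]
          k <- slice_index$k[j]
          fws[[bi]] <- net_forward(m, cs$volume$voxels[, , k, drop = FALSE],
                                   keep_cache = TRUE)
          targets[[bi]] <- cs$mask$labels[, , k, drop = FALSE]
        }
        lg <- batch_loss_grad(lapply(fws, `[[`, "prob"), targets, cfg$loss)
        if (!is.finite(lg$loss)) {
          stop("Non-finite training loss at epoch ", epoch,
               ", case ", slice_index$id[batch[1]],
               "; lower the learning rate.")
        }
        acc <- NULL
        for (bi in seq_along(batch)) {
          g <- net_backward(m, lg$dlogits[[bi]], fws[[bi]]$cache)
          acc <- if (is.null(acc)) g else add_grads(acc, g)
        }
        upd <- rmsprop_update(params, acc, state, lr)
        params <- upd$params
        state <- upd$state
        epoch_losses <- c(epoch_losses, lg$loss)
      }
      m <- list(params = params, cfg = model$cfg)
      class(m) <- "attfocusnet_model"
      ev <- eval_partition(m, cases, split$val, cfg$loss)
      val_hist <- c(val_hist, ev$loss)
      # checkpoint on validation Dice, the task metric (the trigger below
      # still watches the validation loss)
      if (ev$dice > best_val_dice) {
        best_val_dice <- ev$dice
        best_params <- params
      }
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = mean(epoch_losses),
        val_loss = ev$loss, val_dice = ev$dice)
      new_lr <- lr_step(val_hist, cfg$lr0, cfg$lr_factor, cfg$patience_epochs)
      if (new_lr < lr) {
        # on trigger, resume from the best checkpoint at the reduced rate
        # (reduce-on-plateau with best-weight restore); the optimizer state
        # is reset alongside
        params <- best_params
        state <- zeros_like_tree(params)
      }
      lr <- new_lr
    }
  })
  best <- list(params = best_params, cfg = model$cfg, seed = model$seed)
  class(best) <- "attfocusnet_model"
  last <- list(params = params, cfg = model$cfg, seed = model$seed)
  class(last) <- "attfocusnet_model"
  structure(list(model = best, last = last,
                 log = dplyr::bind_rows(log_rows),
                 split = split, config = cfg),
            class = "hemseg_fit")
}

#' @export
print.hemseg_fit <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<hemseg_fit> %d epochs; best val loss %.4f, final val Dice %.4f\n",
              n, min(x$log$val_loss), x$log$val_dice[n]))
  invisible(x)
}

#' @export
glance.hemseg_fit <- function(x, ...) {
  n <- nrow(x$log)
  tibble::tibble(
    epochs = n,
    best_val_loss = min(x$log$val_loss),
    final_val_loss = x$log$val_loss[n],
    final_val_dice = x$log$val_dice[n],
    final_lr = x$log$lr[n],
    n_train = length(x$split$train),
    n_val = length(x$split$val)
  )
}

#' @export
tidy.hemseg_fit <- function(x, ...) x$log

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weights, the network configuration, and the
#' initialization seed.
#'
#' @param model An `attfocusnet_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (write) or the restored model (read).
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "attfocusnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "attfocusnet_model")) stop("Not a model checkpoint: ", path)
  m
}
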