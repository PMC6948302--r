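#' Configure training
#'
#' Defaults follow the published hyperparameter table: learning rate 0.001,
#' batch size 8, L2 regularization weight 0.0001, glorot-normal weight
#' initialization, and an 80/20 train/test split.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Gradient-accumulation batch size (>= 1).
#' @param l2_weight Decoupled L2 penalty applied to convolution weights.
#' @param epochs Training epochs.
#' @param seed Seed governing initialization, shuffling and batching.
#' @param split Train fraction of the dataset split, in (0, 1).
#' @param augmentation Optional [augmentation_spec()] applied online to each
#'   training pair (re-seeded per epoch and sample), or `NULL`.
#' @param threshold Probability threshold used for validation DSC.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @return An object of class `ms_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 8,
                         l2_weight = 1e-4, epochs = 50, seed = 1,
                         split = 0.8, augmentation = NULL, threshold = 0.5,
                         optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  if (split <= 0 || split >= 1)
    ms_stop("msunet_config_error", "split must be in (0, 1)")
  if (batch_size < 1) ms_stop("msunet_config_error", "batch_size must be >= 1")
  if (learning_rate < 0)
    ms_stop("msunet_config_error", "learning_rate must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 l2_weight = l2_weight, epochs = as.integer(epochs),
                 seed = as.integer(seed), split = split,
                 augmentation = augmentation, threshold = threshold,
                 optimizer = optimizer),
            class = "ms_train_config")
}

#' Split a dataset into train and test sets
#'
#' Seeded random split at the configured fraction. Pairs carrying a
#' `source` field (augmented variants from [expand_dataset()]) are grouped
#' so every variant of one source lands on the same side, preventing
#' train/test leakage through augmentation.
#'
#' @param pairs List of image/mask pairs.
#' @param cfg A [train_config()] (uses its `split` and `seed`), or a numeric
#'   fraction.
#' @param seed Seed when `cfg` is a numeric fraction.
#' @return `list(train =, test =)` of disjoint, exhaustive sublists.
#' @export
split_dataset <- function(pairs, cfg = train_config(), seed = NULL) {
  if (is.numeric(cfg)) cfg <- train_config(split = cfg,
                                           seed = if (is.null(seed)) 1 else seed)
  stopifnot(inherits(cfg, "ms_train_config"))
  if (length(pairs) < 2)
    ms_stop("msunet_config_error", "need at least 2 pairs to split")
  groups <- vapply(seq_along(pairs), function(i) {
    s <- pairs[[i]]$source
    if (is.null(s)) i else as.integer(s)
  }, 0L)
  gids <- unique(groups)
  n_train <- round(cfg$split * length(gids))
  if (n_train < 1 || n_train >= length(gids))
    ms_stop("msunet_config_error",
            "split fraction leaves an empty train or test side")
  train_g <- with_seed(cfg$seed, sample(gids, n_train))
  list(train = pairs[groups %in% train_g],
       test = pairs[!groups %in% train_g])
}

#' Train a segmentation model
#'
#' Optimizes the soft Dice loss with Adam (decoupled L2 on convolution
#' weights) under full seeded determinism: batches are reshuffled each epoch
#' with an epoch-derived seed, gradients are accumulated over
#' `batch_size` images and averaged, and the parameters of the best
#' (lowest mean training loss) epoch are retained and restored at the end.
#'
#' @param model An [build_network()] model; mutated in place.
#' @param train_pairs Non-empty list of `list(image =, mask =)` pairs whose
#'   images are already normalized to the network's input size.
#' @param cfg A [train_config()].
#' @param val_pairs Optional held-out pairs; mean validation DSC is logged
#'   per epoch.
#' @param verbose Print one line per epoch.
#' @return `list(model =, history =, best_epoch =)`; `history` is a data
#'   frame with columns `epoch`, `loss` and (if validation) `val_dsc`.
#' @export
train <- function(model, train_pairs, cfg = train_config(),
                  val_pairs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ms_model"), inherits(cfg, "ms_train_config"))
  if (length(train_pairs) == 0)
    ms_stop("msunet_config_error", "training set is empty")
  layers <- model_layers(model)
  history <- data.frame(epoch = integer(), loss = numeric())
  best <- list(loss = Inf, params = NULL, epoch = NA_integer_)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed((cfg$seed + 131 * epoch) %% .Machine$integer.max,
                     sample(length(train_pairs)))
    losses <- numeric(0)
    i <- 1
    while (i <= length(ord)) {
      take <- ord[i:min(i + cfg$batch_size - 1, length(ord))]
      for (l in layers) layer_zero_grads(l)
      for (j in take) {
        pair <- train_pairs[[j]]
        img <- pair$image; msk <- pair$mask
        if (!is.null(cfg$augmentation)) {
          a <- cfg$augmentation
          a$seed <- as.integer((cfg$seed + 7919 * epoch + 104729 * j) %%
                                 .Machine$integer.max)
          ap <- augment_pair(img, msk, a)
          img <- ap$image; msk <- ap$mask
        }
        fr <- forward_network(model, img, training = TRUE)
        loss <- dice_loss(fr$prob, as_chw(msk))
        losses <- c(losses, loss)
        dprob <- dice_loss_grad(array(fr$prob, dim = dim(fr$prob)),
                                as_chw(msk))
        backward_network(model, fr$caches, dprob)
      }
      scale <- 1 / length(take)
      for (l in layers) {
        if (cfg$optimizer == "adam") {
          layer_adam_step(l, cfg$learning_rate, cfg$l2_weight, scale = scale)
        } else {
          sgd_step(l, cfg$learning_rate, cfg$l2_weight, scale)
        }
      }
      i <- i + cfg$batch_size
    }
    mean_loss <- mean(losses)
    if (!is.finite(mean_loss))
      stop(structure(class = c("msunet_training_error", "msunet_error",
                               "error", "condition"),
                     list(message = "training diverged: non-finite loss",
                          call = sys.call(), history = history)))
    row <- data.frame(epoch = epoch, loss = mean_loss)
    if (!is.null(val_pairs)) {
      row$val_dsc <- mean(vapply(val_pairs, function(p) {
        pr <- predict_prob(model, p$image)
        compute_metrics(predict_mask(pr, cfg$threshold), p$mask)$dsc
      }, 0))
    }
    history <- rbind(history, row)
    if (mean_loss < best$loss) {
      best <- list(loss = mean_loss, params = collect_params(model),
                   epoch = epoch)
    }
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f%s\n", epoch, mean_loss,
                  if (!is.null(row$val_dsc))
                    sprintf("  val_dsc %.4f", row$val_dsc) else ""))
  }
  if (!is.null(best$params)) set_params(model, best$params)
  list(model = model, history = history, best_epoch = best$epoch)
}

sgd_step <- function(layer, lr, l2, scale) {
  pn <- layer_param_names(layer); gn <- layer_grad_names(layer)
  for (i in seq_along(pn)) {
    g <- get(gn[i], envir = layer)
    if (is.null(g)) next
    p <- get(pn[i], envir = layer) - lr * g * scale
    if (l2 > 0 && pn[i] == "W") p <- p - lr * l2 * p
    assign(pn[i], p, envir = layer)
  }
  invisible(layer)
}

#' Mean test DSC of a trained model over held-out pairs
#'
#' @param model Trained `ms_model`.
#' @param pairs List of normalized image/mask pairs.
#' @param threshold Probability threshold.
#' @return Mean Dice similarity coefficient.
#' @export
evaluate_model <- function(model, pairs, threshold = 0.5) {
  mean(vapply(pairs, function(p) {
    pr <- predict_prob(model, p$image)
    compute_metrics(predict_mask(pr, threshold), p$mask)$dsc
  }, 0))
}
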