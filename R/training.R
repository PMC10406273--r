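#' Training configuration
#'
#' Mean-squared-error regression with the Adam optimizer, a step learning-rate
#' schedule (multiply by `lr_gamma` every `lr_step` epochs) and early stopping
#' on validation loss. The defaults mirror the published training recipe
#' (learning rate 1e-5, step size 5, up to 200 epochs, batch size 5,
#' per-volume min-max normalization); small synthetic fixtures converge much
#' faster with a larger learning rate and fewer epochs.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param lr_step Epochs between learning-rate decays.
#' @param lr_gamma Decay factor in (0, 1]; `1` disables decay.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement, >= 1).
#' @param min_delta Minimum validation-loss improvement that resets patience.
#' @param batch_size Samples per optimization step.
#' @param seed Seed for shuffling, dropout and weight initialization.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-5, lr_step = 5L, lr_gamma = 0.9,
                         max_epochs = 200L, patience = 10L, min_delta = 0,
                         batch_size = 5L, seed = 1L) {
  stopifnot(learning_rate > 0, lr_gamma > 0, lr_gamma <= 1, patience >= 1,
            is_count(max_epochs), is_count(batch_size), is_count(lr_step),
            min_delta >= 0)
  structure(list(loss = "mse", optimizer = "adam",
                 learning_rate = learning_rate, lr_step = as.integer(lr_step),
                 lr_gamma = lr_gamma, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 batch_size = as.integer(batch_size),
                 normalization = "minmax", seed = as.integer(seed)),
            class = "train_config")
}

#' Min-max normalization of a volume
#'
#' Affinely maps a volume onto `[0, 1]` as `(v - min) / (max - min)`.
#' A constant volume (zero range) maps to all zeros. The map is monotone, so
#' voxel ordering is preserved.
#'
#' @param volume Numeric array with finite values.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(volume) {
  assert_finite(volume, "volume")
  r <- range(volume)
  if (r[1] == r[2]) return(array(0, dim = dim(volume) %||% length(volume)))
  (volume - r[1]) / (r[2] - r[1])
}

#' Build train/validation volume datasets for one network
#'
#' Converts a synthetic study into supervised volume samples for one
#' network: every (subject, timepoint) pair yields one sample whose input is
#' the min-max-normalized fMRI volume at that timepoint and whose target is
#' the network's ground-truth score volume. The split is by subject — never
#' by timepoint — so no subject leaks between train and validation.
#'
#' @param study A [simulate_study()] result (with volumes and truth maps).
#' @param network_id Which network's maps to use as targets.
#' @param val_fraction Fraction of subjects held out for validation.
#' @param seed Seed for the subject shuffle.
#' @param subjects Optional subset of subject ids to use.
#' @return List with elements `train` and `val` (lists of samples, each
#'   `list(input, target)`), plus the subject ids in each split.
#' @export
make_volume_dataset <- function(study, network_id, val_fraction = 1 / 3,
                                seed = 1L, subjects = NULL) {
  stopifnot(inherits(study, "synth_study"))
  subs <- study$subjects
  if (!is.null(subjects)) {
    subs <- subs[vapply(subs, function(s) s$subject_id %in% subjects, logical(1))]
  }
  if (length(subs) < 2) abort("need at least 2 subjects to split train/validation")
  ord <- with_seed(seed, sample.int(length(subs)))
  n_val <- max(1L, round(val_fraction * length(subs)))
  if (n_val >= length(subs)) abort("empty training split")
  val_idx <- ord[seq_len(n_val)]
  train_idx <- ord[-seq_len(n_val)]

  samples_of <- function(idx) {
    purrr::flatten(lapply(subs[idx], function(s) {
      if (is.null(s$truth$score_maps[[network_id]])) {
        abort(sprintf("no ground-truth map for network %s", network_id))
      }
      T <- dim(s$volume)[4]
      lapply(seq_len(T), function(t) {
        list(input = minmax_normalize(s$volume[, , , t]),
             target = s$truth$score_maps[[network_id]][, , , t])
      })
    }))
  }
  list(train = samples_of(train_idx), val = samples_of(val_idx),
       train_subjects = vapply(subs[train_idx], `[[`, "", "subject_id"),
       val_subjects = vapply(subs[val_idx], `[[`, "", "subject_id"))
}

stack_samples <- function(samples, field) {
  d <- dim(samples[[1]][[field]])
  array(unlist(lapply(samples, `[[`, field), use.names = FALSE),
        dim = c(d, 1L, length(samples)))
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train one parcellation model
#'
#' Minimizes voxel-wise mean squared error with Adam, decaying the learning
#' rate by `lr_gamma` every `lr_step` epochs, and stops early when the
#' validation loss has not improved by more than `min_delta` for `patience`
#' epochs. The returned model carries the parameters of the best validation
#' epoch (not the last one) and a per-epoch loss history.
#'
#' @param model A [build_model()] result.
#' @param data A [make_volume_dataset()] result (non-empty `train` and `val`).
#' @param cfg A [train_config()].
#' @return The trained `parc_model`; `attr(, "history")` holds a tibble with
#'   columns `epoch`, `train_mse`, `val_mse`, `lr`.
#' @export
train_model <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "parc_model"), inherits(cfg, "train_config"))
  if (length(data$train) == 0 || length(data$val) == 0) {
    abort("train and validation sets must be non-empty")
  }
  opt <- list(t = 0L,
              m = lapply(model$params, function(p) array(0, dim = dim(p) %||% length(p))),
              v = lapply(model$params, function(p) array(0, dim = dim(p) %||% length(p))))
  history <- vector("list", cfg$max_epochs)
  best_val <- Inf
  best_params <- model$params
  best_state <- model$state
  wait <- 0L

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- cfg$learning_rate * cfg$lr_gamma^((epoch - 1L) %/% cfg$lr_step)
      ord <- sample.int(length(data$train))
      epoch_loss <- 0
      n_seen <- 0L
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        x <- stack_samples(data$train[idx], "input")
        y <- stack_samples(data$train[idx], "target")
        fw <- nn_forward(model, x, training = TRUE)
        model$state <- fw$state
        resid <- fw$out - y
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged to non-finite loss at epoch %d", epoch))
        }
        grads <- nn_backward(model, fw$cache, 2 * resid / length(resid))
        upd <- adam_step(model$params, grads, opt, lr)
        model$params <- upd$params
        opt <- upd$opt
        epoch_loss <- epoch_loss + loss * length(idx)
        n_seen <- n_seen + length(idx)
      }
      train_mse <- epoch_loss / n_seen
      val_mse <- evaluate_mse(model, data$val, batch_size = cfg$batch_size)
      history[[epoch]] <- tibble(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse, lr = lr)
      if (val_mse < best_val - cfg$min_delta) {
        best_val <- val_mse
        best_params <- model$params
        best_state <- model$state
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  model$params <- best_params
  model$state <- best_state
  # refresh batch-norm running statistics for the returned weights
  model <- with_seed(cfg$seed + 1L, recalibrate_bn(model, data$train,
                                                   cfg$batch_size))
  hist <- dplyr::bind_rows(history)
  class(hist) <- c("train_history", class(hist))
  attr(model, "history") <- hist
  model
}

#' Mean squared error of a model on a dataset
#'
#' Evaluation-mode mean over all samples and voxels of the squared
#' difference between predicted and target volumes.
#'
#' @param model A `parc_model`.
#' @param dataset Non-empty list of samples (`list(input, target)`).
#' @param batch_size Samples per forward pass.
#' @return A nonnegative scalar.
#' @export
evaluate_mse <- function(model, dataset, batch_size = 5L) {
  stopifnot(length(dataset) >= 1)
  total <- 0
  n <- 0
  for (start in seq(1, length(dataset), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(dataset))
    x <- stack_samples(dataset[idx], "input")
    y <- stack_samples(dataset[idx], "target")
    out <- nn_forward(model, x, training = FALSE)$out
    total <- total + sum((out - y)^2)
    n <- n + length(y)
  }
  total / n
}

#' Save / load a model checkpoint with a JSON sidecar
#'
#' The checkpoint stores the weights in R's native serialized format; the
#' sidecar records the spec, input dims and network id as JSON.
#'
#' @param model A `parc_model`.
#' @param path Checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  side <- list(network_id = model$network_id, input_dims = model$input_dims,
               spec = unclass(model$spec))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' @export
#' @method autoplot train_history
autoplot.train_history <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("train_mse", "val_mse"),
                              names_to = "split", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error", colour = NULL) +
    ggplot2::theme_minimal()
}
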