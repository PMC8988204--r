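# Training protocol: Adam on the weighted MAE loss, minibatches, dropout,
# validation-loss early stopping with best-weight restoration. Fully
# deterministic given the seed.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Maximum epochs (default 500).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 20).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A list of class `cropmtl_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32,
                         max_epochs = 500, early_stop_patience = 20,
                         seed = 1) {
  if (learning_rate <= 0) {
    stop2("learning_rate must be positive", "cropmtl_invalid_argument")
  }
  batch_size <- assert_count(batch_size, "batch_size")
  max_epochs <- assert_count(max_epochs, "max_epochs")
  early_stop_patience <- assert_count(early_stop_patience,
                                      "early_stop_patience")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "cropmtl_train_config")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- param_map2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  list(params = param_map2(params, upd, `-`), state = state)
}

gather_truth <- function(spec, dataset, idx) {
  tg <- dataset$targets
  out <- list()
  if ("yield" %in% spec$targets) out$yield <- tg$yield_norm[idx]
  if ("gpc" %in% spec$targets) out$gpc <- tg$gpc_norm[idx]
  out
}

#' Train a model on a prepared dataset
#'
#' Minimizes the (weighted, for two-output topologies) mean absolute error
#' on the normalized targets over the training split with Adam, monitors the
#' validation loss each epoch, stops once the validation loss has not
#' improved for `early_stop_patience` epochs, and restores the weights of
#' the best validation epoch.
#'
#' @param spec A [model_spec()] (or an untrained [build_model()] result).
#' @param dataset A split `cropmtl_dataset` whose traits cover the spec's
#'   `input_traits`.
#' @param config A [train_config()].
#' @return A `cropmtl_model` with `trained = TRUE`, `history` (tibble:
#'   epoch, train_loss, val_loss), `best_epoch`, `norm_params`, and the
#'   training seed.
#' @export
train_model <- function(spec, dataset, config = train_config()) {
  model <- if (inherits(spec, "cropmtl_model")) spec else {
    build_model(spec, seed = config$seed)
  }
  sp <- model$spec
  if (is.null(dataset$splits) || length(dataset$splits$train) == 0 ||
      length(dataset$splits$val) == 0) {
    stop2("dataset needs nonempty train and val splits",
          "cropmtl_configuration")
  }
  train_idx <- dataset$splits$train
  val_idx <- dataset$splits$val
  Xtr <- dataset_inputs(dataset, sp$input_traits, train_idx)
  ytr <- gather_truth(sp, dataset, train_idx)
  Xval <- dataset_inputs(dataset, sp$input_traits, val_idx)
  yval <- gather_truth(sp, dataset, val_idx)
  n <- length(train_idx)
  bs <- min(config$batch_size, n)
  zeros <- param_map(model$params, function(m) m * 0)
  state <- list(m = zeros, v = zeros)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- model$params
  best_epoch <- 0L
  wait <- 0L
  t_adam <- 0
  with_seed(derive_seed(config$seed, 61), {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = bs)
      ep_loss <- 0
      ep_n <- 0
      for (s in starts) {
        bidx <- perm[s:min(s + bs - 1, n)]
        Xb <- lapply(Xtr, function(X) X[bidx, , drop = FALSE])
        yb <- lapply(ytr, function(y) y[bidx])
        fw <- model_forward(model, Xb, training = TRUE)
        lg <- batch_loss_and_grad(sp, fw$pred, yb)
        if (!is.finite(lg$loss)) {
          stop2(sprintf("training diverged (non-finite loss) at epoch %d",
                        epoch), "cropmtl_divergence")
        }
        grads <- model_backward(model, fw$cache, lg$dpred)
        t_adam <- t_adam + 1
        st <- adam_step(model$params, grads, state, config$learning_rate,
                        t_adam)
        model$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + lg$loss * length(bidx)
        ep_n <- ep_n + length(bidx)
      }
      vf <- model_forward(model, Xval, training = FALSE)
      vl <- batch_loss_and_grad(sp, vf$pred, yval)$loss
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = ep_loss / ep_n,
                                  val_loss = vl))
      if (vl < best_val - 1e-12) {
        best_val <- vl
        best_params <- model$params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
  })
  model$params <- best_params
  model$trained <- TRUE
  model$history <- tibble::as_tibble(history)
  model$best_epoch <- best_epoch
  model$norm_params <- dataset$norm_params
  model$train_seed <- config$seed
  model
}

#' Predict from a trained model
#'
#' @param object A trained `cropmtl_model`.
#' @param dataset A `cropmtl_dataset`.
#' @param split `"train"`, `"val"`, `"test"` (default) or an index vector.
#' @param denormalize Return predictions on the raw target scale (default
#'   `TRUE`); requires the norm params stored at training time.
#' @param ... Unused.
#' @return A tibble with `id` and one `pred_<target>` column per head.
#' @export
predict.cropmtl_model <- function(object, dataset, split = "test",
                                  denormalize = TRUE, ...) {
  idx <- dataset_split_idx(dataset, split)
  X <- dataset_inputs(dataset, object$spec$input_traits, idx)
  fw <- model_forward(object, X, training = FALSE)
  out <- tibble::tibble(id = dataset$targets$id[idx])
  for (tg in object$spec$targets) {
    v <- fw$pred[[tg]]
    if (denormalize) {
      np <- object$norm_params %||% dataset$norm_params
      if (is.null(np)) {
        stop2("no normalization parameters available to denormalize",
              "cropmtl_configuration")
      }
      v <- denormalize_targets(v, np[[tg]])
    }
    out[[paste0("pred_", tg)]] <- v
  }
  out
}
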