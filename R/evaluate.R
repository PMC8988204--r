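# Evaluation metrics and the model-comparison matrix.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. May be negative for
#' predictors worse than the mean.
#'
#' @param y_true,y_pred Numeric vectors of equal length (n >= 2); `y_true`
#'   must not be constant.
#' @return The scalar R-squared.
#' @export
r_squared <- function(y_true, y_pred) {
  check_metric_args(y_true, y_pred, min_n = 2)
  denom <- sum((y_true - mean(y_true))^2)
  if (denom == 0) {
    stop2("y_true is constant; R-squared is undefined",
          "cropmtl_undefined_denominator")
  }
  1 - sum((y_true - y_pred)^2) / denom
}

#' Root mean squared error and relative RMSE
#'
#' `rmse = sqrt(mean((y - yhat)^2))`; `rrmse = rmse / mean(y) * 100` (in
#' percent; requires a nonzero observed mean).
#'
#' @param y_true,y_pred Numeric vectors of equal length (n >= 1).
#' @return The scalar metric (`rrmse` in percent).
#' @export
rmse <- function(y_true, y_pred) {
  check_metric_args(y_true, y_pred, min_n = 1)
  sqrt(mean((y_true - y_pred)^2))
}

#' @rdname rmse
#' @export
rrmse <- function(y_true, y_pred) {
  check_metric_args(y_true, y_pred, min_n = 1)
  ybar <- mean(y_true)
  if (ybar == 0) {
    stop2("mean of y_true is zero; rRMSE is undefined",
          "cropmtl_undefined_denominator")
  }
  rmse(y_true, y_pred) / ybar * 100
}

check_metric_args <- function(y_true, y_pred, min_n) {
  if (length(y_true) != length(y_pred)) {
    stop2("y_true and y_pred must have equal lengths",
          "cropmtl_invalid_argument")
  }
  if (length(y_true) < min_n) {
    stop2(sprintf("at least %d observations are required", min_n),
          "cropmtl_invalid_argument")
  }
  invisible(TRUE)
}

#' Evaluate a trained model on a dataset split
#'
#' Predictions are denormalized to the raw target scale (kg/ha for yield,
#' percent for GPC) before computing metrics, as are the (possibly
#' perturbed) normalized targets of augmented examples.
#'
#' @param model A trained `cropmtl_model`.
#' @param dataset A split `cropmtl_dataset`.
#' @param split Split name or index vector (default `"test"`).
#' @return A tibble with one row per target: `target`, `r_squared`, `rmse`,
#'   `rrmse`, `n`, `split`.
#' @export
evaluate_model <- function(model, dataset, split = "test") {
  idx <- dataset_split_idx(dataset, split)
  if (length(idx) < 2) {
    stop2("evaluation split needs at least 2 examples",
          "cropmtl_invalid_argument")
  }
  np <- model$norm_params %||% dataset$norm_params
  if (is.null(np)) {
    stop2("no normalization parameters available", "cropmtl_configuration")
  }
  preds <- predict(model, dataset, split = idx, denormalize = TRUE)
  rows <- lapply(model$spec$targets, function(tg) {
    truth_norm <- if (tg == "yield") dataset$targets$yield_norm[idx] else
      dataset$targets$gpc_norm[idx]
    truth <- denormalize_targets(truth_norm, np[[tg]])
    yhat <- preds[[paste0("pred_", tg)]]
    tibble::tibble(target = tg,
                   r_squared = r_squared(truth, yhat),
                   rmse = rmse(truth, yhat),
                   rrmse = rrmse(truth, yhat),
                   n = length(idx),
                   split = if (is.character(split)) split else "custom")
  })
  do.call(rbind, rows)
}

#' Train and compare a list of model configurations
#'
#' Trains every configuration `n_seeds` times (seeds derived from
#' `base_seed`), evaluates on the test split, and reports per-target mean
#' and sd of each metric plus a per-target rank by mean R-squared.
#'
#' @param specs A list of [model_spec()]s.
#' @param dataset A split `cropmtl_dataset`.
#' @param n_seeds Training replicates per configuration (default 5).
#' @param config A [train_config()] template (its seed field is replaced per
#'   replicate).
#' @param base_seed Seed from which replicate seeds are derived.
#' @return A tibble with one row per (configuration, target): topology,
#'   extractor, inputs, loss weights, mean/sd metrics over seeds, and rank.
#' @export
compare_models <- function(specs, dataset, n_seeds = 5,
                           config = train_config(), base_seed = 1) {
  rows <- list()
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    per_seed <- vector("list", n_seeds)
    err <- NA_character_
    for (si in seq_len(n_seeds)) {
      cfg <- config
      # replicate seeds depend only on (base_seed, replicate), so identical
      # specs produce identical rows and all configs see the same seeds
      cfg$seed <- derive_seed(base_seed, si)
      res <- tryCatch(
        evaluate_model(train_model(sp, dataset, cfg), dataset, "test"),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        err <- conditionMessage(res)
        break
      }
      per_seed[[si]] <- res
    }
    for (tg in sp$targets) {
      if (!is.na(err)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          config = ci, topology = sp$topology, extractor = sp$extractor,
          inputs = paste(sp$input_traits, collapse = "+"), target = tg,
          lambda_gpc = unname(sp$loss_weights["gpc"]),
          lambda_yield = unname(sp$loss_weights["yield"]),
          n_seeds = 0L, r_squared = NA_real_, r_squared_sd = NA_real_,
          rmse = NA_real_, rmse_sd = NA_real_,
          rrmse = NA_real_, rrmse_sd = NA_real_, error = err
        )
        next
      }
      m <- do.call(rbind, lapply(per_seed, function(r) r[r$target == tg, ]))
      sdv <- function(x) if (length(x) > 1) stats::sd(x) else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        config = ci, topology = sp$topology, extractor = sp$extractor,
        inputs = paste(sp$input_traits, collapse = "+"), target = tg,
        lambda_gpc = unname(sp$loss_weights["gpc"]),
        lambda_yield = unname(sp$loss_weights["yield"]),
        n_seeds = as.integer(n_seeds),
        r_squared = mean(m$r_squared), r_squared_sd = sdv(m$r_squared),
        rmse = mean(m$rmse), rmse_sd = sdv(m$rmse),
        rrmse = mean(m$rrmse), rrmse_sd = sdv(m$rrmse),
        error = NA_character_
      )
    }
  }
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  for (tg in unique(out$target)) {
    sel <- which(out$target == tg & !is.na(out$r_squared))
    out$rank[sel] <- as.integer(rank(-out$r_squared[sel],
                                     ties.method = "first"))
  }
  out
}
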