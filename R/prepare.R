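# Dataset preparation: vectorization over the 89-day window, linear
# interpolation of missing days, target min-max normalization, time-series
# augmentation (jitter / scale / resample) with target perturbation, and a
# random train/validation/test split.

#' Place a trait series on the fixed 89-day grid
#'
#' @param series Tibble/data.frame with columns `das` (integers in 107..195)
#'   and `value`.
#' @return A list with `values` (numeric length 89, `NA` where unobserved)
#'   and `mask` (logical length 89, `TRUE` where observed).
#' @export
vectorize_series <- function(series) {
  das <- das_window()
  if (any(!series$das %in% das)) {
    stop2(sprintf("observation outside the DAS window [107, 195]: %s",
                  paste(utils::head(setdiff(series$das, das), 5),
                        collapse = ", ")),
          "cropmtl_invalid_argument")
  }
  values <- rep(NA_real_, length(das))
  idx <- match(series$das, das)
  values[idx] <- series$value
  list(values = values, mask = !is.na(values))
}

#' Fill missing entries of a feature vector by linear interpolation
#'
#' Interior gaps are filled by piecewise-linear interpolation between the
#' nearest observed neighbors; leading/trailing gaps take the nearest
#' observed value (constant extrapolation). Observed entries are unchanged
#' and the operation is idempotent.
#'
#' @param values Numeric vector of length 89 with `NA` at unobserved days,
#'   or the list returned by [vectorize_series()].
#' @return Numeric vector of length 89 with no missing entries.
#' @export
interpolate_missing <- function(values) {
  if (is.list(values)) values <- values$values
  obs <- which(!is.na(values))
  if (length(obs) < 2) {
    stop2("at least 2 observed entries are required for interpolation",
          "cropmtl_insufficient_data")
  }
  out <- stats::approx(obs, values[obs], xout = seq_along(values),
                       method = "linear", rule = 2)$y
  out[obs] <- values[obs]
  out
}

#' Min-max normalize targets
#'
#' `x' = (x - min)/(max - min)` with min/max taken over the supplied values
#' (in the pipeline: over original, non-augmented examples only).
#'
#' @param x Numeric vector.
#' @param params Optional `c(min, max)`; computed from `x` when `NULL`.
#' @return For `normalize_targets()`: list(`values`, `params`). For
#'   `denormalize_targets()`: the raw-scale values.
#' @export
normalize_targets <- function(x, params = NULL) {
  if (is.null(params)) {
    if (length(unique(x)) < 2) {
      stop2("target is constant; min-max range is degenerate",
            "cropmtl_degenerate_range")
    }
    params <- c(min = min(x), max = max(x))
  }
  list(values = (x - params[["min"]]) / (params[["max"]] - params[["min"]]),
       params = params)
}

#' @rdname normalize_targets
#' @export
denormalize_targets <- function(x, params) {
  x * (params[["max"]] - params[["min"]]) + params[["min"]]
}

#' Build a prepared dataset from a trial
#'
#' Vectorizes and interpolates every trait series onto the 89-day grid,
#' min-max normalizes yield and GPC over the original plots, optionally
#' min-max scales each trait's features (over original plots) for stable
#' optimization, augments to `augment_to` examples, and splits
#' train/validation/test.
#'
#' @param trial A `cropmtl_trial` (or list with `plots`, `traits`).
#' @param augment_to Total example count after augmentation (default 1000;
#'   set to the number of plots for no augmentation).
#' @param methods Augmentation methods, subset of
#'   `c("jitter", "scale", "resample")`.
#' @param ratios Train/validation/test fractions (must sum to 1).
#' @param seed Integer seed controlling augmentation and the split.
#' @param scale_features Min-max scale each trait over original plots
#'   (default `TRUE`).
#' @param augment_config See [augment_dataset()].
#' @return A list of class `cropmtl_dataset`: `features` (array n x traits
#'   x 89), `targets` (tibble: id, plot_id, yield, gpc, yield_norm,
#'   gpc_norm, provenance, source_id), `norm_params`, `feature_params`,
#'   `splits` (list of index vectors), `traits`, `das`.
#' @export
prepare_dataset <- function(trial, augment_to = 1000,
                            methods = c("jitter", "scale", "resample"),
                            ratios = c(0.8, 0.1, 0.1), seed = 1,
                            scale_features = TRUE,
                            augment_config = list()) {
  plots <- trial$plots
  traits_long <- trial$traits
  traits <- sort(unique(traits_long$trait))
  # keep canonical order when the standard traits are present
  canon <- trait_names()
  if (all(traits %in% canon)) traits <- canon[canon %in% traits]
  das <- das_window()
  n <- nrow(plots)
  feats <- array(NA_real_, dim = c(n, length(traits), length(das)),
                 dimnames = list(NULL, traits, paste0("das", das)))
  for (i in seq_len(n)) {
    sub <- traits_long[traits_long$plot_id == plots$plot_id[i], ]
    for (j in seq_along(traits)) {
      sr <- sub[sub$trait == traits[j], c("das", "value")]
      vec <- vectorize_series(sr)
      feats[i, j, ] <- interpolate_missing(vec)
    }
  }
  yn <- normalize_targets(plots$yield)
  gn <- normalize_targets(plots$gpc)
  feature_params <- NULL
  if (scale_features) {
    feature_params <- lapply(seq_along(traits), function(j) {
      v <- feats[, j, ]
      rng <- range(v)
      if (diff(rng) == 0) rng <- rng + c(0, 1)   # constant trait: leave at 0
      c(min = rng[1], max = rng[2])
    })
    names(feature_params) <- traits
    for (j in seq_along(traits)) {
      p <- feature_params[[j]]
      feats[, j, ] <- (feats[, j, ] - p["min"]) / (p["max"] - p["min"])
    }
  }
  targets <- tibble::tibble(
    id = seq_len(n),
    plot_id = plots$plot_id,
    yield = plots$yield,
    gpc = plots$gpc,
    yield_norm = yn$values,
    gpc_norm = gn$values,
    provenance = "original",
    source_id = seq_len(n)
  )
  ds <- structure(list(
    features = feats, targets = targets,
    norm_params = list(yield = yn$params, gpc = gn$params),
    feature_params = feature_params,
    splits = NULL, traits = traits, das = das
  ), class = "cropmtl_dataset")
  ds <- do.call(augment_dataset,
                c(list(dataset = ds, target_count = augment_to,
                       methods = methods, seed = derive_seed(seed, 37)),
                  augment_config))
  split_dataset(ds, ratios, seed = derive_seed(seed, 41))
}

#' Augment a prepared dataset to a target size
#'
#' Repeatedly picks a random original example and one random method:
#' * `jitter`: adds Gaussian noise with sd = `jitter_frac` times the
#'   per-trait standard deviation of that example's own vector;
#' * `scale`: multiplies the whole traits x days matrix by
#'   `s ~ Uniform(scale_range)`;
#' * `resample`: keeps a random `resample_frac` of days (the same days for
#'   all traits) and re-interpolates.
#'
#' Both normalized targets are then perturbed by a truncated
#' `Normal(0, target_sd)` on `[-target_bound, target_bound]` (or, with
#' `uniform_target_noise = TRUE`, `Uniform(-target_bound, target_bound)`).
#' Augmented examples are appended (originals unchanged) and flagged in
#' `targets$provenance`; deterministic given the seed.
#'
#' @param dataset A `cropmtl_dataset`.
#' @param target_count Final example count (must be >= current size).
#' @param methods Nonempty subset of `c("jitter","scale","resample")`.
#' @param seed Integer seed.
#' @param jitter_frac,scale_range,resample_frac,target_sd,target_bound,uniform_target_noise
#'   Augmentation hyperparameters (defaults 0.03, c(0.9, 1.1), 0.6, 0.05/3,
#'   0.05, FALSE).
#' @return The augmented `cropmtl_dataset` (splits cleared).
#' @export
augment_dataset <- function(dataset, target_count,
                            methods = c("jitter", "scale", "resample"),
                            seed = 1, jitter_frac = 0.03,
                            scale_range = c(0.9, 1.1), resample_frac = 0.6,
                            target_sd = 0.05 / 3, target_bound = 0.05,
                            uniform_target_noise = FALSE) {
  n <- nrow(dataset$targets)
  target_count <- assert_count(target_count, "target_count")
  if (target_count < n) {
    stop2(sprintf("target_count (%d) is below the current size (%d)",
                  target_count, n), "cropmtl_invalid_argument")
  }
  methods <- match.arg(methods, c("jitter", "scale", "resample"),
                       several.ok = TRUE)
  n_new <- target_count - n
  if (n_new == 0) return(dataset)
  orig_idx <- which(dataset$targets$provenance == "original")
  n_traits <- length(dataset$traits)
  n_days <- length(dataset$das)
  new_feats <- array(NA_real_, dim = c(n_new, n_traits, n_days))
  new_rows <- vector("list", n_new)
  with_seed(derive_seed(seed, 43), {
    for (k in seq_len(n_new)) {
      src <- sample(orig_idx, 1)
      m <- if (length(methods) == 1) methods else sample(methods, 1)
      x <- dataset$features[src, , , drop = TRUE]
      if (n_traits == 1) x <- matrix(x, nrow = 1)
      if (m == "jitter") {
        for (j in seq_len(n_traits)) {
          x[j, ] <- x[j, ] + rnorm(n_days, 0, jitter_frac * stats::sd(x[j, ]))
        }
      } else if (m == "scale") {
        x <- x * runif(1, scale_range[1], scale_range[2])
      } else {
        keep <- sort(sample(n_days, max(2, round(resample_frac * n_days))))
        for (j in seq_len(n_traits)) {
          v <- rep(NA_real_, n_days)
          v[keep] <- x[j, keep]
          x[j, ] <- interpolate_missing(v)
        }
      }
      delta <- if (uniform_target_noise) {
        runif(2, -target_bound, target_bound)
      } else {
        rtruncnorm(2, sd = target_sd, bound = target_bound)
      }
      new_feats[k, , ] <- x
      tg <- dataset$targets[src, ]
      new_rows[[k]] <- tibble::tibble(
        id = n + k,
        plot_id = tg$plot_id,
        yield = denormalize_targets(tg$yield_norm + delta[1],
                                    dataset$norm_params$yield),
        gpc = denormalize_targets(tg$gpc_norm + delta[2],
                                  dataset$norm_params$gpc),
        yield_norm = tg$yield_norm + delta[1],
        gpc_norm = tg$gpc_norm + delta[2],
        provenance = "augmented",
        source_id = tg$id
      )
    }
  })
  feats <- array(NA_real_, dim = c(target_count, n_traits, n_days),
                 dimnames = dimnames(dataset$features))
  feats[seq_len(n), , ] <- dataset$features
  feats[n + seq_len(n_new), , ] <- new_feats
  dataset$features <- feats
  dataset$targets <- rbind(dataset$targets, do.call(rbind, new_rows))
  dataset$splits <- NULL
  dataset
}

#' Randomly split a dataset into train/validation/test
#'
#' Sizes are floor allocations of the ratios with the remainder assigned to
#' the training split; assignment is a seeded random permutation, disjoint
#' and exhaustive.
#'
#' @param dataset A `cropmtl_dataset`.
#' @param ratios Length-3 positive fractions summing to 1 (within 1e-9).
#' @param seed Integer seed.
#' @return The dataset with `splits = list(train=, val=, test=)`.
#' @export
split_dataset <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    stop2("ratios must be 3 positive fractions summing to 1",
          "cropmtl_invalid_argument")
  }
  n <- nrow(dataset$targets)
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  n_train <- n - n_val - n_test
  perm <- with_seed(derive_seed(seed, 47), sample.int(n))
  dataset$splits <- list(
    train = sort(perm[seq_len(n_train)]),
    val = sort(perm[n_train + seq_len(n_val)]),
    test = sort(perm[n_train + n_val + seq_len(n_test)])
  )
  dataset
}

# Extract the n x 89 input matrix of one trait for given example indices.
dataset_inputs <- function(dataset, traits, idx) {
  lapply(traits, function(tr) {
    if (!tr %in% dataset$traits) {
      stop2(sprintf("trait '%s' is not in the dataset (has: %s)", tr,
                    paste(dataset$traits, collapse = ", ")),
            "cropmtl_configuration")
    }
    m <- dataset$features[idx, tr, , drop = FALSE]
    matrix(m, nrow = length(idx), ncol = length(dataset$das))
  })
}

dataset_split_idx <- function(dataset, split) {
  if (is.numeric(split)) return(as.integer(split))
  if (is.null(dataset$splits)) {
    stop2("dataset has no splits; call split_dataset() first",
          "cropmtl_configuration")
  }
  idx <- dataset$splits[[split]]
  if (is.null(idx)) {
    stop2(sprintf("unknown split '%s'", split), "cropmtl_invalid_argument")
  }
  idx
}
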