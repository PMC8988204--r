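# Shared helpers for the cropmtl test suite.

# A small trial / prepared dataset, built once and reused across tests.
.cache <- new.env(parent = emptyenv())

tiny_trial <- function() {
  if (is.null(.cache$trial)) {
    .cache$trial <- simulate_trial(n_varieties = 3, n_nitrogen = 2,
                                   n_reps = 2, seed = 42)
  }
  .cache$trial
}

tiny_dataset <- function() {
  if (is.null(.cache$dataset)) {
    .cache$dataset <- prepare_dataset(tiny_trial(), augment_to = 30,
                                      seed = 42)
  }
  .cache$dataset
}

# A deterministic mid-size noiseless trial for training smoke tests.
noiseless_dataset <- function() {
  if (is.null(.cache$noiseless)) {
    cfg <- generator_config(noise_sd = 0, sigma_yield = 0, sigma_gpc = 0)
    trial <- simulate_trial(n_varieties = 30, n_nitrogen = 2, n_reps = 2,
                            config = cfg, seed = 7)
    .cache$noiseless <- prepare_dataset(trial, augment_to = 120, seed = 7)
  }
  .cache$noiseless
}

# Point-cloud construction shorthand.
make_cloud <- function(x, y, z, b = 0.1, g = 0.3, r = 0.2, nir = 0.6) {
  n <- max(lengths(list(x, y, z)))
  tibble::tibble(x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
                 b = rep_len(b, n), g = rep_len(g, n), r = rep_len(r, n),
                 nir = rep_len(nir, n))
}

# Independent brute-force scalar metric implementations (plain loops).
oracle_r_squared <- function(y, yhat) {
  ybar <- 0
  for (v in y) ybar <- ybar + v
  ybar <- ybar / length(y)
  num <- 0
  den <- 0
  for (i in seq_along(y)) {
    num <- num + (y[i] - yhat[i])^2
    den <- den + (y[i] - ybar)^2
  }
  1 - num / den
}

oracle_rmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}

oracle_rrmse <- function(y, yhat) {
  ybar <- 0
  for (v in y) ybar <- ybar + v
  oracle_rmse(y, yhat) / (ybar / length(y)) * 100
}

# Scalar piecewise-linear interpolation oracle: interior gaps linear
# between nearest observed neighbors, leading/trailing gaps constant.
oracle_interpolate <- function(values) {
  obs <- which(!is.na(values))
  out <- values
  for (i in seq_along(values)) {
    if (!is.na(values[i])) next
    lo <- obs[obs < i]
    hi <- obs[obs > i]
    if (length(lo) == 0) {
      out[i] <- values[min(hi)]
    } else if (length(hi) == 0) {
      out[i] <- values[max(lo)]
    } else {
      l <- max(lo)
      h <- min(hi)
      w <- (i - l) / (h - l)
      out[i] <- (1 - w) * values[l] + w * values[h]
    }
  }
  out
}

# Brute-force structural traits on small clouds.
oracle_structural <- function(cloud, grid_cell = 5, voxel = 10) {
  z <- sort(cloud$z)
  n <- length(z)
  # type-7 sample quantile: h = (n - 1) p + 1, linear interpolation
  h <- (n - 1) * 0.99 + 1
  fl <- floor(h)
  q99 <- z[fl] + (h - fl) * (z[min(fl + 1, n)] - z[fl])
  cells <- unique(paste(floor(cloud$x / grid_cell),
                        floor(cloud$y / grid_cell)))
  vox <- unique(paste(floor(cloud$x / voxel), floor(cloud$y / voxel),
                      floor(cloud$z / voxel)))
  c(Hmean = sum(cloud$z) / n, H99 = q99,
    PLA = length(cells) * grid_cell^2 * 1e-6,
    Volume = length(vox) * voxel^3 * 1e-9)
}

oracle_spectral <- function(cloud) {
  acc <- c(GNDVI = 0, CVI = 0, NCPI = 0, MCARI = 0)
  for (i in seq_len(nrow(cloud))) {
    b <- cloud$b[i]; g <- cloud$g[i]; r <- cloud$r[i]; nir <- cloud$nir[i]
    acc <- acc + c(GNDVI = (nir - g) / (nir + g),
                   CVI = (nir / g) * (r / g),
                   NCPI = (r - b) / (r + b),
                   MCARI = ((nir - r) - 0.2 * (nir - g)) * (nir / r))
  }
  acc / nrow(cloud)
}

# Numerical gradient check on a random sample of parameter coordinates.
# Perturbs all parameters away from exact ReLU kinks first (analytic
# subgradients at pre-activation 0 legitimately disagree with central
# differences there).
gradient_check <- function(spec, n = 3, n_coords = 4, seed = 1, eps = 1e-5) {
  model <- build_model(spec, seed = seed)
  model$params <- cropmtl:::param_map(model$params, function(x) {
    x + 0.1 * rnorm(length(x))
  })
  X <- lapply(seq_along(spec$input_traits), function(i) {
    matrix(rnorm(n * spec$input_length), n, spec$input_length)
  })
  # keep every |residual| >= 0.2: at an MAE kink (residual 0) central
  # differences are stably wrong (symmetric V), so bound residuals away
  fw0 <- cropmtl:::model_forward(model, X, training = FALSE)
  truth <- lapply(spec$targets, function(tg) {
    fw0$pred[[tg]] - sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.2, 1)
  })
  names(truth) <- spec$targets
  loss_at <- function(params) {
    m <- model
    m$params <- params
    fw <- cropmtl:::model_forward(m, X, training = FALSE)
    cropmtl:::batch_loss_and_grad(spec, fw$pred, truth)$loss
  }
  fw <- cropmtl:::model_forward(model, X, training = FALSE)
  lg <- cropmtl:::batch_loss_and_grad(spec, fw$pred, truth)
  grads <- cropmtl:::model_backward(model, fw$cache, lg$dpred)

  # enumerate numeric leaves of the parameter tree by positional path
  # (grads mirrors params structurally)
  leaves <- list()
  walk <- function(x, path) {
    if (is.numeric(x)) {
      leaves[[length(leaves) + 1]] <<- path
    } else if (is.list(x)) {
      for (i in seq_along(x)) walk(x[[i]], c(path, i))
    }
  }
  walk(model$params, integer(0))

  numeric_grad <- function(path, ci, h) {
    pp <- model$params
    pm <- model$params
    pp[[path]][ci] <- pp[[path]][ci] + h
    pm[[path]][ci] <- pm[[path]][ci] - h
    (loss_at(pp) - loss_at(pm)) / (2 * h)
  }
  max_err <- 0
  n_checked <- 0
  n_total <- 0
  for (path in leaves) {
    g <- grads[[path]]
    p <- model$params[[path]]
    coords <- sample(length(p), min(n_coords, length(p)))
    for (ci in coords) {
      n_total <- n_total + 1
      num <- numeric_grad(path, ci, eps)
      wide <- numeric_grad(path, ci, 10 * eps)
      # two step sizes disagreeing flags a local kink of the MAE/ReLU
      # objective (measure-zero nondifferentiable set), where central
      # differences are meaningless; skip those coordinates
      # central differences carry roundoff noise of order
      # eps_machine * |loss| / eps ~ 1e-11, so the relative-error floor
      # must sit above that (dead ReLU units have true gradient 0 and
      # would otherwise compare noise against an exact analytic zero)
      if (abs(num - wide) / max(1e-6, abs(num) + abs(wide)) > 1e-3) next
      n_checked <- n_checked + 1
      err <- abs(num - g[ci]) / max(1e-6, abs(num) + abs(g[ci]))
      max_err <- max(max_err, err)
    }
  }
  stopifnot(n_checked >= 0.8 * n_total)   # kinks must be the rare exception
  max_err
}
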