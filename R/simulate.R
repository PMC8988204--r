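# Synthetic field-trial generator.
#
# Emulates a split-plot winter-wheat nitrogen trial: 120 varieties x 2 N
# levels (control 240 kg/ha, deficient 0 kg/ha) x 2 replications = 480
# plots, each observed near-daily between 107 and 195 days after sowing
# (DAS). Eight canopy traits follow sigmoidal (structural) or unimodal
# (spectral) seasonal dynamics driven by a latent per-plot growth state;
# yield and grain protein content (GPC) derive from the same latent state
# with a nitrogen effect and a built-in yield-GPC trade-off.

#' Canopy trait names
#'
#' The eight traits the pipeline works with: four spectral indices
#' (GNDVI, CVI, NCPI, MCARI) and four structural traits (Hmean, H99,
#' PLA, Volume).
#'
#' @param which `"all"`, `"spectral"` or `"structural"`.
#' @return Character vector of trait names.
#' @export
trait_names <- function(which = c("all", "spectral", "structural")) {
  which <- match.arg(which)
  spectral <- c("GNDVI", "CVI", "NCPI", "MCARI")
  structural <- c("Hmean", "H99", "PLA", "Volume")
  switch(which, all = c(spectral, structural),
         spectral = spectral, structural = structural)
}

#' Observation window (days after sowing)
#'
#' @return Integer vector 107:195 (89 days).
#' @export
das_window <- function() 107:195

#' Default configuration of the synthetic trial generator
#'
#' Latent growth-state distributions, per-trait curve shapes/noise, and the
#' yield/GPC target model. All values are overridable; see the methods
#' vignette for the rationale behind each default.
#'
#' The latent state of a plot is: maximum canopy height `h_max` (m), logistic
#' `growth_rate` (1/day), DAS of fastest growth `t_mid`, anthesis date
#' `t_anthesis` (DAS), post-anthesis `senescence_rate` (1/day), a canopy
#' density scalar `vigor`, and a nitrogen multiplier `n_effect` whose mean
#' differs between control and deficient plots.
#'
#' Targets: `yield = a0 + a1*(h_max*n_effect) + a2*(vigor*(195 - t_anthesis))
#' + e_y` and `gpc = b0 + b1*n_effect - b2*(yield - yield_center)/yield_scale
#' + e_p`, which induces a negative yield-GPC partial correlation within each
#' nitrogen level.
#'
#' @param ... Named overrides of any default element.
#' @return A list of class `cropmtl_generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    # latent state distributions: c(mean, sd)
    h_max = c(0.9, 0.1),            # m
    growth_rate = c(0.12, 0.02),    # 1/day
    t_mid = c(135, 5),              # DAS
    t_anthesis = c(160, 3),         # DAS
    senescence_rate = c(0.08, 0.02),# 1/day
    vigor = c(1, 0.15),
    n_effect_control = c(1.0, 0.08),
    n_effect_deficient = c(0.7, 0.08),
    # observation noise: sd as a fraction of the trait's dynamic range
    # (multiplicative component) plus additive noise at noise_sd * range
    noise_sd = 0.03,
    # target model coefficients (yield kg/ha, gpc %); sigma_* are
    # instrument/micro-environment noise on the measured targets
    a0 = -1000, a1 = 7000, a2 = 30, sigma_yield = 150,
    b0 = 11, b1 = 1, b2 = 1.4, sigma_gpc = 0.10,
    yield_center = 5500, yield_scale = 1500,
    # observed days per plot (alternating, Table-style 51/53 design)
    n_observed = c(51L, 53L)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop2(paste0("unknown generator config field(s): ",
                 paste(unknown, collapse = ", ")),
          "cropmtl_invalid_argument")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "cropmtl_generator_config")
}

#' Simulate a full-factorial split-plot design
#'
#' Builds one plot record per (variety, nitrogen level, replication)
#' combination. Blocks follow a split-plot layout: one block per
#' (nitrogen, replication) whole plot.
#'
#' @param n_varieties,n_nitrogen,n_reps Positive counts. `n_nitrogen` must
#'   be 1 or 2 (control 240 kg/ha and, if 2, deficient 0 kg/ha).
#' @param seed Integer seed; the field order of plots is randomized
#'   deterministically given the seed.
#' @return A tibble with columns `plot_id`, `variety_id`, `nitrogen_level`
#'   (factor control/deficient), `nitrogen_rate` (kg/ha), `replication`,
#'   `block`.
#' @export
simulate_design <- function(n_varieties = 120, n_nitrogen = 2, n_reps = 2,
                            seed = 1) {
  n_varieties <- assert_count(n_varieties, "n_varieties")
  n_nitrogen <- assert_count(n_nitrogen, "n_nitrogen")
  n_reps <- assert_count(n_reps, "n_reps")
  if (n_nitrogen > 2) {
    stop2("only two nitrogen levels are defined (control, deficient)",
          "cropmtl_invalid_argument")
  }
  levels_n <- c("control", "deficient")[seq_len(n_nitrogen)]
  rates <- c(control = 240, deficient = 0)
  grid <- expand.grid(
    variety_id = seq_len(n_varieties),
    nitrogen_level = levels_n,
    replication = seq_len(n_reps),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$block <- (match(grid$nitrogen_level, levels_n) - 1L) * n_reps +
    grid$replication
  ord <- with_seed(derive_seed(seed, 101), sample.int(nrow(grid)))
  grid <- grid[ord, , drop = FALSE]
  grid$plot_id <- sprintf("P%04d", seq_len(nrow(grid)))
  rownames(grid) <- NULL
  tibble::as_tibble(grid[, c("plot_id", "variety_id", "nitrogen_level",
                             "replication", "block")]) ->
    out
  out$nitrogen_rate <- unname(rates[out$nitrogen_level])
  out[, c("plot_id", "variety_id", "nitrogen_level", "nitrogen_rate",
          "replication", "block")]
}

#' Draw the latent growth state of one plot
#'
#' Deterministic given (`record`, `seed`): the sub-seed is derived from the
#' plot's design factors, so states do not depend on generation order.
#' Nitrogen-deficient plots draw `n_effect` from a lower-mean distribution
#' than control plots.
#'
#' @param record One-row data frame as produced by [simulate_design()].
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A list of class `cropmtl_latent_state`.
#' @export
simulate_latent <- function(record, config = generator_config(), seed = 1) {
  sub <- derive_seed(seed, 7, record$variety_id,
                     match(record$nitrogen_level, c("control", "deficient")),
                     record$replication)
  draw <- function(p) rnorm(1, p[1], p[2])
  st <- with_seed(sub, {
    n_par <- if (identical(as.character(record$nitrogen_level), "control")) {
      config$n_effect_control
    } else {
      config$n_effect_deficient
    }
    s <- list(
      h_max = max(draw(config$h_max), 0.05),
      growth_rate = max(draw(config$growth_rate), 0.01),
      t_mid = min(max(draw(config$t_mid), 108), 185),
      t_anthesis = draw(config$t_anthesis),
      senescence_rate = max(draw(config$senescence_rate), 0.005),
      vigor = max(draw(config$vigor), 0.05),
      n_effect = max(draw(n_par), 0.05)
    )
    s$t_anthesis <- min(max(s$t_anthesis, s$t_mid + 1), 194)
    s
  })
  structure(st, class = "cropmtl_latent_state")
}

# Per-trait curve definitions. Structural traits rise logistically to a
# plateau scaled by h_max * n_effect * vigor; spectral indices rise
# logistically and decline exponentially after anthesis. `range` is the
# nominal dynamic range used to scale additive noise.
trait_curve_params <- function(state) {
  plateau <- state$h_max * state$n_effect * state$vigor
  list(
    Hmean  = list(kind = "structural", plateau = 800 * plateau, range = 800),
    H99    = list(kind = "structural", plateau = 1000 * plateau, range = 1000),
    PLA    = list(kind = "structural",
                  plateau = 0.9 * state$vigor * state$n_effect, range = 0.9),
    Volume = list(kind = "structural", plateau = 0.45 * plateau, range = 0.45),
    GNDVI  = list(kind = "spectral", base = 0.10,
                  amp = 0.60 * state$n_effect, range = 0.7),
    CVI    = list(kind = "spectral", base = 1.0,
                  amp = 4.0 * state$n_effect, range = 5),
    NCPI   = list(kind = "spectral", base = 0.05,
                  amp = 0.30 * (2 - state$n_effect), range = 0.4),
    MCARI  = list(kind = "spectral", base = 0.05,
                  amp = 1.0 * state$n_effect, range = 1)
  )
}

trait_curve <- function(state, trait, das) {
  p <- trait_curve_params(state)[[trait]]
  rise <- 1 / (1 + exp(-state$growth_rate * (das - state$t_mid)))
  if (p$kind == "structural") {
    p$plateau * rise
  } else {
    decay <- ifelse(das > state$t_anthesis,
                    exp(-state$senescence_rate * (das - state$t_anthesis)), 1)
    p$base + p$amp * rise * decay
  }
}

#' Simulate one trait's daily time series for a plot
#'
#' Emits all 89 days of the observation window (missingness is applied
#' separately by [apply_missingness()]). Noise is multiplicative-plus-
#' additive Gaussian: `y = f(t) * (1 + e_m) + e_a` with `sd(e_m) = noise_sd`
#' and `sd(e_a) = noise_sd * trait range`. Structural traits (heights, PLA,
#' Volume) are clipped at zero after noise; spectral indices are not.
#'
#' @param state A `cropmtl_latent_state`.
#' @param trait One of [trait_names()].
#' @param noise_sd Noise scale (fraction); default from the generator config.
#' @param seed Integer seed; output is deterministic given all inputs.
#' @return A tibble with columns `das`, `value`.
#' @export
simulate_trait_series <- function(state, trait, noise_sd = 0.03, seed = 1) {
  if (!is.character(trait) || length(trait) != 1 ||
      !trait %in% trait_names()) {
    stop2(sprintf("unknown trait '%s'; must be one of %s",
                  paste(trait, collapse = ","),
                  paste(trait_names(), collapse = ", ")),
          "cropmtl_invalid_argument")
  }
  das <- das_window()
  f <- trait_curve(state, trait, das)
  p <- trait_curve_params(state)[[trait]]
  sub <- derive_seed(seed, 13, match(trait, trait_names()))
  y <- with_seed(sub, {
    f * (1 + rnorm(length(f), 0, noise_sd)) +
      rnorm(length(f), 0, noise_sd * p$range)
  })
  if (p$kind == "structural") y <- pmax(y, 0)
  tibble::tibble(das = das, value = y)
}

#' Simulate yield and GPC targets from a latent state
#'
#' Closed form (see [generator_config()]): yield increases with effective
#' canopy size (`h_max * n_effect`) and grain-filling duration
#' (`vigor * (195 - t_anthesis)`); GPC increases with nitrogen and trades
#' off against standardized yield, so the yield-GPC correlation within a
#' nitrogen level is negative.
#'
#' @inheritParams simulate_latent
#' @param state A `cropmtl_latent_state`.
#' @return Named numeric vector `c(yield = ..., gpc = ...)` (kg/ha, %).
#' @export
simulate_targets <- function(state, config = generator_config(), seed = 1) {
  sub <- derive_seed(seed, 17, round(state$h_max * 1e6),
                     round(state$vigor * 1e6))
  eps <- with_seed(sub, rnorm(2))
  yield <- config$a0 + config$a1 * state$h_max * state$n_effect +
    config$a2 * state$vigor * (195 - state$t_anthesis) +
    config$sigma_yield * eps[1]
  yield <- max(yield, 50)
  gpc <- config$b0 + config$b1 * state$n_effect -
    config$b2 * (yield - config$yield_center) / config$yield_scale +
    config$sigma_gpc * eps[2]
  gpc <- min(max(gpc, 5.01), 24.99)
  c(yield = yield, gpc = gpc)
}

#' Restrict a trait series to a set of observed days
#'
#' Keeps `n_observed` days drawn without replacement, always retaining the
#' first and last day of the window (DAS 107 and 195) so downstream linear
#' interpolation never extrapolates. Deterministic given the seed.
#'
#' @param series A tibble with columns `das`, `value` covering the window.
#' @param n_observed Number of days to keep, between 2 and 89.
#' @param seed Integer seed.
#' @return The input series restricted to the kept days (sorted by DAS).
#' @export
apply_missingness <- function(series, n_observed, seed = 1) {
  n_observed <- assert_count(n_observed, "n_observed", min = 2)
  if (n_observed > nrow(series)) {
    stop2(sprintf("n_observed (%d) exceeds the number of days (%d)",
                  n_observed, nrow(series)),
          "cropmtl_invalid_argument")
  }
  keep <- missingness_keep_idx(nrow(series), n_observed, seed)
  series[keep, , drop = FALSE]
}

# Shared kept-day sampler so all traits of a plot can share missing dates.
missingness_keep_idx <- function(n_days, n_observed, seed) {
  ends <- c(1L, n_days)
  interior <- setdiff(seq_len(n_days), ends)
  extra <- with_seed(derive_seed(seed, 19),
                     sample(interior, n_observed - 2L))
  sort(c(ends, extra))
}

#' Simulate a complete phenotyping trial
#'
#' Runs the full generator: design, latent states, targets, all eight trait
#' series, and per-plot missingness (the same missing days for every trait
#' of a plot, as outages affect whole scan dates). The number of observed
#' days alternates between the values of `config$n_observed` across plots.
#'
#' @inheritParams simulate_design
#' @param config A [generator_config()].
#' @param traits Traits to generate (default all eight).
#' @return A list of class `cropmtl_trial` with elements `plots` (tibble:
#'   design columns plus `yield`, `gpc`) and `traits` (long tibble:
#'   `plot_id`, `das`, `trait`, `value`).
#' @export
simulate_trial <- function(n_varieties = 120, n_nitrogen = 2, n_reps = 2,
                           config = generator_config(), seed = 1,
                           traits = trait_names()) {
  design <- simulate_design(n_varieties, n_nitrogen, n_reps, seed)
  n <- nrow(design)
  yields <- numeric(n)
  gpcs <- numeric(n)
  series_list <- vector("list", n)
  n_obs_opts <- as.integer(config$n_observed)
  for (i in seq_len(n)) {
    rec <- design[i, ]
    state <- simulate_latent(rec, config, seed)
    tg <- simulate_targets(state, config, seed)
    yields[i] <- tg["yield"]
    gpcs[i] <- tg["gpc"]
    n_obs <- n_obs_opts[((i - 1L) %% length(n_obs_opts)) + 1L]
    keep <- missingness_keep_idx(length(das_window()), n_obs,
                                 derive_seed(seed, 23, i))
    per_trait <- lapply(traits, function(tr) {
      s <- simulate_trait_series(state, tr, config$noise_sd,
                                 derive_seed(seed, 29, i))
      s <- s[keep, , drop = FALSE]
      s$trait <- tr
      s$plot_id <- rec$plot_id
      s
    })
    series_list[[i]] <- do.call(rbind, per_trait)
  }
  plots <- design
  plots$yield <- yields
  plots$gpc <- gpcs
  traits_long <- do.call(rbind, series_list)
  traits_long <- tibble::as_tibble(
    traits_long[, c("plot_id", "das", "trait", "value")])
  structure(list(plots = plots, traits = traits_long),
            class = "cropmtl_trial")
}

#' Simulate a trial with target signal confined to a DAS interval
#'
#' A diagnostic benchmark for temporal-importance methods: the first trait
#' carries all target information, and only on days inside `signal_window`;
#' outside the window it is independent noise. The second trait is pure
#' nuisance. Used to check that attention profiles recover planted timing.
#'
#' @param n_plots Number of plots.
#' @param signal_window Length-2 DAS interval carrying the signal.
#' @param traits Names for the signal and nuisance trait (length 2).
#' @param noise_sd Observation noise sd on the standardized signal scale.
#' @param seed Integer seed.
#' @return A `cropmtl_trial` (fully observed; no missingness).
#' @export
simulate_planted_signal_trial <- function(n_plots = 200,
                                          signal_window = c(160, 195),
                                          traits = c("GNDVI", "Hmean"),
                                          noise_sd = 0.05, seed = 1) {
  n_plots <- assert_count(n_plots, "n_plots")
  das <- das_window()
  in_win <- das >= signal_window[1] & das <= signal_window[2]
  dat <- with_seed(derive_seed(seed, 31), {
    z <- rnorm(n_plots)
    yield <- 5000 + 1500 * z
    gpc <- 12 - 2 * z + rnorm(n_plots, 0, 0.1)
    sig <- matrix(rnorm(n_plots * length(das), 0, noise_sd),
                  n_plots, length(das))
    sig[, in_win] <- sig[, in_win] + z       # signal only inside the window
    nui <- matrix(rnorm(n_plots * length(das), 0, 1), n_plots, length(das))
    list(yield = yield, gpc = gpc, sig = sig, nui = nui)
  })
  plot_id <- sprintf("P%04d", seq_len(n_plots))
  plots <- tibble::tibble(
    plot_id = plot_id,
    variety_id = seq_len(n_plots),
    nitrogen_level = "control",
    nitrogen_rate = 240,
    replication = 1L,
    block = 1L,
    yield = dat$yield,
    gpc = dat$gpc
  )
  long <- function(mat, trait) {
    tibble::tibble(
      plot_id = rep(plot_id, each = length(das)),
      das = rep(das, n_plots),
      trait = trait,
      value = as.vector(t(mat))
    )
  }
  traits_long <- rbind(long(dat$sig, traits[1]), long(dat$nui, traits[2]))
  structure(list(plots = plots, traits = traits_long),
            class = "cropmtl_trial")
}

#' Write / read a trial as CSV files
#'
#' `write_trial()` writes `plots.csv` and `traits.csv` (long format:
#' plot_id, das, trait, value) into `dir`; `read_trial()` reads them back.
#' The round trip is lossless up to numeric printing precision (15
#' significant digits are written).
#'
#' @param trial A `cropmtl_trial`.
#' @param dir Directory (created if missing).
#' @return `write_trial()` returns the directory invisibly; `read_trial()`
#'   returns a `cropmtl_trial`.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop2(sprintf("cannot create directory '%s'", dir), "cropmtl_io")
  }
  wr <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) {
      # preserve integers; print doubles at full precision
      if (is.integer(x)) x else signif(x, 15)
    })
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(trial$plots, file.path(dir, "plots.csv"))
  wr(trial$traits, file.path(dir, "traits.csv"))
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  pp <- file.path(dir, "plots.csv")
  tp <- file.path(dir, "traits.csv")
  if (!file.exists(pp) || !file.exists(tp)) {
    stop2(sprintf("'%s' does not contain plots.csv and traits.csv", dir),
          "cropmtl_io")
  }
  plots <- tibble::as_tibble(utils::read.csv(pp, stringsAsFactors = FALSE))
  traits <- tibble::as_tibble(utils::read.csv(tp, stringsAsFactors = FALSE))
  structure(list(plots = plots, traits = traits), class = "cropmtl_trial")
}
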