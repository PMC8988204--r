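test_that("simulate_design builds a full factorial deterministically", {
  d <- simulate_design(3, 2, 2, seed = 7)
  expect_equal(nrow(d), 12)
  combos <- unique(d[, c("variety_id", "nitrogen_level", "replication")])
  expect_equal(nrow(combos), 12)
  expect_false(any(duplicated(d$plot_id)))
  expect_identical(d, simulate_design(3, 2, 2, seed = 7))
  expect_false(identical(d$variety_id, simulate_design(3, 2, 2, seed = 8)$variety_id))
  # degenerate design
  expect_equal(nrow(simulate_design(1, 1, 1, seed = 1)), 1)
  # nitrogen rates
  expect_setequal(unique(d$nitrogen_rate), c(240, 0))
})

test_that("simulate_design rejects bad counts", {
  expect_error(simulate_design(0, 2, 2), class = "cropmtl_invalid_argument")
  expect_error(simulate_design(3, 3, 2), class = "cropmtl_invalid_argument")
  expect_error(simulate_design(-1, 2, 2), class = "cropmtl_invalid_argument")
})

test_that("simulate_latent is deterministic and nitrogen-sensitive", {
  d <- simulate_design(100, 2, 1, seed = 3)
  s1 <- simulate_latent(d[1, ], seed = 5)
  expect_identical(s1, simulate_latent(d[1, ], seed = 5))
  states <- lapply(seq_len(nrow(d)), function(i) {
    simulate_latent(d[i, ], seed = 5)
  })
  ne <- vapply(states, `[[`, numeric(1), "n_effect")
  ctrl <- d$nitrogen_level == "control"
  expect_gt(mean(ne[ctrl]), mean(ne[!ctrl]))
  # latent invariants
  for (s in states) {
    expect_gt(s$h_max, 0)
    expect_gt(s$growth_rate, 0)
    expect_true(107 < s$t_mid && s$t_mid < s$t_anthesis && s$t_anthesis < 195)
  }
})

test_that("zero-variance latent config collapses to the configured means", {
  cfg <- generator_config(h_max = c(0.9, 0), growth_rate = c(0.12, 0),
                          t_mid = c(135, 0), t_anthesis = c(160, 0),
                          senescence_rate = c(0.08, 0), vigor = c(1, 0),
                          n_effect_control = c(1, 0))
  d <- simulate_design(1, 1, 1, seed = 1)
  s <- simulate_latent(d[1, ], cfg, seed = 9)
  expect_equal(s$h_max, 0.9)
  expect_equal(s$t_mid, 135)
  expect_equal(s$t_anthesis, 160)
  expect_equal(s$n_effect, 1)
})

test_that("generator_config rejects unknown fields", {
  expect_error(generator_config(not_a_field = 1),
               class = "cropmtl_invalid_argument")
})

test_that("trait series cover 89 days with the documented noiseless shapes", {
  d <- simulate_design(1, 1, 1, seed = 2)
  st <- simulate_latent(d[1, ], seed = 2)
  hm <- simulate_trait_series(st, "Hmean", noise_sd = 0, seed = 2)
  expect_equal(hm$das, das_window())
  expect_equal(nrow(hm), 89)
  # noiseless logistic rise is nondecreasing
  expect_true(all(diff(hm$value) >= 0))
  gv <- simulate_trait_series(st, "GNDVI", noise_sd = 0, seed = 2)
  peak <- gv$das[which.max(gv$value)]
  expect_gte(peak, st$t_mid)
  expect_lte(peak, st$t_anthesis + 5)
  # determinism with noise
  expect_identical(simulate_trait_series(st, "CVI", 0.03, seed = 4),
                   simulate_trait_series(st, "CVI", 0.03, seed = 4))
  # structural traits are clipped at zero
  noisy <- simulate_trait_series(st, "PLA", noise_sd = 2, seed = 4)
  expect_true(all(noisy$value >= 0))
  expect_error(simulate_trait_series(st, "NDVI"),
               class = "cropmtl_invalid_argument")
})

test_that("simulate_targets matches its closed form when noiseless", {
  cfg <- generator_config(sigma_yield = 0, sigma_gpc = 0)
  d <- simulate_design(1, 2, 1, seed = 11)
  st <- simulate_latent(d[1, ], cfg, seed = 11)
  tg <- simulate_targets(st, cfg, seed = 11)
  y_exp <- cfg$a0 + cfg$a1 * st$h_max * st$n_effect +
    cfg$a2 * st$vigor * (195 - st$t_anthesis)
  g_exp <- cfg$b0 + cfg$b1 * st$n_effect -
    cfg$b2 * (y_exp - cfg$yield_center) / cfg$yield_scale
  expect_equal(unname(tg["yield"]), y_exp)
  expect_equal(unname(tg["gpc"]), g_exp)
})

test_that("noiseless regression on the generator terms recovers a1", {
  cfg <- generator_config(sigma_yield = 0, sigma_gpc = 0)
  d <- simulate_design(60, 2, 1, seed = 13)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    st <- simulate_latent(d[i, ], cfg, seed = 13)
    tg <- simulate_targets(st, cfg, seed = 13)
    c(y = unname(tg["yield"]), t1 = st$h_max * st$n_effect,
      t2 = st$vigor * (195 - st$t_anthesis))
  })
  m <- as.data.frame(do.call(rbind, rows))
  # yield has two deterministic terms; regress on both to identify a1
  fit <- lm(y ~ t1 + t2, data = m)
  expect_lt(abs(unname(coef(fit)["t1"]) - cfg$a1), 1e-6)
})

test_that("yield-GPC correlation is negative within nitrogen level", {
  d <- simulate_design(120, 2, 2, seed = 17)
  tg <- t(vapply(seq_len(nrow(d)), function(i) {
    st <- simulate_latent(d[i, ], seed = 17)
    simulate_targets(st, seed = 17)
  }, c(yield = 0, gpc = 0)))
  for (lev in c("control", "deficient")) {
    sel <- d$nitrogen_level == lev
    obs <- cor(tg[sel, "yield"], tg[sel, "gpc"])
    expect_lt(obs, 0)
    # permutation test with 999 shuffles, p < 0.05
    set.seed(999)
    null_cors <- replicate(999, cor(tg[sel, "yield"], sample(tg[sel, "gpc"])))
    p <- (1 + sum(null_cors <= obs)) / (1 + length(null_cors))
    expect_lt(p, 0.05)
  }
})

test_that("with b2 = 0 and b1 > 0 control plots have higher mean GPC", {
  cfg <- generator_config(b2 = 0, b1 = 1)
  d <- simulate_design(500, 2, 1, seed = 19)
  tg <- t(vapply(seq_len(nrow(d)), function(i) {
    st <- simulate_latent(d[i, ], cfg, seed = 19)
    simulate_targets(st, cfg, seed = 19)
  }, c(yield = 0, gpc = 0)))
  ctrl <- d$nitrogen_level == "control"
  expect_gt(mean(tg[ctrl, "gpc"]), mean(tg[!ctrl, "gpc"]))
})

test_that("apply_missingness keeps endpoints and the requested count", {
  d <- simulate_design(1, 1, 1, seed = 23)
  st <- simulate_latent(d[1, ], seed = 23)
  s <- simulate_trait_series(st, "GNDVI", seed = 23)
  expect_identical(apply_missingness(s, 89, seed = 1), s)
  m53 <- apply_missingness(s, 53, seed = 1)
  expect_equal(nrow(m53), 53)
  expect_true(all(c(107, 195) %in% m53$das))
  expect_identical(apply_missingness(s, 53, seed = 1),
                   apply_missingness(s, 53, seed = 1))
  m2 <- apply_missingness(s, 2, seed = 1)
  expect_equal(m2$das, c(107, 195))
  expect_error(apply_missingness(s, 1), class = "cropmtl_invalid_argument")
  expect_error(apply_missingness(s, 90), class = "cropmtl_invalid_argument")
})

test_that("simulate_trial shares missing days across traits of a plot", {
  trial <- tiny_trial()
  expect_s3_class(trial$plots, "tbl_df")
  expect_equal(nrow(trial$plots), 12)
  expect_true(all(c("yield", "gpc") %in% names(trial$plots)))
  counts <- table(trial$traits$plot_id, trial$traits$trait)
  # same observation count for every trait of a plot
  expect_true(all(apply(counts, 1, function(x) length(unique(x)) == 1)))
  # alternating 51/53 observed days
  expect_setequal(unique(as.vector(counts)), c(51, 53))
  # identical observed dates across traits within a plot
  p1 <- trial$traits[trial$traits$plot_id == trial$plots$plot_id[1], ]
  das_by_trait <- split(p1$das, p1$trait)
  for (v in das_by_trait) expect_identical(sort(v), sort(das_by_trait[[1]]))
  # determinism
  expect_identical(trial, simulate_trial(3, 2, 2, seed = 42))
})

test_that("trials round-trip through CSV", {
  dir <- file.path(tempfile("trial"), "out")
  trial <- tiny_trial()
  write_trial(trial, dir)
  expect_true(file.exists(file.path(dir, "plots.csv")))
  expect_true(file.exists(file.path(dir, "traits.csv")))
  back <- read_trial(dir)
  expect_equal(back$plots$plot_id, trial$plots$plot_id)
  expect_equal(back$plots$yield, trial$plots$yield, tolerance = 1e-12)
  expect_equal(back$traits$value, trial$traits$value, tolerance = 1e-12)
  expect_error(read_trial(file.path(dir, "nope")), class = "cropmtl_io")
})

test_that("the planted-signal trial confines signal to the window", {
  trial <- simulate_planted_signal_trial(n_plots = 400, seed = 5)
  expect_equal(nrow(trial$plots), 400)
  z <- (trial$plots$yield - 5000) / 1500
  sig <- trial$traits[trial$traits$trait == "GNDVI", ]
  in_win <- sig[sig$das == 170, ]
  out_win <- sig[sig$das == 120, ]
  expect_gt(cor(in_win$value, z), 0.9)
  expect_lt(abs(cor(out_win$value, z)), 0.2)
  nui <- trial$traits[trial$traits$trait == "Hmean" & trial$traits$das == 170, ]
  expect_lt(abs(cor(nui$value, z)), 0.2)
})
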