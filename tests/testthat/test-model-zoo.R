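test_that("model_spec enforces topology arity and targets", {
  expect_error(model_spec("three_to_one", "Hmean", target = "yield"),
               class = "cropmtl_configuration")
  expect_error(model_spec("one_to_one", c("GNDVI", "Hmean"), target = "yield"),
               class = "cropmtl_configuration")
  expect_error(model_spec("two_to_two", "GNDVI"),
               class = "cropmtl_configuration")
  expect_error(model_spec("one_to_one", "GNDVI"),  # missing target
               class = "cropmtl_configuration")
  expect_error(model_spec("one_to_one", "GNDVI", target = "protein"),
               class = "cropmtl_configuration")
  expect_error(model_spec("one_to_one", "GNDVI", target = "yield",
                          extractor = "GRU"),
               class = "cropmtl_configuration")
  expect_error(model_spec("two_to_two", c("GNDVI", "Hmean"),
                          loss_weights = c(gpc = -1, yield = 2)),
               class = "cropmtl_configuration")
  sp <- model_spec("one_to_two", "GNDVI")
  expect_identical(sp$targets, c("yield", "gpc"))
  expect_output(print(sp), "one_to_two")
})

test_that("rebuilding a spec yields identical parameter counts and shapes", {
  for (topo in c("one_to_one", "two_to_two")) {
    traits <- if (topo == "one_to_one") "Hmean" else c("GNDVI", "Hmean")
    tg <- if (topo == "one_to_one") "yield" else NULL
    for (ex in c("FC", "RNN", "LSTM", "CNN1D", "ATTENTION")) {
      sp <- model_spec(topo, traits, target = tg, extractor = ex)
      m1 <- build_model(sp, seed = 1)
      m2 <- build_model(sp, seed = 2)
      expect_equal(cropmtl:::param_count(m1$params),
                   cropmtl:::param_count(m2$params))
      # same seed -> identical parameters
      expect_identical(m1$params, build_model(sp, seed = 1)$params)
    }
  }
})

test_that("dual-input topologies concatenate branch encodings to width 32", {
  sp <- model_spec("two_to_one", c("GNDVI", "Hmean"), target = "yield")
  m <- build_model(sp)
  expect_equal(dim(m$params$trunk$fuse$W), c(32, 16))
})

test_that("forward passes honor the shape contracts", {
  set.seed(5)
  X1 <- matrix(rnorm(32 * 89), 32, 89)
  X2 <- matrix(rnorm(32 * 89), 32, 89)
  for (ex in c("FC", "RNN", "LSTM", "CNN1D", "ATTENTION")) {
    m1 <- build_model(model_spec("one_to_one", "Hmean", target = "yield",
                                 extractor = ex))
    fw <- cropmtl:::model_forward(m1, list(X1))
    expect_length(fw$pred$yield, 32)
    m2 <- build_model(model_spec("two_to_two", c("GNDVI", "Hmean"),
                                 extractor = ex))
    fw2 <- cropmtl:::model_forward(m2, list(X1, X2))
    expect_named(fw2$pred, c("yield", "gpc"))
    expect_length(fw2$pred$gpc, 32)
  }
  # wrong input length and branch count
  m <- build_model(model_spec("one_to_one", "Hmean", target = "yield"))
  expect_error(cropmtl:::model_forward(m, list(X1[, 1:10])),
               class = "cropmtl_shape")
  expect_error(cropmtl:::model_forward(m, list(X1, X2)),
               class = "cropmtl_configuration")
})

test_that("the attention block emits probability weights and 89 x 5 features", {
  p <- init_attention_params(seed = 3)
  X <- matrix(rnorm(4 * 89), 4, 89)
  out <- extract_features_attention(X, p)
  expect_equal(dim(out$features), c(4, 89, 5))
  expect_equal(dim(out$attention), c(4, 89))
  expect_true(all(out$attention >= 0))
  expect_equal(rowSums(out$attention), rep(1, 4), tolerance = 1e-6)
  expect_error(extract_features_attention(X[, 1:10], p),
               class = "cropmtl_shape")
  # zeroed parameters and inputs -> exactly uniform attention 1/89
  p0 <- cropmtl:::param_map(p, function(x) x * 0)
  u <- extract_features_attention(matrix(0, 2, 89), p0)
  expect_equal(u$attention, matrix(1 / 89, 2, 89))
})

test_that("multitask_loss evaluates Eq.-style weighted MAE", {
  # MAE_gpc = 0.2, MAE_yield = 0.4, equal weights -> 0.3
  expect_equal(multitask_loss(pred_yield = c(0.4, 0.4), pred_gpc = c(0.2, 0.2),
                              true_yield = c(0, 0), true_gpc = c(0, 0)),
               0.3)
  expect_equal(multitask_loss(1:3, 4:6, 1:3, 4:6), 0)
  expect_equal(multitask_loss(c(1, 1), c(3, 5), c(0, 0), c(1, 1),
                              lambda_gpc = 1, lambda_yield = 0),
               mean(abs(c(3, 5) - c(1, 1))))
  expect_error(multitask_loss(1:3, 1:2, 1:3, 1:3),
               class = "cropmtl_invalid_argument")
  expect_error(multitask_loss(1, 1, 1, 1, lambda_gpc = -0.1),
               class = "cropmtl_invalid_argument")
  # with weights summing to 1 the loss lies between the two MAEs
  set.seed(8)
  py <- rnorm(10); pg <- rnorm(10); ty <- rnorm(10); tg <- rnorm(10)
  l <- multitask_loss(py, pg, ty, tg, 0.3, 0.7)
  maes <- c(mean(abs(pg - tg)), mean(abs(py - ty)))
  expect_gte(l, min(maes))
  expect_lte(l, max(maes))
})

test_that("analytic gradients match central differences off ReLU kinks", {
  combos <- list(
    list("one_to_one", "Hmean", "yield", "FC"),
    list("one_to_two", "Hmean", NULL, "FC"),
    list("two_to_one", c("GNDVI", "Hmean"), "gpc", "FC"),
    list("two_to_two", c("GNDVI", "Hmean"), NULL, "FC"),
    list("two_to_two", c("GNDVI", "Hmean"), NULL, "RNN"),
    list("two_to_two", c("GNDVI", "Hmean"), NULL, "LSTM"),
    list("two_to_two", c("GNDVI", "Hmean"), NULL, "CNN1D"),
    list("two_to_two", c("GNDVI", "Hmean"), NULL, "ATTENTION"),
    list("one_to_one", "Hmean", "yield", "LSTM"),
    list("one_to_one", "Hmean", "yield", "ATTENTION")
  )
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    sp <- model_spec(cb[[1]], cb[[2]], target = cb[[3]], extractor = cb[[4]],
                     input_length = 16)
    # fixed RNG state per combo: the MAE loss and ReLU are nondifferentiable
    # on measure-zero sets, so the checked configuration must be pinned
    set.seed(111 + i)
    err <- gradient_check(sp, seed = 11)
    expect_lt(err, 1e-4)
  }
})
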