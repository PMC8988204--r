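# Model zoo: four network topologies (one_to_one, one_to_two, two_to_one,
# two_to_two) crossed with five time-series feature extractors (FC, RNN,
# LSTM, CNN1D, ATTENTION), and the weighted multitask MAE loss.
#
# Layer plan. Single-input topologies: extractor (hidden layer 1, width 16)
# -> dense 16 (hidden 2) -> dense 16 (hidden 3) -> linear head(s).
# Dual-input topologies: one extractor per input branch (hidden layers 1-2,
# untied parameters) -> concatenation to width 32 -> dense 16 (hidden 3)
# -> linear head(s). Dropout follows every hidden layer during training.

EXTRACTORS <- c("FC", "RNN", "LSTM", "CNN1D", "ATTENTION")
TOPOLOGIES <- c("one_to_one", "one_to_two", "two_to_one", "two_to_two")

#' Specify a prediction model
#'
#' @param topology One of `"one_to_one"`, `"one_to_two"`, `"two_to_one"`,
#'   `"two_to_two"`. `one_*` topologies take one input trait, `two_*` take
#'   two; `*_one` topologies predict one target, `*_two` predict both yield
#'   and GPC.
#' @param input_traits Character vector of input trait names (length 1 or 2
#'   to match the topology).
#' @param target For single-output topologies: `"yield"` or `"gpc"`.
#' @param extractor Time-series feature extractor: `"FC"` (dense 89 to 16),
#'   `"RNN"`/`"LSTM"` (16-unit recurrent layer, last state), `"CNN1D"` (16
#'   filters, kernel 3, same padding, global average pooling), or
#'   `"ATTENTION"` (LSTM-to-5-channels, per-channel temporal softmax
#'   attention, flatten, dense to 16).
#' @param hidden_width Width of hidden layers / recurrent units (default 16).
#' @param input_length Days per input vector (default 89).
#' @param loss_weights Named `c(gpc =, yield =)` loss weights, nonnegative,
#'   summing to 1 (default 0.5/0.5). Ignored by single-output topologies.
#' @param dropout_rate Dropout after each hidden layer (default 0.1).
#' @param attention_channels LSTM channels in the attention block (default 5).
#' @return A list of class `cropmtl_spec`.
#' @export
model_spec <- function(topology, input_traits, target = NULL,
                       extractor = "FC", hidden_width = 16,
                       input_length = 89,
                       loss_weights = c(gpc = 0.5, yield = 0.5),
                       dropout_rate = 0.1, attention_channels = 5) {
  if (!topology %in% TOPOLOGIES) {
    stop2(sprintf("unknown topology '%s'", topology), "cropmtl_configuration")
  }
  if (!extractor %in% EXTRACTORS) {
    stop2(sprintf("unknown extractor '%s'", extractor), "cropmtl_configuration")
  }
  n_in <- if (topology %in% c("one_to_one", "one_to_two")) 1L else 2L
  if (length(input_traits) != n_in) {
    stop2(sprintf("topology '%s' takes %d input trait(s), got %d",
                  topology, n_in, length(input_traits)),
          "cropmtl_configuration")
  }
  targets <- if (topology %in% c("one_to_one", "two_to_one")) {
    if (is.null(target) || !target %in% c("yield", "gpc")) {
      stop2("single-output topologies need target = 'yield' or 'gpc'",
            "cropmtl_configuration")
    }
    target
  } else {
    c("yield", "gpc")
  }
  if (any(loss_weights < 0) ||
      !all(c("gpc", "yield") %in% names(loss_weights))) {
    stop2("loss_weights must be a nonnegative named c(gpc=, yield=) vector",
          "cropmtl_configuration")
  }
  structure(list(
    topology = topology, extractor = extractor,
    input_traits = input_traits, targets = targets,
    hidden_width = as.integer(hidden_width),
    input_length = as.integer(input_length),
    loss_weights = loss_weights[c("gpc", "yield")],
    dropout_rate = dropout_rate,
    attention_channels = as.integer(attention_channels)
  ), class = "cropmtl_spec")
}

extractor_init <- function(kind, input_length, width, channels) {
  switch(kind,
    FC = list(fc = dense_init(input_length, width)),
    RNN = list(rnn = rnn_init(width)),
    LSTM = list(lstm = lstm_init(width)),
    CNN1D = list(conv = conv1d_gap_init(filters = width)),
    ATTENTION = list(block = attention_init(input_length, channels),
                     proj = dense_init(input_length * channels, width))
  )
}

extractor_fwd <- function(kind, X, p) {
  switch(kind,
    FC = {
      r <- dense_fwd(X, p$fc, "relu")
      list(out = r$out, cache = list(fc = r$cache), attention = NULL)
    },
    RNN = {
      r <- rnn_last_fwd(X, p$rnn)
      list(out = r$out, cache = list(rnn = r$cache), attention = NULL)
    },
    LSTM = {
      r <- lstm_fwd(X, p$lstm, return_seq = FALSE)
      list(out = r$out, cache = list(lstm = r$cache), attention = NULL)
    },
    CNN1D = {
      r <- conv1d_gap_fwd(X, p$conv)
      list(out = r$out, cache = list(conv = r$cache), attention = NULL)
    },
    ATTENTION = {
      a <- attention_fwd(X, p$block)
      d <- dense_fwd(a$out, p$proj, "relu")
      list(out = d$out, cache = list(block = a$cache, proj = d$cache),
           attention = a$attention)
    }
  )
}

extractor_bwd <- function(kind, dE, cache, p) {
  switch(kind,
    FC = {
      r <- dense_bwd(dE, cache$fc, p$fc)
      list(dX = r$dX, grads = list(fc = r$grads))
    },
    RNN = {
      r <- rnn_last_bwd(dE, cache$rnn, p$rnn)
      list(dX = r$dX, grads = list(rnn = r$grads))
    },
    LSTM = {
      r <- lstm_bwd(dE, cache$lstm, p$lstm)
      list(dX = r$dX, grads = list(lstm = r$grads))
    },
    CNN1D = {
      r <- conv1d_gap_bwd(dE, cache$conv, p$conv)
      list(dX = r$dX, grads = list(conv = r$grads))
    },
    ATTENTION = {
      d <- dense_bwd(dE, cache$proj, p$proj)
      a <- attention_bwd(d$dX, cache$block, p$block)
      list(dX = a$dX, grads = list(block = a$grads, proj = d$grads))
    }
  )
}

#' Build an untrained model from a spec
#'
#' Initializes all parameters (Glorot-uniform kernels, zero biases, unit
#' LSTM forget bias) deterministically from the seed. Rebuilding a spec
#' always yields the same parameter shapes and counts.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initialization.
#' @return A list of class `cropmtl_model` with elements `spec`, `params`,
#'   `seed`, `trained`.
#' @export
build_model <- function(spec, seed = 1) {
  if (!inherits(spec, "cropmtl_spec")) {
    stop2("spec must be created with model_spec()", "cropmtl_configuration")
  }
  w <- spec$hidden_width
  n_br <- length(spec$input_traits)
  params <- with_seed(derive_seed(seed, 53), {
    branches <- lapply(seq_len(n_br), function(i) {
      extractor_init(spec$extractor, spec$input_length, w,
                     spec$attention_channels)
    })
    trunk <- if (n_br == 1) {
      list(h2 = dense_init(w, w), h3 = dense_init(w, w))
    } else {
      list(fuse = dense_init(2 * w, w))
    }
    heads <- lapply(spec$targets, function(tg) dense_init(w, 1))
    names(heads) <- spec$targets
    list(branches = branches, trunk = trunk, heads = heads)
  })
  structure(list(spec = spec, params = params, seed = seed, trained = FALSE),
            class = "cropmtl_model")
}

# Forward pass. inputs: list (one n x input_length matrix per branch).
# Returns predictions (named list of n-vectors), per-branch attention
# matrices (or NULL), and caches for the backward pass.
model_forward <- function(model, inputs, training = FALSE) {
  spec <- model$spec
  p <- model$params
  n_br <- length(spec$input_traits)
  if (length(inputs) != n_br) {
    stop2(sprintf("model expects %d input matrices, got %d",
                  n_br, length(inputs)), "cropmtl_configuration")
  }
  for (X in inputs) {
    if (ncol(X) != spec$input_length) {
      stop2(sprintf("input has %d time steps; model expects %d",
                    ncol(X), spec$input_length), "cropmtl_shape")
    }
  }
  enc <- vector("list", n_br)
  drop_enc <- vector("list", n_br)
  attn <- vector("list", n_br)
  ec <- vector("list", n_br)
  for (i in seq_len(n_br)) {
    e <- extractor_fwd(spec$extractor, inputs[[i]], p$branches[[i]])
    d <- dropout_fwd(e$out, spec$dropout_rate, training)
    enc[[i]] <- e
    drop_enc[[i]] <- d
    attn[[i]] <- e$attention
  }
  if (n_br == 1) {
    h2 <- dense_fwd(drop_enc[[1]]$out, p$trunk$h2, "relu")
    d2 <- dropout_fwd(h2$out, spec$dropout_rate, training)
    h3 <- dense_fwd(d2$out, p$trunk$h3, "relu")
    d3 <- dropout_fwd(h3$out, spec$dropout_rate, training)
    top <- d3$out
    trunk_cache <- list(h2 = h2$cache, d2 = d2$cache,
                        h3 = h3$cache, d3 = d3$cache)
  } else {
    conc <- cbind(drop_enc[[1]]$out, drop_enc[[2]]$out)
    hf <- dense_fwd(conc, p$trunk$fuse, "relu")
    df <- dropout_fwd(hf$out, spec$dropout_rate, training)
    top <- df$out
    trunk_cache <- list(fuse = hf$cache, dfuse = df$cache)
  }
  preds <- list()
  head_caches <- list()
  for (tg in spec$targets) {
    hh <- dense_fwd(top, p$heads[[tg]], "linear")
    preds[[tg]] <- as.vector(hh$out)
    head_caches[[tg]] <- hh$cache
  }
  list(pred = preds, attention = attn,
       cache = list(extractors = lapply(enc, `[[`, "cache"),
                    drop_enc = lapply(drop_enc, `[[`, "cache"),
                    trunk = trunk_cache, heads = head_caches))
}

# Backward pass. dpred: named list of n-vectors (gradients of the loss wrt
# each head's output). Returns a gradient tree mirroring model$params.
model_backward <- function(model, cache, dpred) {
  spec <- model$spec
  p <- model$params
  n_br <- length(spec$input_traits)
  dtop <- NULL
  head_grads <- list()
  for (tg in spec$targets) {
    hb <- dense_bwd(matrix(dpred[[tg]], ncol = 1), cache$heads[[tg]],
                    p$heads[[tg]])
    head_grads[[tg]] <- hb$grads
    dtop <- if (is.null(dtop)) hb$dX else dtop + hb$dX
  }
  if (n_br == 1) {
    d3 <- dropout_bwd(dtop, cache$trunk$d3)
    h3 <- dense_bwd(d3, cache$trunk$h3, p$trunk$h3)
    d2 <- dropout_bwd(h3$dX, cache$trunk$d2)
    h2 <- dense_bwd(d2, cache$trunk$h2, p$trunk$h2)
    trunk_grads <- list(h2 = h2$grads, h3 = h3$grads)
    denc <- list(h2$dX)
  } else {
    dfuse <- dropout_bwd(dtop, cache$trunk$dfuse)
    hf <- dense_bwd(dfuse, cache$trunk$fuse, p$trunk$fuse)
    trunk_grads <- list(fuse = hf$grads)
    w <- spec$hidden_width
    denc <- list(hf$dX[, seq_len(w), drop = FALSE],
                 hf$dX[, w + seq_len(w), drop = FALSE])
  }
  branch_grads <- vector("list", n_br)
  for (i in seq_len(n_br)) {
    dE <- dropout_bwd(denc[[i]], cache$drop_enc[[i]])
    eb <- extractor_bwd(spec$extractor, dE, cache$extractors[[i]],
                        p$branches[[i]])
    branch_grads[[i]] <- eb$grads
  }
  list(branches = branch_grads, trunk = trunk_grads, heads = head_grads)
}

#' Weighted multitask mean-absolute-error loss
#'
#' `loss = lambda_gpc * mean(|pred_gpc - true_gpc|) +
#'  lambda_yield * mean(|pred_yield - true_yield|)`, evaluated on the
#' normalized target scale during training. With weights summing to 1 the
#' total lies between the two per-task MAEs.
#'
#' @param pred_yield,pred_gpc,true_yield,true_gpc Equal-length numeric
#'   vectors.
#' @param lambda_gpc,lambda_yield Nonnegative loss weights (defaults 0.5).
#' @return The scalar loss.
#' @export
multitask_loss <- function(pred_yield, pred_gpc, true_yield, true_gpc,
                           lambda_gpc = 0.5, lambda_yield = 0.5) {
  lens <- c(length(pred_yield), length(pred_gpc),
            length(true_yield), length(true_gpc))
  if (length(unique(lens)) != 1) {
    stop2("prediction/truth vectors must have equal lengths",
          "cropmtl_invalid_argument")
  }
  if (lambda_gpc < 0 || lambda_yield < 0) {
    stop2("loss weights must be nonnegative", "cropmtl_invalid_argument")
  }
  lambda_gpc * mean(abs(pred_gpc - true_gpc)) +
    lambda_yield * mean(abs(pred_yield - true_yield))
}

# Loss and head gradients for a batch, honoring the topology's targets.
batch_loss_and_grad <- function(spec, preds, truth) {
  lw <- spec$loss_weights
  loss <- 0
  dpred <- list()
  for (tg in spec$targets) {
    lam <- if (length(spec$targets) == 1) 1 else unname(lw[tg])
    resid <- preds[[tg]] - truth[[tg]]
    loss <- loss + lam * mean(abs(resid))
    dpred[[tg]] <- lam * sign(resid) / length(resid)
  }
  list(loss = loss, dpred = dpred)
}

#' Initialize an attention feature-extraction block
#'
#' Standalone access to the attention module used by the `ATTENTION`
#' extractor: an LSTM mapping a length-`input_length` series to `channels`
#' feature channels per day, a per-channel dense map over the time axis with
#' a softmax along time, and the elementwise product of the two branches.
#'
#' @param input_length Series length (default 89).
#' @param channels Feature channels (default 5).
#' @param seed Integer seed.
#' @return An opaque parameter list for [extract_features_attention()].
#' @export
init_attention_params <- function(input_length = 89, channels = 5, seed = 1) {
  with_seed(derive_seed(seed, 59), attention_init(input_length, channels))
}

#' Apply the attention feature-extraction block
#'
#' @param input An n x input_length matrix (one time series per row).
#' @param params From [init_attention_params()].
#' @return A list: `features` (array n x input_length x channels) and
#'   `attention` (n x input_length matrix; each row is nonnegative and sums
#'   to 1 over the days).
#' @export
extract_features_attention <- function(input, params) {
  input <- as.matrix(input)
  T_ <- ncol(params$att[[1]]$W)
  if (ncol(input) != T_) {
    stop2(sprintf("input has %d time steps; attention block expects %d",
                  ncol(input), T_), "cropmtl_shape")
  }
  r <- attention_fwd(input, params)
  C <- length(params$att)
  feats <- array(r$out, dim = c(nrow(input), T_, C))
  list(features = feats, attention = r$attention)
}

#' @export
print.cropmtl_spec <- function(x, ...) {
  cat(sprintf("<cropmtl model spec> %s / %s\n", x$topology, x$extractor))
  cat("  inputs: ", paste(x$input_traits, collapse = ", "), "\n", sep = "")
  cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  if (length(x$targets) == 2) {
    cat(sprintf("  loss weights: gpc=%.2f yield=%.2f\n",
                x$loss_weights["gpc"], x$loss_weights["yield"]))
  }
  invisible(x)
}
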