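# End-to-end orchestration: YAML run configuration, staged execution with
# artifact output and a JSON run manifest, and the full model-comparison
# study (one-to-one per trait, fusion, multitask weight sweep, and the five
# two-to-two extractor variants).

#' Default run configuration
#'
#' Nested stage configurations consumed by [run_stage()] /
#' [run_pipeline()]. A single global seed expands into per-stage sub-seeds,
#' so any stage can be rerun in isolation with identical results.
#'
#' @param seed Global seed.
#' @param ... Named overrides merged (shallowly per stage) into the
#'   defaults.
#' @return A list of class `cropmtl_run_config`.
#' @export
default_run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(n_varieties = 120, n_nitrogen = 2, n_reps = 2,
                    generator = list()),
    prepare = list(augment_to = 1000,
                   methods = c("jitter", "scale", "resample"),
                   ratios = c(0.8, 0.1, 0.1), scale_features = TRUE),
    model = list(topology = "two_to_two", extractor = "ATTENTION",
                 input_traits = c("GNDVI", "Hmean"), target = NULL,
                 hidden_width = 16, dropout_rate = 0.1,
                 loss_weights = c(gpc = 0.5, yield = 0.5)),
    training = list(learning_rate = 0.001, batch_size = 32,
                    max_epochs = 500, early_stop_patience = 20),
    evaluation = list(split = "test"),
    attention = list(split = "test", anthesis_das = 160),
    study = list(n_seeds = 2)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "cropmtl_run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return A `cropmtl_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop2(sprintf("config file '%s' does not exist", path), "cropmtl_io")
  }
  raw <- yaml::read_yaml(path)
  cfg <- do.call(default_run_config,
                 c(list(seed = raw$seed %||% 1),
                   raw[setdiff(names(raw), "seed")]))
  # YAML reads named maps as lists; coerce known vector fields
  lw <- cfg$model$loss_weights
  if (is.list(lw)) cfg$model$loss_weights <- unlist(lw)
  if (is.list(cfg$prepare$ratios)) {
    cfg$prepare$ratios <- unlist(cfg$prepare$ratios)
  }
  cfg
}

write_manifest <- function(out_dir, stage, cfg) {
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = as.character(getRversion()),
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' Stages: `"simulate"` (writes plots.csv/traits.csv), `"prepare"` (writes
#' prepared targets, split assignment and norm params), `"train"` (trains
#' the configured model; writes the training log), `"evaluate"` (writes the
#' metric report), `"attention"` (writes the daily-importance profile CSV
#' and figure), `"reproduce-study"` (the full comparison matrix; see
#' [reproduce_study()]). Each stage writes a JSON run manifest and returns
#' its main artifact invisibly. Stages after `"simulate"` reuse in-memory
#' artifacts passed via `state` or read their inputs from `out_dir`.
#'
#' @param stage Stage name.
#' @param config A `cropmtl_run_config` (or path to a YAML file).
#' @param out_dir Output/exchange directory.
#' @param state Optional list carrying artifacts between stages (as used by
#'   [run_pipeline()]).
#' @return Invisibly, the updated `state`.
#' @export
run_stage <- function(stage, config = default_run_config(), out_dir,
                      state = list()) {
  stages <- c("simulate", "prepare", "train", "evaluate", "attention",
              "reproduce-study")
  if (!stage %in% stages) {
    stop2(sprintf("unknown stage '%s'; use one of: %s", stage,
                  paste(stages, collapse = ", ")),
          "cropmtl_invalid_argument")
  }
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  if (stage == "simulate") {
    gc_args <- config$simulate$generator %||% list()
    gcfg <- do.call(generator_config, gc_args)
    state$trial <- simulate_trial(config$simulate$n_varieties,
                                  config$simulate$n_nitrogen,
                                  config$simulate$n_reps,
                                  config = gcfg,
                                  seed = derive_seed(seed, 1))
    write_trial(state$trial, out_dir)
  } else if (stage == "prepare") {
    trial <- state$trial %||% read_trial(out_dir)
    state$dataset <- prepare_dataset(
      trial,
      augment_to = config$prepare$augment_to,
      methods = config$prepare$methods,
      ratios = config$prepare$ratios,
      scale_features = config$prepare$scale_features %||% TRUE,
      seed = derive_seed(seed, 2)
    )
    tg <- state$dataset$targets
    tg$split <- NA_character_
    for (snm in names(state$dataset$splits)) {
      tg$split[state$dataset$splits[[snm]]] <- snm
    }
    utils::write.csv(tg, file.path(out_dir, "prepared_targets.csv"),
                     row.names = FALSE)
    jsonlite::write_json(state$dataset$norm_params,
                         file.path(out_dir, "norm_params.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (stage == "train") {
    if (is.null(state$dataset)) {
      stop2("no prepared dataset available; run the 'prepare' stage first",
            "cropmtl_missing_input")
    }
    mc <- config$model
    sp <- model_spec(mc$topology, mc$input_traits, target = mc$target,
                     extractor = mc$extractor,
                     hidden_width = mc$hidden_width %||% 16,
                     loss_weights = mc$loss_weights %||%
                       c(gpc = 0.5, yield = 0.5),
                     dropout_rate = mc$dropout_rate %||% 0.1)
    tc <- train_config(learning_rate = config$training$learning_rate,
                       batch_size = config$training$batch_size,
                       max_epochs = config$training$max_epochs,
                       early_stop_patience = config$training$early_stop_patience,
                       seed = derive_seed(seed, 3))
    state$model <- train_model(sp, state$dataset, tc)
    utils::write.csv(state$model$history,
                     file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
  } else if (stage == "evaluate") {
    if (is.null(state$model) || is.null(state$dataset)) {
      stop2("no trained model/dataset available; run earlier stages first",
            "cropmtl_missing_input")
    }
    state$report <- evaluate_model(state$model, state$dataset,
                                   config$evaluation$split %||% "test")
    utils::write.csv(state$report, file.path(out_dir, "eval_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(state$report, file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else if (stage == "attention") {
    if (is.null(state$model) || is.null(state$dataset)) {
      stop2("no trained model/dataset available; run earlier stages first",
            "cropmtl_missing_input")
    }
    prof <- extract_attention_profile(state$model, state$dataset,
                                      config$attention$split %||% "test")
    state$attention_profile <- prof
    utils::write.csv(prof, file.path(out_dir, "attention_profile.csv"),
                     row.names = FALSE)
    export_profile_plot(prof, file.path(out_dir, "attention_profile.png"),
                        anthesis_das = config$attention$anthesis_das %||% 160)
  } else { # reproduce-study
    if (is.null(state$dataset)) {
      stop2("no prepared dataset available; run the 'prepare' stage first",
            "cropmtl_missing_input")
    }
    tc <- train_config(learning_rate = config$training$learning_rate,
                       batch_size = config$training$batch_size,
                       max_epochs = config$training$max_epochs,
                       early_stop_patience = config$training$early_stop_patience)
    st <- reproduce_study(state$dataset,
                          n_seeds = config$study$n_seeds %||% 2,
                          config = tc, base_seed = derive_seed(seed, 4))
    state$study <- st
    utils::write.csv(st$table, file.path(out_dir, "comparison_table.csv"),
                     row.names = FALSE)
    if (!is.null(st$attention_profile)) {
      utils::write.csv(st$attention_profile,
                       file.path(out_dir, "study_attention_profile.csv"),
                       row.names = FALSE)
    }
  }
  write_manifest(out_dir, stage, config)
  invisible(state)
}

#' Run pipeline stages in order
#'
#' @param config A `cropmtl_run_config` or path to a YAML file.
#' @param out_dir Output directory.
#' @param stages Stages to execute, in order (default: simulate through
#'   attention).
#' @return Invisibly, the final state (trial, dataset, model, report,
#'   attention profile as applicable).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = c("simulate", "prepare", "train",
                                    "evaluate", "attention")) {
  if (is.character(config)) config <- read_run_config(config)
  state <- list()
  for (sg in stages) state <- run_stage(sg, config, out_dir, state)
  invisible(state)
}

#' Reproduce the full model-comparison study
#'
#' Trains and evaluates, each `n_seeds` times on the supplied dataset:
#' the 8 one-to-one models per target (16 configurations), the two-to-one
#' fusion model per target (GNDVI + Hmean), the one-to-two multitask model
#' across the nine yield/GPC loss-weight ratios 0.9:0.1 ... 0.1:0.9, and
#' the five two-to-two extractor variants (FC, RNN, LSTM, CNN1D,
#' ATTENTION). Returns the comparison table (one row per configuration and
#' target: 16 + 2 + 18 + 10 rows) plus the attention model's daily
#' importance profile.
#'
#' @param dataset A split `cropmtl_dataset` containing the eight traits.
#' @param n_seeds Training replicates per configuration.
#' @param config A [train_config()] template.
#' @param base_seed Seed from which all replicate seeds derive.
#' @param one_to_one_traits Traits for the one-to-one scan (default all
#'   traits in the dataset).
#' @return A list with `table` (tibble) and `attention_profile`.
#' @export
reproduce_study <- function(dataset, n_seeds = 2, config = train_config(),
                            base_seed = 1,
                            one_to_one_traits = dataset$traits) {
  specs <- list()
  for (tr in one_to_one_traits) {
    for (tg in c("yield", "gpc")) {
      specs[[length(specs) + 1]] <- model_spec("one_to_one", tr, target = tg)
    }
  }
  fusion_inputs <- intersect(c("GNDVI", "Hmean"), dataset$traits)
  if (length(fusion_inputs) < 2) fusion_inputs <- dataset$traits[1:2]
  for (tg in c("yield", "gpc")) {
    specs[[length(specs) + 1]] <- model_spec("two_to_one", fusion_inputs,
                                             target = tg)
  }
  hm <- intersect("Hmean", dataset$traits)
  if (length(hm) == 0) hm <- dataset$traits[1]
  for (ly in seq(0.9, 0.1, by = -0.1)) {
    specs[[length(specs) + 1]] <- model_spec(
      "one_to_two", hm,
      loss_weights = c(gpc = round(1 - ly, 1), yield = round(ly, 1)))
  }
  for (ex in EXTRACTORS) {
    specs[[length(specs) + 1]] <- model_spec("two_to_two", fusion_inputs,
                                             extractor = ex)
  }
  table <- compare_models(specs, dataset, n_seeds = n_seeds, config = config,
                          base_seed = base_seed)
  att_cfg <- config
  att_cfg$seed <- derive_seed(base_seed, 9999)
  att_spec <- model_spec("two_to_two", fusion_inputs, extractor = "ATTENTION")
  att_profile <- tryCatch({
    m <- train_model(att_spec, dataset, att_cfg)
    extract_attention_profile(m, dataset, "test")
  }, error = function(e) NULL)
  list(table = table, attention_profile = att_profile)
}
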