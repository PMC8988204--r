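# Attention-based daily feature-importance analysis.
#
# The ATTENTION extractor's temporal softmax yields, for every example and
# input trait, a probability vector over the 89 days. Averaging over the
# examples of a split and scaling to percent gives an interpretable
# "importance per day" profile (the per-trait profile sums to 100%).

#' Extract daily attention-importance profiles
#'
#' Runs a forward pass of a trained `two_to_two` model with the `ATTENTION`
#' extractor over a dataset split, averages the per-day softmax attention
#' weights (already channel-averaged) over examples, and scales to percent.
#'
#' @param model A trained `cropmtl_model` with topology `two_to_two` and
#'   extractor `ATTENTION`.
#' @param dataset A split `cropmtl_dataset`.
#' @param split Split name or index vector (default `"test"`).
#' @return A tibble of class `cropmtl_attention_profile` with columns
#'   `input_trait`, `das`, `importance_pct` (89 rows per input trait; each
#'   trait's values sum to 100) and attribute `n_examples`.
#' @export
extract_attention_profile <- function(model, dataset, split = "test") {
  sp <- model$spec
  if (sp$topology != "two_to_two" || sp$extractor != "ATTENTION") {
    stop2("attention profiles require a two_to_two model with the ATTENTION extractor",
          "cropmtl_configuration")
  }
  idx <- dataset_split_idx(dataset, split)
  X <- dataset_inputs(dataset, sp$input_traits, idx)
  fw <- model_forward(model, X, training = FALSE)
  rows <- lapply(seq_along(sp$input_traits), function(i) {
    daily <- colMeans(fw$attention[[i]]) * 100
    tibble::tibble(input_trait = sp$input_traits[i],
                   das = dataset$das,
                   importance_pct = daily)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_examples") <- length(idx)
  class(out) <- c("cropmtl_attention_profile", class(out))
  out
}

#' Pre- vs post-anthesis mean daily importance
#'
#' @param profile One trait's rows of an attention profile (columns `das`,
#'   `importance_pct`).
#' @param anthesis_das Anthesis date (DAS), strictly inside (107, 195);
#'   default 160. Days before it are "pre", days at or after it "post".
#' @return Named vector `c(pre_mean =, post_mean =)` in percent per day.
#' @export
stage_importance <- function(profile, anthesis_das = 160) {
  if (!is.numeric(anthesis_das) || length(anthesis_das) != 1 ||
      anthesis_das <= 107 || anthesis_das >= 195) {
    stop2("anthesis_das must lie strictly inside (107, 195)",
          "cropmtl_invalid_argument")
  }
  if (length(unique(profile$input_trait %||% "x")) > 1) {
    stop2("stage_importance takes a single trait's profile",
          "cropmtl_invalid_argument")
  }
  pre <- profile$importance_pct[profile$das < anthesis_das]
  post <- profile$importance_pct[profile$das >= anthesis_das]
  c(pre_mean = mean(pre), post_mean = mean(post))
}

#' Plot daily attention profiles
#'
#' One bar panel per input trait with the anthesis date marked.
#'
#' @param profiles A `cropmtl_attention_profile` (any number of traits).
#' @param anthesis_das Anthesis marker (default 160).
#' @return A ggplot object.
#' @export
plot_attention_profiles <- function(profiles, anthesis_das = 160) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    stop2("no profiles to plot", "cropmtl_invalid_argument")
  }
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = das, y = importance_pct)) +
    ggplot2::geom_col(fill = "#2c7fb8", width = 0.8) +
    ggplot2::geom_vline(xintercept = anthesis_das, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~input_trait, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Days after sowing",
                  y = "Attention importance (% per day)") +
    ggplot2::theme_minimal()
}

#' Export attention profiles as a figure
#'
#' @inheritParams plot_attention_profiles
#' @param path Output file (extension selects the device, e.g. `.png`,
#'   `.svg`).
#' @param width,height,dpi Figure geometry passed to [ggplot2::ggsave()].
#' @return The path, invisibly.
#' @export
export_profile_plot <- function(profiles, path, anthesis_das = 160,
                                width = 8, height = 3.2, dpi = 150) {
  p <- plot_attention_profiles(profiles, anthesis_das)
  n_panels <- length(unique(profiles$input_trait))
  ggplot2::ggsave(path, p, width = width, height = height * n_panels,
                  dpi = dpi)
  invisible(path)
}
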