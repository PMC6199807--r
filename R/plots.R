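#' Methylation profile of a target by smoking group
#'
#' Mean per-CpG methylation (with standard-error ribbons) along the
#' amplicon, split by smoking status — the regional profile view of a
#' target.
#'
#' @param mat A `haplo_meth` tibble.
#' @param covariates Covariate tibble with `sample_id` and `smoking`.
#' @param target Target label to plot.
#' @return A ggplot object.
#' @export
plot_methylation_profile <- function(mat, covariates, target) {
  df <- mat |>
    filter(.data$target == !!target) |>
    left_join(select(covariates, "sample_id", "smoking"), by = "sample_id") |>
    summarise(mean_m = mean(.data$m, na.rm = TRUE),
              se = sd(.data$m, na.rm = TRUE) / sqrt(sum(!is.na(.data$m))),
              .by = c("cpg_pos", "smoking")) |>
    mutate(group = ifelse(.data$smoking == 1, "smoker", "non-smoker"))
  ggplot2::ggplot(df, ggplot2::aes(.data$cpg_pos, .data$mean_m,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_m - .data$se,
                                      ymax = .data$mean_m + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(smoker = "#c0392b",
                                            `non-smoker` = "#2c5aa0"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "genomic position", y = "methylation rate",
                  colour = NULL, fill = NULL, title = target)
}

#' @describeIn covariate_tests Per-CpG significance track:
#'   -log10 adjusted p against genomic position, faceted by target.
#' @param object An `asm_tests` tibble.
#' @param ... Unused.
#' @method autoplot asm_tests
#' @export
autoplot.asm_tests <- function(object, ...) {
  df <- filter(object, !.data$untestable)
  ggplot2::ggplot(df, ggplot2::aes(.data$cpg_pos,
                                   -log10(.data$p_adjusted))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$estimate > 0)) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::facet_wrap(~ target, scales = "free_x") +
    ggplot2::labs(x = "genomic position",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "effect > 0",
                  title = unique(df$covariate))
}

#' @describeIn evaluate_three_models ROC curves of the evaluated models on
#'   the test set.
#' @param object A `smoking_model_set` (or single `smoking_model_report`).
#' @param ... Unused.
#' @method autoplot smoking_model_set
#' @export
autoplot.smoking_model_set <- function(object, ...) {
  df <- purrr::map_dfr(object, function(r) {
    mutate(r$roc, model = sprintf("%s (AUC = %.3f)", r$model, r$auc))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL)
}

#' @rdname autoplot.smoking_model_set
#' @method autoplot smoking_model_report
#' @export
autoplot.smoking_model_report <- function(object, ...) {
  autoplot.smoking_model_set(structure(list(object),
                                       class = "smoking_model_set"))
}
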