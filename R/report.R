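#' Plot condition learning curves
#'
#' Percent correct (or normalized correct-key activation) per condition
#' against training epoch, averaged over retained runs.
#'
#' @param x a `tonal_experiment`.
#' @param dv `"percent_correct"` or `"activation"`.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(x, dv = c("percent_correct", "activation")) {
  dv <- match.arg(dv)
  cm <- condition_means(x, dv)
  ylab <- if (dv == "percent_correct") "Correct key identification (%)"
          else "Normalized C-major activation"
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$epoch, y = .data$mean,
                                   colour = .data$condition,
                                   shape = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Training epoch", y = ylab, colour = NULL,
                  shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot the training agreement curve
#'
#' @param x a `tonal_experiment`.
#' @return A ggplot object.
#' @export
plot_agreement_curve <- function(x) {
  ag <- aggregate(agreement ~ epoch, data = x$agreement, FUN = mean)
  ggplot2::ggplot(ag, ggplot2::aes(x = .data$epoch, y = .data$agreement)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Training epoch",
                  y = "Agreement with labelled key (%)") +
    ggplot2::theme_minimal()
}

#' Write an experiment report bundle
#'
#' Emits tidy CSVs (raw trajectory records, condition x epoch means for
#' both measures, agreement curve, per-epoch pairwise comparison tables for
#' both measures) plus learning-curve figures into a directory.
#'
#' @param x a `tonal_experiment`.
#' @param dir output directory (created if needed).
#' @param anova_pc,anova_act optional [rm_anova()] reports to include; if
#'   `NULL` they are computed from `x`.
#' @param figures write PNG figures as well (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir, anova_pc = NULL, anova_act = NULL,
                         figures = TRUE) {
  stopifnot(inherits(x, "tonal_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(anova_pc)) anova_pc <- rm_anova(x, "percent_correct")
  if (is.null(anova_act)) anova_act <- rm_anova(x, "activation")

  out <- function(name) file.path(dir, name)
  write.csv(x$trajectories, out("trajectories.csv"), row.names = FALSE)
  write.csv(x$agreement, out("agreement.csv"), row.names = FALSE)
  write.csv(condition_means(x, "percent_correct"),
            out("means_percent_correct.csv"), row.names = FALSE)
  write.csv(condition_means(x, "activation"),
            out("means_activation.csv"), row.names = FALSE)
  write.csv(anova_pc$omnibus, out("anova_percent_correct.csv"),
            row.names = FALSE)
  write.csv(anova_act$omnibus, out("anova_activation.csv"),
            row.names = FALSE)
  write.csv(cbind(anova_pc$simple,
                  stats::reshape(anova_pc$pairwise[c("epoch", "pair",
                                                     "significant")],
                                 idvar = "epoch", timevar = "pair",
                                 direction = "wide")[-1]),
            out("pairwise_percent_correct.csv"), row.names = FALSE)
  write.csv(cbind(anova_act$simple,
                  stats::reshape(anova_act$pairwise[c("epoch", "pair",
                                                      "significant")],
                                 idvar = "epoch", timevar = "pair",
                                 direction = "wide")[-1]),
            out("pairwise_activation.csv"), row.names = FALSE)
  manifest <- list(
    n_runs = x$config$n_runs,
    base_seed = x$config$base_seed,
    corpus_seed = x$config$corpus_spec$seed,
    retained_runs = x$retained_runs,
    excluded_runs = x$excluded_runs,
    final_agreement = round(x$final_agreement, 2))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (figures) {
    ggplot2::ggsave(out("learning_curves_percent_correct.png"),
                    plot_learning_curves(x, "percent_correct"),
                    width = 7, height = 4.5, dpi = 150)
    ggplot2::ggsave(out("learning_curves_activation.png"),
                    plot_learning_curves(x, "activation"),
                    width = 7, height = 4.5, dpi = 150)
    ggplot2::ggsave(out("agreement_curve.png"), plot_agreement_curve(x),
                    width = 7, height = 4.5, dpi = 150)
  }
  invisible(dir)
}
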