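#' Plot genetic-gain trajectories of a study
#'
#' Mean scaled TMI gain (genetic standard deviations) of the breeding ram
#' cohort per evaluated cycle, one line per scenario, with a +/- 1 SD
#' ribbon across replicates.
#'
#' @param object A `merino_study`.
#' @param cohort,trait Passed to [gain_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.merino_study <- function(object, cohort = "breeding_rams",
                                  trait = "TMI", ...) {
  gt <- gain_table(object, cohort, trait)
  ggplot2::ggplot(gt, ggplot2::aes(x = .data$cycle, y = .data$mean_gain,
                                   colour = .data$scenario,
                                   fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_gain - .data$sd_gain,
                                      ymax = .data$mean_gain + .data$sd_gain),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "breeding cycle (post-reference)",
                  y = sprintf("genetic gain of %s [genetic SD]", trait),
                  colour = "scenario", fill = "scenario") +
    ggplot2::theme_minimal()
}

#' Plot EBV accuracies of a study
#'
#' Mean EBV accuracy per scenario, cohort and trait with +/- 1 SD error
#' bars across replicates.
#'
#' @param study A `merino_study`.
#' @param traits Traits to show (default TMI and the field fattening
#'   traits).
#' @return A ggplot object.
#' @export
plot_accuracy <- function(study, traits = c("TMI", field_traits())) {
  at <- accuracy_table(study, traits)
  at$trait <- factor(at$trait, levels = traits)
  ggplot2::ggplot(at, ggplot2::aes(x = .data$trait,
                                   y = .data$mean_accuracy,
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = NULL, y = "EBV accuracy (cor(TBV, EBV))",
                  fill = "scenario") +
    ggplot2::theme_minimal()
}

#' Plot kinship trajectories
#'
#' Mean kinship of the breeding population per evaluated cycle and
#' scenario, averaged over replicates.
#'
#' @param study A `merino_study`.
#' @return A ggplot object.
#' @export
plot_kinship <- function(study) {
  kin <- as_tibble(study)
  kin <- kin[kin$metric == "kinship", ]
  ks <- dplyr::summarise(
    dplyr::group_by(kin, .data$scenario, .data$cycle),
    mean_kinship = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(ks, ggplot2::aes(x = .data$cycle, y = .data$mean_kinship,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "breeding cycle", y = "mean kinship",
                  colour = "scenario") +
    ggplot2::theme_minimal()
}
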