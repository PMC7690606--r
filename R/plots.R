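#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_segment geom_rect
#'   geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Stage funnel of a discovery run
#'
#' @param object A `discovery_run`.
#' @param ... Unused.
#' @return A ggplot: variants surviving each filtering stage.
#' @export
autoplot.discovery_run <- function(object, ...) {
  df <- object$stages
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot(df, aes(x = .data$stage, y = .data$n_out)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "variants retained",
         title = "Candidate attrition by filtering stage") +
    theme_minimal()
}

#' Genotype counts by founder-tie class
#'
#' @param object A `genotype_report`.
#' @param ... Unused.
#' @return A ggplot: genotype counts per tie class, faceted by cohort.
#' @export
autoplot.genotype_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$cells, cols = all_of(GT_LEVELS),
                            names_to = "genotype", values_to = "n")
  df$genotype <- factor(df$genotype, levels = GT_LEVELS)
  ggplot(df, aes(x = .data$tie_class, y = .data$n, fill = .data$genotype)) +
    geom_col(position = "dodge") +
    facet_wrap(~cohort) +
    labs(x = "founder tie", y = "animals",
         title = "Validation genotypes by pedigree tie to the founder") +
    theme_minimal()
}

#' Plot shared-homozygosity regions along a chromosome
#'
#' @param regions Region tibble from [shared_homozygosity_regions()].
#' @param truth_interval Optional length-2 numeric (start, end) of a known
#'   seeded interval, drawn as a shaded band.
#' @return A ggplot of region extents per chromosome.
#' @export
plot_roh <- function(regions, truth_interval = NULL) {
  p <- ggplot(regions)
  if (!is.null(truth_interval)) {
    p <- p + geom_rect(
      xmin = truth_interval[1] / 1e6, xmax = truth_interval[2] / 1e6,
      ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.3
    )
  }
  p +
    geom_segment(aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                     y = .data$chrom, yend = .data$chrom),
                 linewidth = 3, colour = "firebrick") +
    labs(x = "position (Mb)", y = "chromosome",
         title = "Runs of homozygosity shared by affected animals") +
    theme_minimal()
}
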