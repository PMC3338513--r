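#' Plot a chromosome-walk relatedness profile
#'
#' Observed related-pair counts by span, optionally against the
#' permuted-genome baseline, one panel per dataset.
#'
#' @param profile a `walk_profile` from [relatedness_profile()].
#' @param baseline optional `walk_baseline` from [permutation_baseline()].
#' @return a ggplot object.
#' @export
plot_walk_profile <- function(profile, baseline = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$span, y = .data$count)) +
    ggplot2::geom_line(ggplot2::aes(colour = "observed")) +
    ggplot2::facet_wrap(~dataset, scales = "free_y") +
    ggplot2::labs(
      x = "span n (2 = adjacent)", y = "related gene pairs",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_line(
      data = baseline,
      ggplot2::aes(y = .data$mean_count, colour = "permuted"),
    )
  }
  p
}

#' @export
autoplot.walk_profile <- function(object, ...) plot_walk_profile(object, ...)

#' Plot the paracluster-size distribution
#'
#' Gene counts (including and excluding interstitial genes) by paracluster
#' size, size measured as the number of paralog members.
#'
#' @param metrics a `genome_summary` from [genome_metrics()].
#' @return a ggplot object.
#' @export
plot_size_distribution <- function(metrics) {
  sd <- metrics$size_distribution |>
    tidyr::pivot_longer(
      c("genes_incl_interstitial", "genes_excl_interstitial"),
      names_to = "counting", values_to = "genes"
    )
  ggplot2::ggplot(sd, ggplot2::aes(
    x = factor(.data$size), y = .data$genes, fill = .data$counting
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "paracluster size (paralog members)", y = "genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.genome_summary <- function(object, ...) plot_size_distribution(object)

#' Plot a threshold or gap sweep
#'
#' Total clustered genes as a function of the swept parameter, one line per
#' dataset plus the merged total.
#'
#' @param sweep output of [threshold_sweep()] or [gap_sweep()].
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep) {
  xvar <- if ("threshold" %in% names(sweep)) "threshold" else "max_gap"
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data[[xvar]], y = .data$genes_in_paraclusters,
    colour = .data$dataset
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = "genes in paraclusters") +
    ggplot2::theme_minimal()
}
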