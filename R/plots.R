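#' @importFrom ggplot2 ggplot aes autoplot geom_line geom_point geom_col
#'   geom_hline labs facet_wrap theme_minimal
NULL

#' Plot an LD-decay curve
#'
#' @param object An [ld_decay_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ld_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$dist_mid / 1e3, y = .data$mean_r2)) +
    geom_line(colour = "steelblue") +
    facet_wrap(~chrom) +
    labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    theme_minimal()
}

#' Plot per-sample mismatch percentages
#'
#' @param object A [cross_platform_report()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mismatch_report <- function(object, ...) {
  ggplot(object$per_sample, aes(
    x = stats::reorder(.data$sample_id, .data$pct_zygosity),
    y = .data$pct_zygosity, fill = .data$population
  )) +
    geom_col() +
    geom_hline(yintercept = object$overall_mean, linetype = 2) +
    labs(x = NULL, y = "zygosity mismatch (%)", fill = "population") +
    theme_minimal() +
    ggplot2::coord_flip()
}

#' Plot the bootstrap distribution of an FST estimate
#'
#' @param object A [wc_fst()] result with bootstrap replicates.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fst_result <- function(object, ...) {
  if (!length(object$boot)) abort("no bootstrap replicates to plot.")
  ggplot(tibble(theta = object$boot), aes(x = .data$theta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$theta, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = 2) +
    labs(x = expression(hat(theta)), y = "bootstrap replicates") +
    theme_minimal()
}
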