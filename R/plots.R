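# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_step
#'   labs theme_minimal facet_wrap scale_y_continuous autoplot
NULL

#' Plot a precision-recall curve
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$recall, y = .data$precision)) +
    geom_step(direction = "vh") +
    geom_point(size = 1) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(
      title = sprintf("AUPR = %.3f (precision %.3f, recall %.3f)",
                      object$aupr, object$precision, object$recall),
      x = "recall", y = "precision"
    ) +
    theme_minimal()
}

#' Plot a community profile as a composition bar
#'
#' Taxa at or below `others_cutoff` relative abundance are folded into a
#' single "others" bar segment.
#'
#' @param object A `community_profile`.
#' @param others_cutoff Fraction below-or-at which taxa are folded (default
#'   2%).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot community_profile
#' @export
autoplot.community_profile <- function(object, others_cutoff = 0.02, ...) {
  ra <- collapse_others(relative_abundance(object), others_cutoff)
  ra$label <- ifelse(is.na(ra$name) | ra$name == "",
                     as.character(ra$tax_id), ra$name)
  ra$label <- factor(ra$label, levels = ra$label[order(-ra$fraction)])
  ggplot(ra, aes(x = "sample", y = .data$fraction, fill = .data$label)) +
    geom_col() +
    labs(x = NULL, y = "relative abundance", fill = attr(object, "rank")) +
    theme_minimal()
}

#' Plot a classifier score-threshold sweep
#'
#' Retained-read counts of the classifier-only and alignment-verified series
#' against the minimum classifier score (the output of
#' [score_threshold_sweep()]).
#'
#' @param sweep Tibble from [score_threshold_sweep()].
#' @return A ggplot.
#' @export
plot_score_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    sweep[c("threshold", "retained_classifier", "retained_verified")],
    -"threshold", names_to = "series", values_to = "retained",
    names_prefix = "retained_")
  ggplot(long, aes(x = .data$threshold, y = .data$retained,
                   colour = .data$series)) +
    geom_line() + geom_point() +
    labs(x = "minimum classifier score", y = "reads retained",
         colour = NULL) +
    theme_minimal()
}

#' Plot an AS/Cov threshold grid
#'
#' Precision, recall and AUPR as lines over the alignment-score grid,
#' faceted by coverage threshold (the output of [grid_sweep()]).
#'
#' @param grid Tibble from [grid_sweep()].
#' @return A ggplot.
#' @export
plot_grid_sweep <- function(grid) {
  long <- tidyr::pivot_longer(
    grid[c("min_alignment_score", "min_coverage_pct", "precision", "recall",
           "aupr")],
    c("precision", "recall", "aupr"),
    names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$min_alignment_score, y = .data$value,
                   colour = .data$metric)) +
    geom_line() + geom_point() +
    facet_wrap(~min_coverage_pct, labeller = ggplot2::label_both) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "minimum alignment score (AS)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot hit-ratio diagnostics
#'
#' Candidate-count versus hit-length/query-length ratio for each read, the
#' view used to justify the multi-match cutoff.
#'
#' @param diag Output of [hit_ratio_diagnostics()].
#' @param max_matches Cutoff drawn as a horizontal reference line.
#' @return A ggplot.
#' @export
plot_hit_ratio <- function(diag, max_matches = 50L) {
  ggplot(diag$reads, aes(x = .data$hit_ratio, y = .data$num_matches)) +
    geom_point(alpha = 0.4, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = max_matches, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    labs(x = "hit length / query length ratio",
         y = "candidate taxa per read") +
    theme_minimal()
}
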