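# ggplot2 helpers for the main result types.

#' Precision-recall curve of a detector evaluation
#'
#' @param ap_result result of [average_precision()].
#' @return A ggplot.
#' @export
plot_pr_curve <- function(ap_result) {
  cv <- ap_result$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = recall, y = precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("AP = %.3f", ap_result$ap),
                  x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' Segmenter benchmark summary plot
#'
#' @param grid result of [run_segmenter_grid()].
#' @return A ggplot of AO per segmenter and condition.
#' @export
plot_segmenter_grid <- function(grid) {
  grid$condition <- ifelse(grid$guide == "degraded", "degraded guide",
                           sprintf("jitter %.1f um", grid$jitter_um))
  ggplot2::ggplot(grid, ggplot2::aes(x = condition, y = ao, fill = segmenter)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "average overlap (AO)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' DNA content histogram coloured by EdU status
#'
#' @param records per-cell tibble with `c_value` and `edu_pos`.
#' @param binwidth histogram bin width on the C-value scale.
#' @return A ggplot.
#' @export
plot_dna_histogram <- function(records, binwidth = 0.1) {
  records$EdU <- ifelse(records$edu_pos, "EdU+", "EdU-")
  ggplot2::ggplot(records, ggplot2::aes(x = c_value, fill = EdU)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(2, 4), linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "DNA content (C)", y = "cells") +
    ggplot2::theme_minimal()
}

#' Phase indices along the distal-proximal axis
#'
#' @param indices per-bin tibble from [phase_indices()].
#' @return A stacked-proportion ggplot.
#' @export
plot_phase_indices <- function(indices) {
  long <- do.call(rbind, lapply(c("G1", "S", "G2M", "M"), function(ph)
    tibble::tibble(bin = indices$bin, phase = ph, index = indices[[ph]])))
  ggplot2::ggplot(long, ggplot2::aes(x = bin, y = index, fill = phase)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cell row bin", y = "phase index") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phase_classifiers <- function(object, ...) {
  tab <- object$repeats
  long <- rbind(
    tibble::tibble(phase = tab$phase, metric = "sensitivity", value = tab$sensitivity),
    tibble::tibble(phase = tab$phase, metric = "specificity", value = tab$specificity))
  ggplot2::ggplot(long, ggplot2::aes(x = phase, y = value, colour = metric)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0.66, linetype = 2) +
    ggplot2::labs(y = "classification performance") +
    ggplot2::theme_minimal()
}
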