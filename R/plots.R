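# Base-graphics diagnostic plots.

#' Plot a recency curve
#'
#' @param curve output of [recency_curve()] (or a list of them, averaged).
#' @param ... passed to [graphics::plot()].
#' @export
plot_recency_curve <- function(curve, ...) {
  if (is.list(curve)) curve <- Reduce(`+`, curve) / length(curve)
  k <- length(curve)
  graphics::plot(rev(seq_len(k)), rev(curve), type = "b", pch = 16,
                 xlab = "fixations before decision",
                 ylab = "P(fixation on chosen option)",
                 ylim = c(0.3, 1), xaxt = "n", ...)
  graphics::axis(1, at = seq_len(k), labels = rev(seq_len(k)))
  graphics::abline(h = 0.5, lty = 3)
  invisible(curve)
}

#' Plot Vincentized decision-time quantiles
#'
#' @param q named quantile vector from [vincentized_quantiles()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_vincentized_quantiles <- function(q, ...) {
  probs <- as.numeric(sub("^q", "", names(q)))
  graphics::plot(q, probs, type = "b", pch = 16,
                 xlab = "decision time (fixations)",
                 ylab = "cumulative probability", ...)
  invisible(q)
}
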