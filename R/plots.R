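#' Trace plot of a fitted chain
#'
#' Log-likelihood and log-posterior against iteration, with the burn-in
#' boundary marked. A stabilizing, upward-trending curve indicates
#' convergence of the sampler.
#'
#' @param object An `hm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hm_fit
#' @export
autoplot.hm_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$scalars[, c("iteration", "log_lik", "log_post")],
                           -"iteration", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$burn_in + 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Chain trace (dashed line: end of burn-in)")
}

#' @rdname autoplot.hm_fit
#' @method autoplot hm_scan
#' @export
autoplot.hm_scan <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$second_len, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$results[object$results$second_len == object$best, ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "candidate second-motif length",
                  y = "held-out label accuracy")
}

#' Plot a position-specific probability matrix
#'
#' Stacked per-position letter probabilities of one of the estimated motifs
#' (a simple alternative to a sequence logo; letters with probability below
#' `min_prob` are left unlabelled).
#'
#' @param x An `hm_fit` object or a K x J column-stochastic matrix with
#'   letter rownames.
#' @param which For a fit: `"first"`, `"second"` or `"background"`.
#' @param min_prob Minimum probability for a letter label to be drawn.
#' @return A ggplot object.
#' @export
plot_motif <- function(x, which = c("first", "second", "background"),
                       min_prob = 0.05) {
  if (inherits(x, "hm_fit")) {
    which <- match.arg(which)
    d <- dplyr::filter(tidy.hm_fit(x), .data$motif == which)
  } else {
    mat <- as.matrix(x)
    if (is.null(rownames(mat))) stop("matrix must have letter rownames")
    d <- tibble::tibble(position = rep(seq_len(ncol(mat)), each = nrow(mat)),
                        letter = rep(rownames(mat), ncol(mat)),
                        prob = as.vector(mat))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$position), y = .data$prob,
                                  fill = .data$letter)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$prob >= min_prob, .data$letter, "")),
                       position = ggplot2::position_stack(vjust = 0.5), size = 3) +
    ggplot2::labs(x = "motif position", y = "probability")
}
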