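#' Predict held-out binding labels at the MAP estimate
#'
#' For each held-out index (a `g` label masked to `NA` before fitting), the
#' prediction is the `g` value of the MAP snapshot. Accuracy against the
#' held-out truths is attached as an attribute and is the criterion used for
#' motif-length selection.
#'
#' @param fit An `hm_fit` object.
#' @param held_out Tibble with columns `index` and `truth`, as returned by
#'   [mask_known_g()].
#' @return A tibble with columns `index`, `truth`, `estimate`, `correct`,
#'   with attribute `accuracy` (fraction correct).
#' @export
predict_masked_labels <- function(fit, held_out) {
  stopifnot(inherits(fit, "hm_fit"))
  if (nrow(held_out) == 0) stop("the hold-out set is empty; accuracy is undefined")
  if (!all(held_out$index %in% fit$problem$unknown_g)) {
    stop("every held-out index must have been masked (NA) before fitting")
  }
  est <- fit$map$g[held_out$index]
  out <- tibble::tibble(index = held_out$index,
                        truth = as.integer(held_out$truth),
                        estimate = as.integer(est),
                        correct = est == held_out$truth)
  attr(out, "accuracy") <- mean(out$correct)
  out
}

#' Masked-label prediction accuracy
#'
#' @inheritParams predict_masked_labels
#' @return The fraction of held-out `g` labels predicted correctly.
#' @export
masked_label_accuracy <- function(fit, held_out) {
  attr(predict_masked_labels(fit, held_out), "accuracy")
}

#' Select the second motif length by held-out label accuracy
#'
#' Masks a fraction of the known `g` labels once (the same masked set is
#' reused for every candidate, for comparability), fits the model for each
#' candidate second-motif length, and scores the masked-label predictions at
#' the MAP estimate. The selected length is the accuracy argmax, with ties
#' broken towards the smaller length.
#'
#' @param data Data frame with columns `seq`, `w`, `g` (0/1/`NA`).
#' @param first_len Fixed first-motif length.
#' @param candidates Integer vector of candidate second-motif lengths.
#' @param mask_fraction Fraction of known `g` labels to hold out.
#' @param seed Optional seed controlling both the masking and every chain.
#' @param ... Further arguments passed to [decompose_motifs()]
#'   (e.g. `iterations`, `alphabet`).
#' @return An object of class `hm_scan`: a list with `results` (tibble of
#'   `second_len`, `accuracy`), `best` (selected length) and `held_out`.
#' @export
scan_second_length <- function(data, first_len = 9, candidates = 2:9,
                               mask_fraction = 0.2, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  candidates <- sort(unique(as.integer(candidates)))
  masked <- mask_known_g(data, mask_fraction)
  if (nrow(masked$held_out) == 0) stop("no known `g` labels available to hold out")
  chain_seeds <- sample.int(.Machine$integer.max, length(candidates))
  acc <- vapply(seq_along(candidates), function(k) {
    fit <- decompose_motifs(masked$data, first_len = first_len,
                            second_len = candidates[k], seed = chain_seeds[k], ...)
    masked_label_accuracy(fit, masked$held_out)
  }, numeric(1))
  results <- tibble::tibble(second_len = candidates, accuracy = acc)
  structure(list(results = results,
                 best = candidates[which.max(acc)],  # first max = smallest length
                 held_out = masked$held_out),
            class = "hm_scan")
}

#' @export
print.hm_scan <- function(x, ...) {
  cat(sprintf("<hm_scan> selected second-motif length: %d\n", x$best))
  print(x$results)
  invisible(x)
}

# Normalized L1 error: mean absolute elementwise difference.
normalized_l1 <- function(est, truth) mean(abs(est - truth))

#' Evaluate a fitted chain against simulation truth
#'
#' Computes, per iteration: the normalized L1 errors (average absolute error
#' per element) of the background and the two motif matrices against the
#' generating values; the accuracy of the latent `g` labels over the
#' originally masked entries; the exact-start accuracies of the two binding
#' position vectors, counted over the sequences whose true label makes the
#' position identifiable (`w = 1` for the first, `g = 1` for the second); and
#' the log likelihood. A `map` attribute holds the same metrics at the MAP
#' snapshot, and an `alignment` attribute reports whether shifting the
#' estimated second motif by one column would fit the truth better (a
#' diagnostic for unresolved shift modes; no realignment is applied).
#'
#' @param fit An `hm_fit` object.
#' @param truth The `truth` component of an [sim_hier_motifs()] object (or a
#'   compatible list).
#' @return A tibble with columns `iteration`, `error_theta0`, `error_first`,
#'   `error_second`, `acc_g`, `acc_a`, `acc_b`, `log_lik`.
#' @export
recovery_metrics <- function(fit, truth) {
  stopifnot(inherits(fit, "hm_fit"))
  p <- fit$problem
  if (length(truth$theta0) != p$K ||
      !all(dim(truth$first_motif) == c(p$K, p$J)) ||
      !all(dim(truth$second_motif) == c(p$K, p$J2))) {
    stop("dimensions of `truth` do not match the fitted model")
  }
  masked_g <- intersect(truth$masked_g, p$unknown_g)
  w1 <- which(truth$w == 1)
  g1 <- which(truth$g == 1)

  one <- function(snap) {
    c(error_theta0 = normalized_l1(snap$theta0, truth$theta0),
      error_first = normalized_l1(snap$Theta1, truth$first_motif),
      error_second = normalized_l1(snap$Theta2, truth$second_motif),
      acc_g = if (length(masked_g)) mean(snap$g[masked_g] == truth$g[masked_g]) else NA_real_,
      acc_a = if (length(w1)) mean(snap$a[w1] == truth$a_start[w1]) else NA_real_,
      acc_b = if (length(g1)) mean(snap$b[g1] == truth$b_start[g1]) else NA_real_)
  }
  m <- t(vapply(fit$trace, one, numeric(6)))
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, iteration = seq_len(fit$iterations), .before = 1)
  out$log_lik <- fit$scalars$log_lik

  if (fit$iterations > 0) {
    attr(out, "map") <- one(fit$map)
    attr(out, "alignment") <- shift_alignment_check(fit$map$Theta2, truth$second_motif)
  }
  out
}

# Diagnostic: would a +/-1 column shift of the estimate fit the truth better?
shift_alignment_check <- function(est, truth) {
  J <- ncol(est)
  if (J < 2) return(list(shift = 0L, improved = FALSE))
  err0 <- normalized_l1(est, truth)
  errm <- normalized_l1(est[, -1, drop = FALSE], truth[, -J, drop = FALSE])
  errp <- normalized_l1(est[, -J, drop = FALSE], truth[, -1, drop = FALSE])
  errs <- c(`-1` = errm, `0` = err0, `1` = errp)
  best <- c(-1L, 0L, 1L)[which.min(errs)]
  list(shift = best, improved = best != 0L, errors = errs)
}
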