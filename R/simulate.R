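#' Simulate sequences with two planted hierarchical motifs
#'
#' Generates a synthetic dataset from the generative model: a background
#' distribution drawn from Dirichlet(1), each first-motif column from a
#' symmetric Dirichlet(`eta`) and each second-motif column from
#' Dirichlet(`gamma`) (small concentrations give strongly conserved motifs),
#' binding starts uniform over each sequence's valid range, binding labels
#' `w` and `g` Bernoulli(`label_prob`), and residues drawn per the four-case
#' model with the second motif taking precedence at overlapping positions.
#' Afterwards each `g` label is masked to `NA` with probability `miss_g_w1`
#' when `w = 1` and `miss_g_w0` when `w = 0`, emulating that evidence about
#' the downstream binding is rarely collected when the upstream binding
#' failed. `w` is never masked unless `mask_w_prob > 0`.
#'
#' The defaults are the simulation conditions used throughout the package's
#' own evaluation: 200 sequences of length 15 over the amino-acid alphabet,
#' motif lengths 9 and 5, `eta = gamma = 0.05`, Bernoulli(0.3) labels,
#' 10% missing `g` among `w = 1` and fully missing `g` among `w = 0`.
#'
#' @param n Number of sequences.
#' @param len Common sequence length.
#' @param alphabet Passed to [motif_alphabet()].
#' @param first_len,second_len Motif lengths.
#' @param eta,gamma Symmetric Dirichlet concentrations for the first and
#'   second motif columns.
#' @param label_prob Bernoulli parameter for both labels.
#' @param miss_g_w1,miss_g_w0 Masking probabilities for `g` given `w = 1`
#'   resp. `w = 0`.
#' @param mask_w_prob Masking probability for `w` (default 0: `w` fully
#'   observed).
#' @param seed Optional integer seed for full reproducibility.
#' @return An object of class `hm_sim`: a list with `data` (tibble of
#'   `id`, `seq`, `w`, `g` as exposed to inference, `NA` = masked) and
#'   `truth` (list with the generating `theta0`, `first_motif`,
#'   `second_motif`, full `w`, `g`, `a_start`, `b_start`, and the masked
#'   index sets `masked_w`, `masked_g`).
#' @examples
#' sim <- sim_hier_motifs(n = 20, len = 10, first_len = 4, second_len = 3,
#'                        alphabet = "DNA", seed = 1)
#' sim$data
#' @export
sim_hier_motifs <- function(n = 200, len = 15, alphabet = "AA",
                            first_len = 9, second_len = 5,
                            eta = 0.05, gamma = 0.05,
                            label_prob = 0.3,
                            miss_g_w1 = 0.1, miss_g_w0 = 1,
                            mask_w_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, eta > 0, gamma > 0)
  if (label_prob < 0 || label_prob > 1) stop("`label_prob` must be in [0, 1]")
  for (v in c(miss_g_w1, miss_g_w0, mask_w_prob)) {
    if (v < 0 || v > 1) stop("masking probabilities must be in [0, 1]")
  }
  letters_out <- motif_alphabet(alphabet)
  K <- length(letters_out)
  J <- as.integer(first_len); J2 <- as.integer(second_len)
  if (len < max(J, J2)) stop("`len` must be at least the longer motif length")

  theta0 <- rdirichlet1(rep(1, K))
  Theta1 <- vapply(seq_len(J), function(j) rdirichlet1(rep(eta, K)), numeric(K))
  Theta2 <- vapply(seq_len(J2), function(j) rdirichlet1(rep(gamma, K)), numeric(K))

  w <- stats::rbinom(n, 1, label_prob)
  g <- stats::rbinom(n, 1, label_prob)
  a <- sample.int(len - J + 1, n, replace = TRUE)
  b <- sample.int(len - J2 + 1, n, replace = TRUE)

  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- sample.int(K, len, replace = TRUE, prob = theta0)
    if (w[i] == 1) {
      for (j in seq_len(J)) {
        s[a[i] + j - 1] <- sample.int(K, 1, prob = Theta1[, j])
      }
    }
    if (g[i] == 1) {  # second motif overrides any overlap
      for (j in seq_len(J2)) {
        s[b[i] + j - 1] <- sample.int(K, 1, prob = Theta2[, j])
      }
    }
    seqs[i] <- decode_seq(s, letters_out)
  }

  g_obs <- g
  mask_g <- stats::runif(n) < ifelse(w == 1, miss_g_w1, miss_g_w0)
  g_obs[mask_g] <- NA_integer_
  w_obs <- w
  mask_w <- if (mask_w_prob > 0) stats::runif(n) < mask_w_prob else rep(FALSE, n)
  w_obs[mask_w] <- NA_integer_

  structure(list(
    data = tibble::tibble(id = paste0("seq", seq_len(n)), seq = seqs,
                          w = w_obs, g = g_obs),
    truth = list(theta0 = theta0, first_motif = Theta1, second_motif = Theta2,
                 w = w, g = g, a_start = a, b_start = b,
                 masked_w = which(mask_w), masked_g = which(mask_g),
                 alphabet = letters_out, first_len = J, second_len = J2)
  ), class = "hm_sim")
}

#' @export
print.hm_sim <- function(x, ...) {
  cat(sprintf("<hm_sim> %d sequences, K = %d, motif lengths %d / %d\n",
              nrow(x$data), length(x$truth$theta0),
              x$truth$first_len, x$truth$second_len))
  cat(sprintf("  labels: %d w = 1, %d g = 1; masked: %d w, %d g\n",
              sum(x$truth$w), sum(x$truth$g),
              length(x$truth$masked_w), length(x$truth$masked_g)))
  invisible(x)
}

#' Mask a fraction of the known second labels
#'
#' Turns an exact `ceiling(fraction * #known)`-sized uniformly random subset
#' of the known `g` labels into `NA`, returning both the masked data and the
#' held-out truths for later accuracy scoring. This is the hold-out device
#' used for motif-length selection: predictions of the masked labels at the
#' MAP estimate are scored against the held-out values.
#'
#' @param data Data frame with columns `seq`, `w`, `g` (and optionally `id`).
#' @param fraction Fraction of the known `g` labels to mask, in \[0, 1\].
#' @param seed Optional seed.
#' @return A list with `data` (the masked tibble) and `held_out`, a tibble of
#'   `index` (row number) and `truth` (the hidden 0/1 value).
#' @export
mask_known_g <- function(data, fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]")
  data <- tibble::as_tibble(data)
  known <- which(!is.na(data$g))
  n_mask <- ceiling(fraction * length(known))
  idx <- if (n_mask > 0) sort(sample(known, n_mask)) else integer(0)
  held_out <- tibble::tibble(index = idx, truth = as.integer(data$g[idx]))
  data$g[idx] <- NA_integer_
  list(data = data, held_out = held_out)
}
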