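# Full-conditional Gibbs updates. All categorical/Bernoulli posteriors are
# normalized in log space (log-sum-exp) before drawing.

#' Draw a motif column from its Dirichlet full conditional
#'
#' The conjugate update for a motif column (or the background vector):
#' a draw from Dirichlet(`h + alpha`).
#'
#' @param h Non-negative letter-count vector (length K).
#' @param alpha Strictly positive hyperparameter vector (length K).
#' @return A probability vector of length K.
#' @export
sample_theta <- function(h, alpha) {
  if (length(h) != length(alpha)) stop("`h` and `alpha` must have equal length")
  if (any(alpha <= 0)) stop("`alpha` must be strictly positive")
  if (any(h < 0)) stop("counts must be non-negative")
  rdirichlet1(h + alpha)
}

# --- label conditionals ------------------------------------------------------

# Posterior probability that label w_i = 1, holding g_i, a_i, b_i and the
# parameters at their current values. Two-term normalization of
# f(w = x) = case likelihood x Bernoulli(p0) prior.
label_posterior_w <- function(p, st, i) {
  s <- p$seqs[[i]]
  l1 <- ll_seq(s, 1L, st$g[i], st$a[i], st$b[i], p$J, p$J2, st$lt0, st$lT1, st$lT2) + log(p$p0)
  l0 <- ll_seq(s, 0L, st$g[i], st$a[i], st$b[i], p$J, p$J2, st$lt0, st$lT1, st$lT2) + log(1 - p$p0)
  1 / (1 + exp(l0 - l1))
}

label_posterior_g <- function(p, st, i) {
  s <- p$seqs[[i]]
  l1 <- ll_seq(s, st$w[i], 1L, st$a[i], st$b[i], p$J, p$J2, st$lt0, st$lT1, st$lT2) + log(p$p0)
  l0 <- ll_seq(s, st$w[i], 0L, st$a[i], st$b[i], p$J, p$J2, st$lt0, st$lT1, st$lT2) + log(1 - p$p0)
  1 / (1 + exp(l0 - l1))
}

#' Resample one unknown binding label
#'
#' Draws `w[i]` (or `g[i]`) from its Bernoulli full conditional, conditioning
#' on the other label's current value, the current binding positions and the
#' current parameters. Only indices whose label is unknown may be resampled.
#'
#' @param problem An [motif_problem()] object.
#' @param state A sampler state (see [initialize_state()]).
#' @param i Sequence index; must belong to the unknown-label set.
#' @return The updated state.
#' @export
sample_label_w <- function(problem, state, i) {
  if (!(i %in% problem$unknown_w)) stop("label w is known for sequence ", i)
  state$w[i] <- stats::rbinom(1, 1, label_posterior_w(problem, state, i))
  state
}

#' @rdname sample_label_w
#' @export
sample_label_g <- function(problem, state, i) {
  if (!(i %in% problem$unknown_g)) stop("label g is known for sequence ", i)
  state$g[i] <- stats::rbinom(1, 1, label_posterior_g(problem, state, i))
  state
}

# --- position conditionals ---------------------------------------------------

# Normalized posterior over first-binding starts for sequence i, holding the
# labels, the second-binding window and the parameters fixed. When w_i = 0 the
# likelihood does not involve a_i and the conditional reduces to the uniform
# prior over valid starts.
position_posterior_a <- function(p, st, i) {
  s <- p$seqs[[i]]
  ncand <- p$len[i] - p$J + 1
  if (st$w[i] == 0) return(rep(1 / ncand, ncand))
  pos <- outer(seq_len(p$J) - 1L, seq_len(ncand), `+`)  # J x ncand positions
  lets <- s[pos]
  delta <- st$lT1[cbind(as.vector(lets), rep(seq_len(p$J), ncand))] -
    st$lt0[as.vector(lets)]
  dim(delta) <- dim(pos)
  if (st$g[i] == 1) {
    inb <- pos >= st$b[i] & pos <= st$b[i] + p$J2 - 1
    delta[inb] <- 0  # overlapping positions are governed by the second motif
  }
  lw <- colSums(delta)
  pr <- exp(lw - logsumexp(lw))
  pr / sum(pr)
}

position_posterior_b <- function(p, st, i) {
  s <- p$seqs[[i]]
  ncand <- p$len[i] - p$J2 + 1
  if (st$g[i] == 0) return(rep(1 / ncand, ncand))
  pos <- outer(seq_len(p$J2) - 1L, seq_len(ncand), `+`)
  lets <- s[pos]
  delta2 <- st$lT2[cbind(as.vector(lets), rep(seq_len(p$J2), ncand))] -
    st$lt0[as.vector(lets)]
  dim(delta2) <- dim(pos)
  lw <- colSums(delta2)
  if (st$w[i] == 1) {
    # first-motif contribution over a-positions outside the candidate window
    apos <- st$a[i]:(st$a[i] + p$J - 1)
    d1 <- st$lT1[cbind(s[apos], seq_len(p$J))] - st$lt0[s[apos]]
    cand <- seq_len(ncand)
    ina <- outer(apos, cand, function(ap, x) ap >= x & ap <= x + p$J2 - 1)
    lw <- lw + sum(d1) - as.vector(crossprod(d1, ina))
  }
  pr <- exp(lw - logsumexp(lw))
  pr / sum(pr)
}

#' Resample one binding start position
#'
#' Draws `a[i]` (or `b[i]`) from its categorical full conditional over the
#' valid 1-based starts, holding labels, the other window and the parameters
#' fixed. If the relevant label is 0 the draw is uniform over valid starts.
#'
#' @inheritParams sample_label_w
#' @return The updated state.
#' @export
sample_position_a <- function(problem, state, i) {
  pr <- position_posterior_a(problem, state, i)
  state$a[i] <- sample.int(length(pr), 1, prob = pr)
  state
}

#' @rdname sample_position_a
#' @export
sample_position_b <- function(problem, state, i) {
  pr <- position_posterior_b(problem, state, i)
  state$b[i] <- sample.int(length(pr), 1, prob = pr)
  state
}

# --- one sweep ---------------------------------------------------------------

# One systematic-scan Gibbs sweep in the fixed order
# W_U, G_~U, A, B, Theta, Theta~, theta0.
gibbs_sweep <- function(p, st) {
  for (i in p$unknown_w) st <- sample_label_w(p, st, i)
  for (i in p$unknown_g) st <- sample_label_g(p, st, i)
  for (i in seq_len(p$n)) st <- sample_position_a(p, st, i)
  for (i in seq_len(p$n)) st <- sample_position_b(p, st, i)
  cnt <- motif_counts(p, st$w, st$g, st$a, st$b)
  for (j in seq_len(p$J)) st$Theta1[, j] <- sample_theta(cnt$first[, j], p$alpha1[, j])
  for (j in seq_len(p$J2)) st$Theta2[, j] <- sample_theta(cnt$second[, j], p$alpha2[, j])
  st$theta0 <- sample_theta(cnt$background, p$alpha0)
  state_refresh_logs(st)
}
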