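# Grouped Metropolis-Hastings shift moves. Motif samplers are prone to
# settling in a mode translated by one position from the truth; because the
# positions, the motif matrix and the unknown labels are tightly coupled,
# shifting the positions alone is almost never accepted. Each move therefore
# proposes, jointly: all binding starts shifted by a common delta of -1 or +1
# (probability 1/2 each), a motif matrix regenerated from the counts at the
# shifted positions, and unknown labels regenerated from their two-point
# conditionals under the shifted motif. The proposal is accepted with the
# usual MH probability.
#
# Boundary handling: binding starts are also maintained for sequences whose
# current labels make them likelihood-irrelevant (their full conditional is
# the uniform prior), and with many such rows some always sit at a boundary,
# so a plain translation of every row would almost never stay in range and
# the move could never fire. The shift is therefore cyclic: each row wraps
# within its own valid start range. This is a label-independent bijection
# that the reverse shift (-delta) undoes exactly, so the proposal stays
# symmetric in the positions; wrapping is immaterial for irrelevant rows
# (uniform conditional), and a wrapped binding-relevant row usually costs
# likelihood, so harmful shifts are still rejected by the MH ratio.

# Two-point label proposal densities f* under hypothetical (a, Theta) for the
# first move (or (b, Theta2) for the second). Returns P(label = 1).
f_star_w <- function(p, st, i, a1, lT1) {
  s <- p$seqs[[i]]
  l1 <- ll_seq(s, 1L, st$g[i], a1, st$b[i], p$J, p$J2, st$lt0, lT1, st$lT2) + log(p$p0)
  l0 <- ll_seq(s, 0L, st$g[i], a1, st$b[i], p$J, p$J2, st$lt0, lT1, st$lT2) + log(1 - p$p0)
  1 / (1 + exp(l0 - l1))
}

f_star_g <- function(p, st, i, b1, lT2) {
  s <- p$seqs[[i]]
  l1 <- ll_seq(s, st$w[i], 1L, st$a[i], b1, p$J, p$J2, st$lt0, st$lT1, lT2) + log(p$p0)
  l0 <- ll_seq(s, st$w[i], 0L, st$a[i], b1, p$J, p$J2, st$lt0, st$lT1, lT2) + log(1 - p$p0)
  1 / (1 + exp(l0 - l1))
}

# log Bernoulli mass of value x under P(x = 1) = pr
lbern <- function(x, pr) ifelse(x == 1, log(pr), log1p(-pr))

# Cyclic shift of 1-based starts within per-row valid ranges.
wrap_shift <- function(start, delta, ncand) {
  as.integer((start + delta - 1L) %% ncand + 1L)
}

#' Grouped shift move for the first binding process
#'
#' Proposes a common translation `a* = a + delta` of every binding start
#' (`delta` drawn uniformly from -1/+1, rows wrapping cyclically within their
#' valid range), regenerates each first-motif column from
#' Dirichlet(counts at the shifted positions + alpha), regenerates every
#' unknown `w` from its two-point conditional under the shifted motif, and
#' accepts or rejects the three blocks jointly by the Metropolis-Hastings
#' ratio. `shift_move_second()` is the mirror image acting on `b`, the second
#' motif and the unknown `g` labels.
#'
#' @inheritParams sample_label_w
#' @return A list with `state` (updated or unchanged), `accepted` (logical)
#'   and `delta`.
#' @export
shift_move_first <- function(problem, state) {
  p <- problem; st <- state
  delta <- sample(c(-1L, 1L), 1)
  a_new <- wrap_shift(st$a, delta, p$len - p$J + 1L)

  # proposed Theta1 from shifted-position counts under the current labels
  cnt_new <- motif_counts(p, st$w, st$g, a_new, st$b)
  Theta1_new <- vapply(seq_len(p$J),
                       function(j) rdirichlet1(cnt_new$first[, j] + p$alpha1[, j]),
                       numeric(p$K))
  lT1_new <- log(Theta1_new)

  # proposed unknown labels under (a*, Theta1*)
  w_new <- st$w
  lq_fwd_lab <- 0
  for (i in p$unknown_w) {
    pr <- f_star_w(p, st, i, a_new[i], lT1_new)
    w_new[i] <- stats::rbinom(1, 1, pr)
    lq_fwd_lab <- lq_fwd_lab + lbern(w_new[i], pr)
  }

  st_new <- st
  st_new$a <- a_new; st_new$Theta1 <- Theta1_new; st_new$lT1 <- lT1_new
  st_new$w <- w_new

  # joint scores pi(.) = likelihood x priors on the shifted blocks
  # (position priors are uniform over identical ranges and cancel)
  block_prior <- function(s) {
    val <- 0
    for (j in seq_len(p$J)) val <- val + ldirichlet(s$Theta1[, j], p$alpha1[, j])
    if (length(p$unknown_w)) val <- val + sum(lbern(s$w[p$unknown_w], p$p0))
    val
  }
  lpi_new <- ll_state(p, st_new) + block_prior(st_new)
  lpi_old <- ll_state(p, st) + block_prior(st)

  # forward proposal density
  lq_fwd <- log(0.5) + lq_fwd_lab
  for (j in seq_len(p$J)) {
    lq_fwd <- lq_fwd + ldirichlet(Theta1_new[, j], cnt_new$first[, j] + p$alpha1[, j])
  }
  # reverse proposal: regenerate the current state from the proposed one
  # (reverse delta, counts at the current positions under the proposed labels)
  cnt_rev <- motif_counts(p, w_new, st$g, st$a, st$b)
  lq_rev <- log(0.5)
  for (j in seq_len(p$J)) {
    lq_rev <- lq_rev + ldirichlet(st$Theta1[, j], cnt_rev$first[, j] + p$alpha1[, j])
  }
  for (i in p$unknown_w) {
    pr <- f_star_w(p, st, i, st$a[i], st$lT1)
    lq_rev <- lq_rev + lbern(st$w[i], pr)
  }

  log_alpha <- (lpi_new - lpi_old) + (lq_rev - lq_fwd)
  if (log(stats::runif(1)) <= min(0, log_alpha)) {
    list(state = st_new, accepted = TRUE, delta = delta)
  } else {
    list(state = st, accepted = FALSE, delta = delta)
  }
}

#' @rdname shift_move_first
#' @export
shift_move_second <- function(problem, state) {
  p <- problem; st <- state
  delta <- sample(c(-1L, 1L), 1)
  b_new <- wrap_shift(st$b, delta, p$len - p$J2 + 1L)

  cnt_new <- motif_counts(p, st$w, st$g, st$a, b_new)
  Theta2_new <- vapply(seq_len(p$J2),
                       function(j) rdirichlet1(cnt_new$second[, j] + p$alpha2[, j]),
                       numeric(p$K))
  lT2_new <- log(Theta2_new)

  g_new <- st$g
  lq_fwd_lab <- 0
  for (i in p$unknown_g) {
    pr <- f_star_g(p, st, i, b_new[i], lT2_new)
    g_new[i] <- stats::rbinom(1, 1, pr)
    lq_fwd_lab <- lq_fwd_lab + lbern(g_new[i], pr)
  }

  st_new <- st
  st_new$b <- b_new; st_new$Theta2 <- Theta2_new; st_new$lT2 <- lT2_new
  st_new$g <- g_new

  block_prior <- function(s) {
    val <- 0
    for (j in seq_len(p$J2)) val <- val + ldirichlet(s$Theta2[, j], p$alpha2[, j])
    if (length(p$unknown_g)) val <- val + sum(lbern(s$g[p$unknown_g], p$p0))
    val
  }
  lpi_new <- ll_state(p, st_new) + block_prior(st_new)
  lpi_old <- ll_state(p, st) + block_prior(st)

  lq_fwd <- log(0.5) + lq_fwd_lab
  for (j in seq_len(p$J2)) {
    lq_fwd <- lq_fwd + ldirichlet(Theta2_new[, j], cnt_new$second[, j] + p$alpha2[, j])
  }
  cnt_rev <- motif_counts(p, st$w, g_new, st$a, st$b)
  lq_rev <- log(0.5)
  for (j in seq_len(p$J2)) {
    lq_rev <- lq_rev + ldirichlet(st$Theta2[, j], cnt_rev$second[, j] + p$alpha2[, j])
  }
  for (i in p$unknown_g) {
    pr <- f_star_g(p, st, i, st$b[i], st$lT2)
    lq_rev <- lq_rev + lbern(st$g[i], pr)
  }

  log_alpha <- (lpi_new - lpi_old) + (lq_rev - lq_fwd)
  if (log(stats::runif(1)) <= min(0, log_alpha)) {
    list(state = st_new, accepted = TRUE, delta = delta)
  } else {
    list(state = st, accepted = FALSE, delta = delta)
  }
}
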