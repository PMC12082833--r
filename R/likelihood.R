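# Observed-data likelihood for the four binding cases.
#
# Each sequence falls into one of four cases according to its labels (w, g):
#   (0,0) every residue from the background theta0;
#   (1,0) residues in the first binding window from the first motif columns;
#   (0,1) residues in the second binding window from the second motif columns;
#   (1,1) the second motif governs its whole window, and the first motif
#         governs only those first-window positions that fall outside it --
#         position a_j keeps column j of the first motif regardless of how
#         many positions overlap.

#' Count letters at a set of positions
#'
#' Tallies the residues of `sequence` at the given 1-based positions into a
#' length-K count vector ordered like the alphabet.
#'
#' @param sequence A single character string.
#' @param positions Integer vector of 1-based positions (a set; duplicates are
#'   counted as often as listed).
#' @param alphabet Passed to [motif_alphabet()].
#' @return Named integer vector of length K; the total equals
#'   `length(positions)`.
#' @examples
#' count_letters("TDLLQAC", 3:5, "AA")
#' @export
count_letters <- function(sequence, positions, alphabet = "AA") {
  letters_out <- motif_alphabet(alphabet)
  s <- encode_seq(sequence, letters_out)
  positions <- as.integer(positions)
  if (length(positions) && (min(positions) < 1 || max(positions) > length(s))) {
    stop("positions out of range for the sequence")
  }
  counts <- tabulate(s[positions], nbins = length(letters_out))
  stats::setNames(as.integer(counts), letters_out)
}

# Fast single-sequence log likelihood; s is an integer-coded sequence and
# lt0/lT1/lT2 are log parameters. Starts are assumed valid.
ll_seq <- function(s, w, g, a1, b1, J, J2, lt0, lT1, lT2) {
  val <- sum(lt0[s])
  if (g == 1) {
    bpos <- b1:(b1 + J2 - 1)
    lb <- s[bpos]
    val <- val + sum(lT2[cbind(lb, seq_len(J2))]) - sum(lt0[lb])
    if (w == 1) {
      apos <- a1:(a1 + J - 1)
      keep <- apos < b1 | apos > b1 + J2 - 1
      if (any(keep)) {
        la <- s[apos[keep]]
        val <- val + sum(lT1[cbind(la, which(keep))]) - sum(lt0[la])
      }
    }
  } else if (w == 1) {
    apos <- a1:(a1 + J - 1)
    la <- s[apos]
    val <- val + sum(lT1[cbind(la, seq_len(J))]) - sum(lt0[la])
  }
  val
}

#' Log likelihood of one sequence under its binding case
#'
#' Evaluates the log of the case likelihood selected by the labels `(w, g)`,
#' with the second motif taking precedence over the first at overlapping
#' positions.
#'
#' @inheritParams count_letters
#' @param w,g Binary labels for the first and second binding process.
#' @param a_start,b_start 1-based binding start positions; the windows
#'   `a_start:(a_start+J-1)` and `b_start:(b_start+J2-1)` must lie inside the
#'   sequence.
#' @param theta0 Background probability vector (length K).
#' @param first_motif,second_motif Column-stochastic K x J and K x J2
#'   position-specific probability matrices.
#' @return The log likelihood (a single number).
#' @examples
#' th <- rep(1 / 4, 4)
#' M <- matrix(1 / 4, 4, 2)
#' case_log_likelihood("ACGT", 0, 0, 1, 1, th, M, M, alphabet = "DNA")
#' @export
case_log_likelihood <- function(sequence, w, g, a_start, b_start,
                                theta0, first_motif, second_motif,
                                alphabet = "AA") {
  letters_out <- motif_alphabet(alphabet)
  s <- encode_seq(sequence, letters_out)
  if (!(w %in% c(0, 1)) || !(g %in% c(0, 1))) stop("labels w and g must be 0 or 1")
  J <- ncol(first_motif); J2 <- ncol(second_motif)
  if (a_start < 1 || a_start + J - 1 > length(s)) stop("invalid first-motif start")
  if (b_start < 1 || b_start + J2 - 1 > length(s)) stop("invalid second-motif start")
  ll_seq(s, w, g, as.integer(a_start), as.integer(b_start), J, J2,
         log(theta0), log(first_motif), log(second_motif))
}

#' Joint log likelihood of a fully labelled dataset
#'
#' Sum of [case_log_likelihood()] over all sequences. Every label must be
#' instantiated to 0/1 (during sampling, unknowns carry their current values).
#'
#' @param data Data frame with columns `seq`, `w`, `g` (all labels 0/1).
#' @param a_start,b_start Integer vectors of binding starts, one per sequence.
#' @inheritParams case_log_likelihood
#' @return The joint log likelihood.
#' @export
joint_log_likelihood <- function(data, a_start, b_start,
                                 theta0, first_motif, second_motif,
                                 alphabet = "AA") {
  if (anyNA(data$w) || anyNA(data$g)) stop("all labels must be instantiated to 0/1")
  sum(vapply(seq_len(nrow(data)), function(i) {
    case_log_likelihood(data$seq[[i]], data$w[[i]], data$g[[i]],
                        a_start[[i]], b_start[[i]],
                        theta0, first_motif, second_motif, alphabet)
  }, numeric(1)))
}

# Joint log likelihood of a problem/state pair (internal hot path).
ll_state <- function(p, st) {
  tot <- 0
  for (i in seq_len(p$n)) {
    tot <- tot + ll_seq(p$seqs[[i]], st$w[i], st$g[i], st$a[i], st$b[i],
                        p$J, p$J2, st$lt0, st$lT1, st$lT2)
  }
  tot
}

# Log posterior score used for MAP ranking: likelihood + Bernoulli prior on
# the unknown labels + Dirichlet priors on all parameter blocks + the uniform
# position priors (a constant, kept so the score is a complete joint density).
log_posterior <- function(p, st) {
  val <- ll_state(p, st)
  if (length(p$unknown_w)) {
    x <- st$w[p$unknown_w]
    val <- val + sum(x * log(p$p0) + (1 - x) * log(1 - p$p0))
  }
  if (length(p$unknown_g)) {
    x <- st$g[p$unknown_g]
    val <- val + sum(x * log(p$p0) + (1 - x) * log(1 - p$p0))
  }
  val <- val + ldirichlet(st$theta0, p$alpha0)
  for (j in seq_len(p$J)) val <- val + ldirichlet(st$Theta1[, j], p$alpha1[, j])
  for (j in seq_len(p$J2)) val <- val + ldirichlet(st$Theta2[, j], p$alpha2[, j])
  val - sum(log(p$len - p$J + 1)) - sum(log(p$len - p$J2 + 1))
}
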