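# Residue-count bookkeeping feeding the conjugate Dirichlet updates.

# Internal workhorse: counts for arbitrary hypothetical labels/positions.
# Returns list(first = K x J, second = K x J2, background = length K).
motif_counts <- function(p, w, g, a, b) {
  H1 <- matrix(0L, p$K, p$J)
  H2 <- matrix(0L, p$K, p$J2)
  H0 <- integer(p$K)
  j1 <- seq_len(p$J)
  j2 <- seq_len(p$J2)
  for (i in seq_len(p$n)) {
    s <- p$seqs[[i]]
    covered <- logical(length(s))
    if (g[i] == 1) {
      bpos <- b[i]:(b[i] + p$J2 - 1)
      idx <- cbind(s[bpos], j2)
      H2[idx] <- H2[idx] + 1L
      covered[bpos] <- TRUE
    }
    if (w[i] == 1) {
      apos <- a[i]:(a[i] + p$J - 1)
      keep <- !covered[apos]  # first-motif counts only off the second window
      if (any(keep)) {
        idx <- cbind(s[apos[keep]], j1[keep])
        H1[idx] <- H1[idx] + 1L
        covered[apos] <- TRUE
      } else covered[apos] <- TRUE
    }
    H0 <- H0 + tabulate(s[!covered], nbins = p$K)
  }
  list(first = H1, second = H2, background = H0)
}

#' Accumulate motif and background letter counts
#'
#' Tallies, across all sequences, the residues governed by each column of the
#' two motifs and by the background, under the current labels and binding
#' positions. Column j of the first motif collects letters at the j-th
#' first-window position for sequences with `w = 1`, skipping positions that
#' fall inside the second window when `g = 1`; column j of the second motif
#' collects letters at the j-th second-window position for all sequences with
#' `g = 1`; every remaining residue (including whole sequences with
#' `w = g = 0`) counts towards the background.
#'
#' @param problem An [motif_problem()] object.
#' @param w,g Fully instantiated 0/1 label vectors.
#' @param a_start,b_start Binding start vectors.
#' @return A list with components `first` (K x J), `second` (K x J2) and
#'   `background` (length K), with letter rows ordered like the alphabet.
#' @export
accumulate_motif_counts <- function(problem, w, g, a_start, b_start) {
  stopifnot(length(w) == problem$n, length(g) == problem$n)
  if (anyNA(w) || anyNA(g)) stop("labels must be fully instantiated")
  cnt <- motif_counts(problem, as.integer(w), as.integer(g),
                      as.integer(a_start), as.integer(b_start))
  rownames(cnt$first) <- rownames(cnt$second) <- problem$letters
  names(cnt$background) <- problem$letters
  cnt
}
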