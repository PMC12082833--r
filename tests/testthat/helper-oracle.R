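# Independent linear-space oracle: assigns each residue position its
# governing distribution (second motif dominates overlaps, then first motif,
# then background) and multiplies probabilities directly. Deliberately
# independent of the package's count-based log-space implementation.
oracle_seq_lik <- function(sequence, w, g, a1, b1, theta0, M1, M2, letters) {
  s <- match(strsplit(sequence, "")[[1]], letters)
  J <- ncol(M1); J2 <- ncol(M2)
  prob <- 1
  for (pos in seq_along(s)) {
    prob <- prob * if (g == 1 && pos >= b1 && pos <= b1 + J2 - 1) {
      M2[s[pos], pos - b1 + 1]
    } else if (w == 1 && pos >= a1 && pos <= a1 + J - 1) {
      M1[s[pos], pos - a1 + 1]
    } else {
      theta0[s[pos]]
    }
  }
  prob
}

# Brute-force enumeration of the position full conditional by evaluating the
# oracle at every candidate start and normalizing.
oracle_position_posterior <- function(sequence, w, g, b1, theta0, M1, M2, letters,
                                      which = c("a", "b"), a1 = NULL) {
  which <- match.arg(which)
  L <- nchar(sequence)
  if (which == "a") {
    ncand <- L - ncol(M1) + 1
    f <- vapply(seq_len(ncand), function(x) {
      oracle_seq_lik(sequence, w, g, x, b1, theta0, M1, M2, letters)
    }, numeric(1))
  } else {
    ncand <- L - ncol(M2) + 1
    f <- vapply(seq_len(ncand), function(x) {
      oracle_seq_lik(sequence, w, g, a1, x, theta0, M1, M2, letters)
    }, numeric(1))
  }
  f / sum(f)
}

# Random column-stochastic matrix, built without the package's Dirichlet code.
rand_pspm <- function(K, J) {
  m <- matrix(stats::runif(K * J, 0.05, 1), K, J)
  sweep(m, 2, colSums(m), "/")
}

rand_seq <- function(L, letters) paste(sample(letters, L, replace = TRUE), collapse = "")

dna <- c("A", "C", "G", "T")
aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Tiny labelled dataset over DNA used by several conditional tests.
micro_problem <- function(w = c(1, 1), g = c(1, 0), L = 6, J = 2, J2 = 2,
                          seed = 42) {
  set.seed(seed)
  d <- tibble::tibble(seq = c(rand_seq(L, dna), rand_seq(L, dna)),
                      w = w, g = g)
  motif_problem(d, first_len = J, second_len = J2, alphabet = "DNA")
}

# A fixed, fully specified state for a problem (parameters drawn once).
fixed_state <- function(p, seed = 7) {
  set.seed(seed)
  st <- initialize_state(p)
  st$theta0 <- as.vector(rand_pspm(p$K, 1))
  st$Theta1 <- rand_pspm(p$K, p$J)
  st$Theta2 <- rand_pspm(p$K, p$J2)
  hiermotif:::state_refresh_logs(st)
}

# Planted strongly conserved first-motif dataset used by the shift-move
# rescue experiments: all w = 1 and g = 0 known, near-degenerate motif
# columns, true starts leaving room for a +1 shift.
planted_first_motif <- function(n = 100, L = 15, J = 9) {
  theta0 <- as.vector(rand_pspm(20, 1))
  pref <- sample.int(20, J, replace = TRUE)
  Theta1 <- matrix(0.002 / 19, 20, J)
  Theta1[cbind(pref, seq_len(J))] <- 0.998
  a_true <- sample.int(L - J, n, replace = TRUE)  # +1 shift stays in range
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample.int(20, L, replace = TRUE, prob = theta0)
    for (j in seq_len(J)) s[a_true[i] + j - 1] <- sample.int(20, 1, prob = Theta1[, j])
    paste(aa20[s], collapse = "")
  }, character(1))
  list(data = tibble::tibble(seq = seqs, w = 1, g = 0),
       theta0 = theta0, Theta1 = Theta1, a_true = a_true)
}

# Initial state sitting in the mode shifted one position right of the truth:
# positions at true + 1 and a first motif regenerated from those windows.
shifted_init <- function(p, planted) {
  st <- initialize_state(p)
  st$a <- planted$a_true + 1L
  cnt <- accumulate_motif_counts(p, st$w, st$g, st$a, st$b)
  st$Theta1 <- apply(cnt$first + 1, 2, function(x) x / sum(x))
  st$theta0 <- (cnt$background + 1) / sum(cnt$background + 1)
  hiermotif:::state_refresh_logs(st)
}
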