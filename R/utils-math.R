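# Numerical primitives shared by the samplers. Everything likelihood-shaped is
# kept in log space; linear-space products underflow already at L = 30, K = 20.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Draw from a Dirichlet distribution
#'
#' One draw from Dirichlet(`alpha`), via normalized Gamma variates. Used for
#' the conjugate full-conditional updates of the motif columns and the
#' background frequencies.
#'
#' @param alpha Positive concentration vector.
#' @return A probability vector of the same length as `alpha`.
#' @keywords internal
rdirichlet1 <- function(alpha) {
  if (any(alpha <= 0)) stop("Dirichlet concentration parameters must be positive")
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  # guard against all-zero draws at tiny concentrations
  while (sum(x) == 0) x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

# Log density of Dirichlet(alpha) at probability vector x.
ldirichlet <- function(x, alpha) {
  if (any(alpha <= 0)) stop("Dirichlet concentration parameters must be positive")
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}
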