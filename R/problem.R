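#' Assemble a motif-decomposition problem
#'
#' Validates and encodes the inputs to the sampler: the sequences, the two
#' partially observed binary binding labels, the two motif lengths, and the
#' prior hyperparameters. The first label `w` marks the upstream binding
#' process (e.g. MHC binding-and-presentation), the second label `g` the
#' downstream one (e.g. T cell recognition); `NA` marks an unknown label that
#' the sampler will treat as latent.
#'
#' @param data Data frame with one row per sequence: a character column `seq`,
#'   and columns `w` and `g` with values 0, 1 or `NA`. An optional `id` column
#'   is carried through; otherwise ids `seq1..seqn` are generated.
#' @param first_len,second_len Motif lengths J and J-tilde for the first and
#'   second binding process. Both must be at most the shortest sequence length.
#' @param alphabet Passed to [motif_alphabet()].
#' @param alpha0,alpha_first,alpha_second Dirichlet hyperparameters for the
#'   background and the two motif matrices. Scalars are recycled to length K
#'   (and across motif columns); a K-vector applies to every column; a K x J
#'   matrix gives one vector per column. Defaults of 1 are the flat priors.
#' @param p0 Bernoulli prior probability that an unknown label equals 1.
#' @return An object of class `hm_problem` holding the encoded sequences,
#'   lengths, alphabet, observed labels, unknown-label index sets, motif
#'   lengths and hyperparameters.
#' @examples
#' d <- tibble::tibble(seq = c("ACGTAC", "TTGACA"), w = c(1, 0), g = c(NA, 1))
#' p <- motif_problem(d, first_len = 3, second_len = 2, alphabet = "DNA")
#' p$unknown_g
#' @export
motif_problem <- function(data, first_len, second_len, alphabet = "AA",
                          alpha0 = 1, alpha_first = 1, alpha_second = 1,
                          p0 = 0.5) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  if (!all(c("seq", "w", "g") %in% names(data))) {
    stop("`data` must have columns `seq`, `w` and `g`")
  }
  letters <- motif_alphabet(alphabet)
  K <- length(letters)
  n <- nrow(data)
  ids <- if ("id" %in% names(data)) as.character(data$id) else paste0("seq", seq_len(n))
  if (anyDuplicated(ids)) stop("sequence ids must be unique")

  check_label <- function(x, name) {
    x <- as.numeric(x)
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) stop(sprintf("label `%s` must be 0, 1 or NA (row %d)",
                               name, which(bad)[1]))
    as.integer(x)
  }
  w_obs <- check_label(data$w, "w")
  g_obs <- check_label(data$g, "g")

  seqs <- lapply(seq_len(n), function(i) {
    encode_seq(data$seq[[i]], letters, what = sprintf("sequence '%s'", ids[i]))
  })
  len <- lengths(seqs)

  first_len <- as.integer(first_len)
  second_len <- as.integer(second_len)
  if (first_len < 1 || second_len < 1) stop("motif lengths must be >= 1")
  if (first_len > min(len) || second_len > min(len)) {
    stop("motif lengths cannot exceed the shortest sequence length")
  }
  if (!(p0 > 0 && p0 < 1)) stop("`p0` must lie strictly between 0 and 1")

  expand_alpha <- function(a, J, name) {
    if (is.matrix(a)) {
      if (nrow(a) != K || ncol(a) != J) stop(sprintf("`%s` must be %d x %d", name, K, J))
      m <- a
    } else if (length(a) == 1) {
      m <- matrix(a, K, J)
    } else if (length(a) == K) {
      m <- matrix(a, K, J)
    } else stop(sprintf("`%s` must be a scalar, length-%d vector, or %d x %d matrix",
                        name, K, K, J))
    if (any(m <= 0)) stop(sprintf("`%s` must be strictly positive", name))
    m
  }

  structure(list(
    seqs = seqs, len = len, n = n, ids = ids,
    letters = letters, K = K,
    w_obs = w_obs, g_obs = g_obs,
    unknown_w = which(is.na(w_obs)), unknown_g = which(is.na(g_obs)),
    J = first_len, J2 = second_len,
    alpha0 = if (length(alpha0) == 1) rep(alpha0, K) else {
      if (length(alpha0) != K || any(alpha0 <= 0)) stop("`alpha0` must be a positive scalar or length-K vector")
      as.numeric(alpha0)
    },
    alpha1 = expand_alpha(alpha_first, first_len, "alpha_first"),
    alpha2 = expand_alpha(alpha_second, second_len, "alpha_second"),
    p0 = p0
  ), class = "hm_problem")
}

#' @export
print.hm_problem <- function(x, ...) {
  cat(sprintf("<hm_problem> %d sequences (lengths %d-%d), K = %d\n",
              x$n, min(x$len), max(x$len), x$K))
  cat(sprintf("  motif lengths: first %d, second %d\n", x$J, x$J2))
  cat(sprintf("  unknown labels: %d of w, %d of g; p0 = %.2f\n",
              length(x$unknown_w), length(x$unknown_g), x$p0))
  invisible(x)
}

# Attach log-parameter caches after any change to theta0/Theta1/Theta2.
state_refresh_logs <- function(state) {
  state$lt0 <- log(state$theta0)
  state$lT1 <- log(state$Theta1)
  state$lT2 <- log(state$Theta2)
  state
}

#' Draw an initial sampler state
#'
#' Unknown labels are drawn Bernoulli(1/2), binding starts uniformly over each
#' sequence's valid range, and the background and every motif column from a
#' flat Dirichlet.
#'
#' @param problem An [motif_problem()] object.
#' @return A list with components `w`, `g` (full label vectors with unknowns
#'   filled by draws), `a`, `b` (binding start vectors), `theta0`, `Theta1`,
#'   `Theta2` (background vector and the two K x J column-stochastic motif
#'   matrices).
#' @export
initialize_state <- function(problem) {
  p <- problem
  w <- p$w_obs
  g <- p$g_obs
  if (length(p$unknown_w)) w[p$unknown_w] <- stats::rbinom(length(p$unknown_w), 1, 0.5)
  if (length(p$unknown_g)) g[p$unknown_g] <- stats::rbinom(length(p$unknown_g), 1, 0.5)
  a <- vapply(p$len, function(L) sample.int(L - p$J + 1, 1), integer(1))
  b <- vapply(p$len, function(L) sample.int(L - p$J2 + 1, 1), integer(1))
  state <- list(
    w = as.integer(w), g = as.integer(g), a = a, b = b,
    theta0 = rdirichlet1(rep(1, p$K)),
    Theta1 = vapply(seq_len(p$J), function(j) rdirichlet1(rep(1, p$K)), numeric(p$K)),
    Theta2 = vapply(seq_len(p$J2), function(j) rdirichlet1(rep(1, p$K)), numeric(p$K))
  )
  state_refresh_logs(state)
}
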