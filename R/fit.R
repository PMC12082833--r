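#' Decompose a composite hierarchical motif by MCMC
#'
#' Runs the Gibbs sampler with grouped Metropolis-Hastings shift moves on a
#' labelled sequence set and returns the chain trace together with the
#' maximum a posteriori (MAP) estimate. Each iteration sequentially updates
#' the unknown `w` labels, the unknown `g` labels, the first and second
#' binding starts, the two motif matrices and the background from their full
#' conditionals; the first shift move is attempted every
#' `shift_first_every` iterations and the second every `shift_second_every`
#' (on iterations divisible by both, first then second). After `burn_in`
#' iterations the visited states are candidates for the MAP estimate, the
#' single snapshot with the highest joint log posterior.
#'
#' @param data Data frame with columns `seq`, `w`, `g` (0/1/`NA`), optional
#'   `id`.
#' @param first_len,second_len Motif lengths.
#' @param alphabet Passed to [motif_alphabet()].
#' @param iterations,burn_in Number of sweeps and the number of initial
#'   sweeps excluded from estimation (`burn_in < iterations` unless
#'   `iterations = 0`).
#' @param shift_first_every,shift_second_every Periods of the two shift
#'   moves; `Inf` disables a move.
#' @param alpha0,alpha_first,alpha_second,p0 Prior hyperparameters, see
#'   [motif_problem()].
#' @param seed Optional integer seed; fixing it makes the whole trace
#'   reproducible.
#' @param init Optional initial state (as from [initialize_state()]); by
#'   default a fresh random initialization is drawn.
#' @return An object of class `hm_fit` with components `problem`, `trace` (a
#'   list of per-iteration snapshots), `scalars` (tibble of iteration,
#'   log-likelihood, log-posterior and shift-move flags), `map` (the MAP
#'   snapshot), `map_iteration`, and the call configuration.
#' @examples
#' sim <- sim_hier_motifs(n = 30, len = 10, first_len = 4, second_len = 3,
#'                        alphabet = "DNA", seed = 1)
#' fit <- decompose_motifs(sim$data, first_len = 4, second_len = 3,
#'                         alphabet = "DNA", iterations = 20, burn_in = 10,
#'                         seed = 1)
#' glance(fit)
#' @export
decompose_motifs <- function(data, first_len, second_len, alphabet = "AA",
                             iterations = 100, burn_in = 50,
                             shift_first_every = 5, shift_second_every = 10,
                             alpha0 = 1, alpha_first = 1, alpha_second = 1,
                             p0 = 0.5, seed = NULL, init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (iterations > 0 && burn_in >= iterations) stop("`burn_in` must be smaller than `iterations`")
  if (shift_first_every < 1 || shift_second_every < 1) stop("shift periods must be >= 1")
  p <- motif_problem(data, first_len, second_len, alphabet,
                     alpha0, alpha_first, alpha_second, p0)
  st <- if (is.null(init)) initialize_state(p) else state_refresh_logs(init)

  trace <- vector("list", iterations)
  sc <- list(log_lik = numeric(iterations), log_post = numeric(iterations),
             shift1_attempted = logical(iterations), shift1_accepted = logical(iterations),
             shift2_attempted = logical(iterations), shift2_accepted = logical(iterations))

  for (t in seq_len(iterations)) {
    st <- gibbs_sweep(p, st)
    if (is.finite(shift_first_every) && t %% shift_first_every == 0) {
      mv <- shift_move_first(p, st)
      st <- mv$state
      sc$shift1_attempted[t] <- TRUE
      sc$shift1_accepted[t] <- mv$accepted
    }
    if (is.finite(shift_second_every) && t %% shift_second_every == 0) {
      mv <- shift_move_second(p, st)
      st <- mv$state
      sc$shift2_attempted[t] <- TRUE
      sc$shift2_accepted[t] <- mv$accepted
    }
    sc$log_lik[t] <- ll_state(p, st)
    sc$log_post[t] <- log_posterior(p, st)
    trace[[t]] <- list(w = st$w, g = st$g, a = st$a, b = st$b,
                       theta0 = st$theta0, Theta1 = st$Theta1, Theta2 = st$Theta2)
  }

  fit <- structure(list(
    problem = p,
    trace = trace,
    scalars = tibble::tibble(iteration = seq_len(iterations),
                             log_lik = sc$log_lik, log_post = sc$log_post,
                             shift1_attempted = sc$shift1_attempted,
                             shift1_accepted = sc$shift1_accepted,
                             shift2_attempted = sc$shift2_attempted,
                             shift2_accepted = sc$shift2_accepted),
    iterations = iterations, burn_in = burn_in,
    shift_first_every = shift_first_every,
    shift_second_every = shift_second_every,
    seed = seed
  ), class = "hm_fit")
  if (iterations > 0) {
    fit$map_iteration <- map_iteration(fit)
    fit$map <- trace[[fit$map_iteration]]
  }
  fit
}

map_iteration <- function(fit) {
  post <- seq(fit$burn_in + 1, fit$iterations)
  if (!length(post)) stop("no post-burn-in samples to select the MAP from")
  post[which.max(fit$scalars$log_post[post])]
}

#' Maximum a posteriori snapshot of a fitted chain
#'
#' Returns the post-burn-in snapshot with the highest joint log posterior
#' (likelihood plus all prior densities): the point estimate of all
#' parameters and latent variables.
#'
#' @param fit An `hm_fit` object.
#' @return A list with `w`, `g`, `a`, `b`, `theta0`, `Theta1`, `Theta2`.
#' @export
map_estimate <- function(fit) {
  stopifnot(inherits(fit, "hm_fit"))
  if (fit$iterations == 0) stop("no post-burn-in samples to select the MAP from")
  fit$trace[[map_iteration(fit)]]
}

#' @export
print.hm_fit <- function(x, ...) {
  cat(sprintf("<hm_fit> %d sequences, motif lengths %d / %d, %d iterations (%d burn-in)\n",
              x$problem$n, x$problem$J, x$problem$J2, x$iterations, x$burn_in))
  if (x$iterations > 0) {
    cat(sprintf("  MAP at iteration %d: log-posterior %.2f, log-likelihood %.2f\n",
                x$map_iteration, x$scalars$log_post[x$map_iteration],
                x$scalars$log_lik[x$map_iteration]))
  }
  invisible(x)
}
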