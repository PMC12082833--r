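#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the MAP motif estimates of a fit
#'
#' Returns the MAP position-specific probabilities in long form, one row per
#' (motif, position, letter).
#'
#' @param x An `hm_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `motif` (`"background"`, `"first"`,
#'   `"second"`), `position`, `letter`, `prob`.
#' @method tidy hm_fit
#' @export
tidy.hm_fit <- function(x, ...) {
  p <- x$problem
  map <- map_estimate(x)
  long <- function(mat, motif) {
    tibble::tibble(motif = motif,
                   position = rep(seq_len(ncol(mat)), each = nrow(mat)),
                   letter = rep(p$letters, ncol(mat)),
                   prob = as.vector(mat))
  }
  dplyr::bind_rows(long(matrix(map$theta0, ncol = 1), "background"),
                   long(map$Theta1, "first"),
                   long(map$Theta2, "second"))
}

#' One-row summary of a fit
#'
#' @param x An `hm_fit` object.
#' @param ... Unused.
#' @return A tibble with the data size, chain settings, MAP iteration and
#'   score, and the shift-move acceptance rates.
#' @method glance hm_fit
#' @export
glance.hm_fit <- function(x, ...) {
  sc <- x$scalars
  rate <- function(att, acc) if (any(att)) mean(acc[att]) else NA_real_
  tibble::tibble(
    n = x$problem$n,
    first_len = x$problem$J,
    second_len = x$problem$J2,
    iterations = x$iterations,
    burn_in = x$burn_in,
    map_iteration = x$map_iteration %||% NA_integer_,
    log_lik = if (x$iterations > 0) sc$log_lik[x$map_iteration] else NA_real_,
    log_post = if (x$iterations > 0) sc$log_post[x$map_iteration] else NA_real_,
    shift1_acceptance = rate(sc$shift1_attempted, sc$shift1_accepted),
    shift2_acceptance = rate(sc$shift2_attempted, sc$shift2_accepted)
  )
}

#' @method tidy hm_scan
#' @export
tidy.hm_scan <- function(x, ...) x$results

#' @method glance hm_scan
#' @export
glance.hm_scan <- function(x, ...) {
  tibble::tibble(best = x$best,
                 best_accuracy = x$results$accuracy[x$results$second_len == x$best],
                 n_candidates = nrow(x$results),
                 n_held_out = nrow(x$held_out))
}
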