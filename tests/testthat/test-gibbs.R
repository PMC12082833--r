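test_that("Dirichlet draws are simplex points with the conjugate-posterior mean", {
  set.seed(21)
  draws <- t(vapply(1:5000, function(i) sample_theta(c(10, 0, 0, 0), rep(1, 4)),
                    numeric(4)))
  expect_true(all(draws > 0 & draws < 1))
  expect_equal(rowSums(draws), rep(1, 5000), tolerance = 1e-12)
  expect_equal(unname(colMeans(draws)), c(11, 1, 1, 1) / 14, tolerance = 0.02)
  expect_error(sample_theta(c(1, 1), c(1, 0)), "positive")
  expect_error(sample_theta(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("label full conditional matches the two-term closed form", {
  # window letters have first-motif probability 0.5 each vs background 1/20:
  # p(w = 1) = 0.5^3 / (0.5^3 + 0.05^3) with a flat label prior
  set.seed(22)
  s <- rand_seq(7, aa20)
  p <- motif_problem(tibble::tibble(seq = s, w = NA, g = 0), 3, 3, "AA")
  st <- initialize_state(p)
  st$g[1] <- 0L; st$a[1] <- 2L
  st$theta0 <- rep(1 / 20, 20)
  win <- match(strsplit(s, "")[[1]][2:4], aa20)
  M1 <- matrix(0.5 / 19, 20, 3)
  M1[cbind(win, 1:3)] <- 0.5
  st$Theta1 <- M1
  st <- hiermotif:::state_refresh_logs(st)

  p_expected <- 0.5^3 / (0.5^3 + 0.05^3)
  expect_equal(hiermotif:::label_posterior_w(p, st, 1), p_expected, tolerance = 1e-12)

  draws <- vapply(1:5000, function(k) sample_label_w(p, st, 1)$w[1], integer(1))
  expect_equal(mean(draws), p_expected, tolerance = 0.02)
  expect_error(sample_label_w(p, st, 2), "known|subscript")
})

test_that("symmetric label likelihoods give probability one half", {
  p <- micro_problem(w = c(NA, 1), g = c(0, 0))
  st <- fixed_state(p)
  st$Theta1 <- matrix(st$theta0, p$K, p$J)  # motif identical to background
  st <- hiermotif:::state_refresh_logs(st)
  expect_equal(hiermotif:::label_posterior_w(p, st, 1), 0.5, tolerance = 1e-12)
})

test_that("position conditional is uniform when the label is off", {
  p <- micro_problem(w = c(0, 0), g = c(0, 0))
  st <- fixed_state(p)
  expect_equal(hiermotif:::position_posterior_a(p, st, 1), rep(1 / 5, 5))
  expect_equal(hiermotif:::position_posterior_b(p, st, 2), rep(1 / 5, 5))
})

test_that("near-degenerate motif concentrates the position posterior on its window", {
  set.seed(23)
  planted <- planted_first_motif(n = 1, L = 15, J = 9)
  p <- motif_problem(planted$data, 9, 5, "AA")
  st <- initialize_state(p)
  st$theta0 <- planted$theta0
  st$Theta1 <- planted$Theta1
  st <- hiermotif:::state_refresh_logs(st)
  post <- hiermotif:::position_posterior_a(p, st, 1)
  expect_gt(post[planted$a_true[1]], 0.99)
})

test_that("gibbs conditionals reproduce exact label marginals on a micro model", {
  # n = 2, L = 5, K = 2, J = J2 = 1; parameters fixed at truth. Long-run
  # sampled label frequencies must match enumeration over labels x positions.
  set.seed(24)
  letters2 <- c("A", "C")
  seqs <- c("AACAA", "CAACC")
  d <- tibble::tibble(seq = seqs, w = c(NA, 1), g = c(0, NA))
  p <- motif_problem(d, 1, 1, alphabet = letters2)
  th0 <- c(0.7, 0.3)
  M1 <- matrix(c(0.15, 0.85), 2, 1)
  M2 <- matrix(c(0.4, 0.6), 2, 1)

  # exact marginals by enumeration (uniform position priors, p0 = 0.5)
  joint <- 0; pw1 <- 0; pg2 <- 0
  for (w1 in 0:1) for (g2 in 0:1) {
    lik <- 0
    for (a1 in 1:5) for (b1 in 1:5) {
      lik <- lik + oracle_seq_lik(seqs[1], w1, 0, a1, b1, th0, M1, M2, letters2) / 25
    }
    lik2 <- 0
    for (a2 in 1:5) for (b2 in 1:5) {
      lik2 <- lik2 + oracle_seq_lik(seqs[2], 1, g2, a2, b2, th0, M1, M2, letters2) / 25
    }
    term <- lik * lik2 * 0.25  # Bernoulli(1/2) priors on the two unknowns
    joint <- joint + term
    if (w1 == 1) pw1 <- pw1 + term
    if (g2 == 1) pg2 <- pg2 + term
  }
  pw1 <- pw1 / joint; pg2 <- pg2 / joint

  st <- initialize_state(p)
  st$theta0 <- th0; st$Theta1 <- M1; st$Theta2 <- M2
  st <- hiermotif:::state_refresh_logs(st)
  iters <- 20000
  hits_w <- 0; hits_g <- 0
  for (t in seq_len(iters)) {
    st <- sample_label_w(p, st, 1)
    st <- sample_label_g(p, st, 2)
    for (i in 1:2) st <- sample_position_a(p, st, i)
    for (i in 1:2) st <- sample_position_b(p, st, i)
    hits_w <- hits_w + st$w[1]
    hits_g <- hits_g + st$g[2]
  }
  expect_equal(hits_w / iters, pw1, tolerance = 0.03)
  expect_equal(hits_g / iters, pg2, tolerance = 0.03)
})

test_that("known labels are never modified by a sweep", {
  p <- micro_problem(w = c(1, 0), g = c(0, 1))
  st <- fixed_state(p)
  for (k in 1:20) st <- hiermotif:::gibbs_sweep(p, st)
  expect_identical(st$w, c(1L, 0L))
  expect_identical(st$g, c(0L, 1L))
})
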