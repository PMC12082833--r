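test_that("count_letters tallies residues at the requested positions", {
  full <- count_letters("TDLLQAC", 1:7, "AA")
  expect_equal(sum(full), 7)
  expect_equal(unname(full[c("T", "D", "L", "Q", "A", "C")]), c(1, 1, 2, 1, 1, 1))
  expect_equal(sum(full[setdiff(names(full), c("T", "D", "L", "Q", "A", "C"))]), 0)

  win <- count_letters("TDLLQAC", 3:5, "AA")
  expect_equal(unname(win[c("L", "Q")]), c(2, 1))
  expect_equal(sum(win), 3)

  expect_equal(sum(count_letters("TDLLQAC", integer(0), "AA")), 0)
  expect_error(count_letters("TDLLQAC", 8, "AA"), "out of range")
  expect_error(count_letters("TBX", 1:3, "AA"), "not in the alphabet")
})

test_that("the double-binding case drops the first-motif factor under full overlap", {
  # second motif fully covers the first window: no first-motif factor at all
  th0 <- rep(1 / 20, 20)
  obs <- c("L", "L", "Q")  # residues at positions 3:5 of TDLLQAC
  M2 <- vapply(obs, function(ch) {
    v <- rep(0.5 / 19, 20); v[match(ch, aa20)] <- 0.5; v
  }, numeric(20))
  set.seed(1)
  M1 <- rand_pspm(20, 3)  # must not enter the likelihood
  ll <- case_log_likelihood("TDLLQAC", w = 1, g = 1, a_start = 3, b_start = 3,
                            th0, M1, M2, alphabet = "AA")
  expect_equal(ll, log(0.05^4 * 0.5^3), tolerance = 1e-12)
})

test_that("the no-binding case is pure background", {
  set.seed(2)
  s <- rand_seq(11, aa20)
  M <- rand_pspm(20, 3)
  ll <- case_log_likelihood(s, 0, 0, 1, 1, rep(1 / 20, 20), M, M, "AA")
  expect_equal(ll, 11 * log(1 / 20), tolerance = 1e-12)
})

test_that("disjoint windows satisfy the case additivity identity", {
  set.seed(3)
  s <- rand_seq(12, dna)
  th0 <- as.vector(rand_pspm(4, 1))
  M1 <- rand_pspm(4, 3); M2 <- rand_pspm(4, 2)
  args <- list(th0, M1, M2, alphabet = "DNA")
  ll <- function(w, g) do.call(case_log_likelihood, c(list(s, w, g, 2, 8), args))
  expect_equal(ll(1, 1), ll(1, 0) + ll(0, 1) - ll(0, 0), tolerance = 1e-10)
  expect_equal(ll(1, 1), log(oracle_seq_lik(s, 1, 1, 2, 8, th0, M1, M2, dna)),
               tolerance = 1e-10)
})

test_that("all four cases match the per-residue product oracle on random instances", {
  set.seed(4)
  for (rep in 1:30) {
    L <- sample(6:12, 1)
    J <- sample(2:4, 1); J2 <- sample(2:4, 1)
    s <- rand_seq(L, dna)
    th0 <- as.vector(rand_pspm(4, 1))
    M1 <- rand_pspm(4, J); M2 <- rand_pspm(4, J2)
    a1 <- sample.int(L - J + 1, 1); b1 <- sample.int(L - J2 + 1, 1)
    for (w in 0:1) for (g in 0:1) {
      expect_equal(case_log_likelihood(s, w, g, a1, b1, th0, M1, M2, "DNA"),
                   log(oracle_seq_lik(s, w, g, a1, b1, th0, M1, M2, dna)),
                   tolerance = 1e-9)
    }
  }
})

test_that("case likelihoods reject invalid inputs", {
  M <- rand_pspm(4, 3)
  th0 <- rep(0.25, 4)
  expect_error(case_log_likelihood("ACGTAC", 1, 0, 5, 1, th0, M, M, "DNA"),
               "invalid first-motif start")
  expect_error(case_log_likelihood("ACGTAC", 0, 1, 1, 0, th0, M, M, "DNA"),
               "invalid second-motif start")
  expect_error(case_log_likelihood("ACGTAC", 2, 0, 1, 1, th0, M, M, "DNA"),
               "must be 0 or 1")
})

test_that("joint log likelihood sums per-sequence case likelihoods", {
  set.seed(5)
  th0 <- as.vector(rand_pspm(4, 1))
  M1 <- rand_pspm(4, 2); M2 <- rand_pspm(4, 2)

  d1 <- tibble::tibble(seq = rand_seq(8, dna), w = 1, g = 1)
  expect_equal(joint_log_likelihood(d1, 3, 5, th0, M1, M2, "DNA"),
               case_log_likelihood(d1$seq, 1, 1, 3, 5, th0, M1, M2, "DNA"))

  d0 <- tibble::tibble(seq = c(rand_seq(6, dna), rand_seq(9, dna)), w = 0, g = 0)
  expect_equal(joint_log_likelihood(d0, c(1, 1), c(1, 1), rep(0.25, 4), M1, M2, "DNA"),
               15 * log(0.25), tolerance = 1e-12)

  d3 <- tibble::tibble(seq = replicate(3, rand_seq(10, dna)),
                       w = c(1, 0, 1), g = c(1, 1, 0))
  a <- c(2, 1, 5); b <- c(4, 6, 2)
  expect_equal(joint_log_likelihood(d3, a, b, th0, M1, M2, "DNA"),
               sum(log(vapply(1:3, function(i) {
                 oracle_seq_lik(d3$seq[i], d3$w[i], d3$g[i], a[i], b[i],
                                th0, M1, M2, dna)
               }, numeric(1)))), tolerance = 1e-9)
  expect_error(joint_log_likelihood(tibble::tibble(seq = "ACGT", w = NA, g = 0),
                                    1, 1, th0, M1, M2, "DNA"),
               "instantiated")
})
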