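test_that("normalized L1 error is the average absolute error per element", {
  truth <- matrix(0.25, 4, 2)
  est <- truth
  est[1, 1] <- est[1, 1] + 0.1
  est[2, 1] <- est[2, 1] - 0.1
  expect_equal(hiermotif:::normalized_l1(est, truth), 0.2 / 8)
  expect_equal(hiermotif:::normalized_l1(truth, truth), 0)
})

test_that("metrics are exact when the estimate equals the truth", {
  sim <- sim_hier_motifs(n = 25, len = 10, first_len = 4, second_len = 3,
                         alphabet = "DNA", label_prob = 0.5, miss_g_w0 = 0.5,
                         seed = 61)
  fit <- decompose_motifs(sim$data, 4, 3, alphabet = "DNA",
                          iterations = 1, burn_in = 0, seed = 62)
  truth <- fit$trace[[1]]
  truth <- list(theta0 = truth$theta0, first_motif = truth$Theta1,
                second_motif = truth$Theta2, w = truth$w, g = truth$g,
                a_start = truth$a, b_start = truth$b,
                masked_g = fit$problem$unknown_g)
  m <- recovery_metrics(fit, truth)
  expect_equal(m$error_theta0, 0)
  expect_equal(m$error_first, 0)
  expect_equal(m$error_second, 0)
  expect_equal(m$acc_g, 1)
  expect_equal(m$acc_a, 1)
  expect_equal(m$acc_b, 1)
  expect_equal(m$log_lik, fit$scalars$log_lik)
  expect_error(recovery_metrics(fit, list(theta0 = rep(0.25, 4),
                                          first_motif = matrix(0.25, 4, 2),
                                          second_motif = matrix(0.25, 4, 3))),
               "dimensions")
})

test_that("masked-label predictions read off the MAP snapshot", {
  sim <- sim_hier_motifs(n = 30, len = 10, first_len = 4, second_len = 3,
                         alphabet = "DNA", label_prob = 0.5, miss_g_w0 = 1,
                         seed = 63)
  fit <- decompose_motifs(sim$data, 4, 3, alphabet = "DNA",
                          iterations = 10, burn_in = 5, seed = 64)
  idx <- fit$problem$unknown_g
  held <- tibble::tibble(index = idx, truth = fit$map$g[idx])
  pred <- predict_masked_labels(fit, held)
  expect_equal(attr(pred, "accuracy"), 1)
  expect_identical(pred$estimate, fit$map$g[idx])
  expect_equal(masked_label_accuracy(fit, held), 1)

  flipped <- tibble::tibble(index = idx, truth = 1L - fit$map$g[idx])
  expect_equal(masked_label_accuracy(fit, flipped), 0)

  expect_error(predict_masked_labels(fit, tibble::tibble(index = integer(0),
                                                         truth = integer(0))),
               "empty")
  known <- setdiff(seq_len(30), idx)[1]
  expect_error(predict_masked_labels(fit, tibble::tibble(index = known, truth = 1L)),
               "masked")
})

test_that("a single-candidate length scan returns that candidate", {
  sim <- sim_hier_motifs(n = 40, len = 12, first_len = 4, second_len = 3,
                         alphabet = "DNA", miss_g_w0 = 0, miss_g_w1 = 0,
                         label_prob = 0.5, seed = 65)
  scan <- scan_second_length(sim$data, first_len = 4, candidates = 3,
                             mask_fraction = 0.2, seed = 66, alphabet = "DNA",
                             iterations = 10, burn_in = 5)
  expect_equal(scan$best, 3)
  expect_equal(nrow(scan$results), 1)
  expect_equal(nrow(scan$held_out), ceiling(0.2 * 40))
  expect_s3_class(tidy(scan), "tbl_df")
  expect_equal(glance(scan)$n_candidates, 1)
})

test_that("the alignment diagnostic flags a one-column shift", {
  truth <- rand_pspm(4, 5)
  shifted <- cbind(truth[, -1], rand_pspm(4, 1))  # estimate shifted left
  chk <- hiermotif:::shift_alignment_check(shifted, truth)
  expect_true(chk$improved)
  expect_equal(chk$shift, 1L)
  same <- hiermotif:::shift_alignment_check(truth, truth)
  expect_false(same$improved)
})

test_that("tidy and glance summarise a fit", {
  sim <- sim_hier_motifs(n = 30, len = 10, first_len = 4, second_len = 3,
                         alphabet = "DNA", seed = 67)
  fit <- decompose_motifs(sim$data, 4, 3, alphabet = "DNA",
                          iterations = 12, burn_in = 6, seed = 68)
  td <- tidy(fit)
  expect_setequal(unique(td$motif), c("background", "first", "second"))
  expect_equal(nrow(td), 4 * (1 + 4 + 3))
  sums <- tapply(td$prob, interaction(td$motif, td$position, drop = TRUE), sum)
  expect_equal(unname(as.vector(sums)), rep(1, 8), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_equal(gl$iterations, 12)
  p1 <- autoplot(fit)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(plot_motif(fit, "second"), "ggplot")
})
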