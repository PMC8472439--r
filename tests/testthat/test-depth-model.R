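test_that("expected fractions follow the copy-state closed forms", {
  expect_equal(expected_fraction(2, 1e6, 1e6), 0.5)
  expect_equal(expected_fraction(1, 1e6, 1e6), 1 / 3)
  expect_equal(expected_fraction(3, 1e6, 1e6), 0.6)
  p <- expected_fraction(0:4, 2e6, 5e6)
  expect_true(all(diff(p) > 0))
  expect_true(p[1] > 0)  # homozygous-deletion floor keeps the fraction positive
})

test_that("beta-binomial likelihood reduces to binomial and peaks at the MLE", {
  o <- 5; n <- 10
  expect_equal(target_loglik(o, n - o, 0.5, 1e-9),
               dbinom(o, n, 0.5, log = TRUE), tolerance = 1e-6)
  ps <- seq(0.05, 0.95, by = 0.001)
  ll <- vapply(ps, function(p) target_loglik(o, n - o, p, 0.05), numeric(1))
  expect_equal(ps[which.max(ll)], o / n, tolerance = 2e-3)
  # a target with half the expected reads is better explained by one copy
  o_half <- 50; r <- 200; N_s <- 1e5; N_r <- 2e5  # diploid expectation 100
  ll1 <- target_loglik(o_half, r, expected_fraction(1, N_s, N_r), 0.01)
  ll2 <- target_loglik(o_half, r, expected_fraction(2, N_s, N_r), 0.01)
  expect_gt(ll1, ll2)
  # no reads, no information
  expect_identical(target_loglik(0, 0, 0.5, 0.01), 0)
})

test_that("the maximizing copy state is non-decreasing in the observed count", {
  N_s <- 1e5; N_r <- 5e5
  p_states <- expected_fraction(0:4, N_s, N_r)
  n <- 600
  best <- vapply(0:n, function(o) {
    ll <- vapply(p_states, function(p) target_loglik(o, n - o, p, 0.02),
                 numeric(1))
    which.max(ll)
  }, integer(1))
  expect_true(all(diff(best) >= 0))
})

test_that("reference selection favours correlated profiles and flags degenerate input", {
  set.seed(11)
  n_t <- 300
  profile <- rlnorm(n_t, log(100), 0.6)
  test <- rpois(n_t, profile)
  near <- t(vapply(1:5, function(i) rpois(n_t, profile), numeric(n_t)))
  far <- t(vapply(1:26, function(i) rpois(n_t, sample(profile)), numeric(n_t)))
  counts <- rbind(test, near, far)
  batch <- count_matrix(counts, sprintf("S%02d", 1:32), "ES")
  ref <- select_reference("S01", batch)
  expect_true(all(ref$reference_ids %in% sprintf("S%02d", 2:6)))
  expect_gt(ref$rho, 0)
  expect_false("S01" %in% ref$reference_ids)

  two <- count_matrix(rbind(test, test), c("A", "B"), "TsoE",
                      allow_any_size = TRUE)
  ref2 <- select_reference("A", two)
  expect_identical(ref2$reference_ids, "B")
  expect_lt(ref2$rho, 0.01)  # identical profiles: overdispersion at its floor

  zero <- count_matrix(rbind(test * 0L, test), c("A", "B"), "TsoE",
                       allow_any_size = TRUE)
  expect_error(select_reference("A", zero), "zero total")
  one <- count_matrix(matrix(test, nrow = 1), "A", "TsoE",
                      allow_any_size = TRUE)
  expect_error(select_reference("A", one), "batch")
})

test_that("Viterbi path matches exhaustive enumeration on small 2-state instances", {
  states <- c(1L, 2L)
  transition <- 1e-3
  brute_force <- function(emission) {
    Tn <- ncol(emission)
    paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
    score <- apply(paths, 1, function(idx) {
      s <- sum(emission[cbind(idx, seq_len(Tn))])
      entered <- c(states[idx[1]] != 2L,
                   if (Tn > 1) idx[-1] != idx[-Tn] & states[idx[-1]] != 2L)
      s + sum(entered) * log(transition)
    })
    states[paths[which.max(score), ]]
  }
  set.seed(202)
  for (Tn in 2:12) {
    emission <- matrix(rnorm(2 * Tn, sd = 2), nrow = 2)
    expect_identical(viterbi_states(emission, states, transition),
                     brute_force(emission),
                     info = sprintf("T=%d", Tn))
  }
})

test_that("Viterbi ties break toward the diploid-proximal state", {
  emission <- matrix(0, nrow = 5, ncol = 4)  # all states equally likely
  expect_identical(viterbi_states(emission, 0:4, 1e-4), rep(2L, 4))
})

test_that("spiked CNVs are called with correct state and boundaries", {
  spikes <- data.frame(sample = 1, chrom = "chrS1", first_target = 100,
                       last_target = 109, copy_number = 1,
                       mosaic_fraction = 1)
  sim <- simulate_batch(sim_spec(n_samples = 32, n_targets = 500,
                                 mean_depth = 200, rho = 0.01,
                                 spikes = spikes, seed = 42))
  ref <- select_reference("S01", sim$batch)
  calls <- call_segments(ref, sim$grid)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "loss")
  expect_equal(calls$copy_number, 1L)
  expect_equal(calls$first_target, 100L)
  expect_equal(calls$last_target, 109L)
  expect_lt(abs(calls$mean_ratio - 0.5), 0.1)

  gain <- data.frame(sample = 2, chrom = "chrS1", first_target = 50,
                     last_target = 57, copy_number = 3, mosaic_fraction = 1)
  sim2 <- simulate_batch(sim_spec(n_samples = 32, n_targets = 500,
                                  mean_depth = 200, rho = 0.01,
                                  spikes = gain, seed = 43))
  calls2 <- call_segments(select_reference("S02", sim2$batch), sim2$grid)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$type, "gain")
  expect_equal(calls2$copy_number, 3L)

  expect_error(call_segments(ref, tiny_grid(5)), "disagree")
})

test_that("clean batches stay quiet: few spurious calls per sample", {
  n_calls <- vapply(1:20, function(seed) {
    sim <- simulate_batch(sim_spec(n_samples = 16, n_targets = 300,
                                   mean_depth = 200, rho = 0.01,
                                   seed = 1000 + seed))
    nrow(call_segments(select_reference("S01", sim$batch), sim$grid))
  }, numeric(1))
  expect_lte(mean(n_calls), 0.1)
})

test_that("mosaic fraction inverts the depth-ratio shift", {
  expect_equal(estimate_mosaic(list(copy_number = 3, mean_ratio = 1.29))$fraction,
               0.58)
  m <- estimate_mosaic(list(copy_number = 1, mean_ratio = 0.5))
  expect_equal(m$fraction, 1)
  expect_true(m$constitutive)
  expect_equal(estimate_mosaic(list(copy_number = 3, mean_ratio = 1))$fraction, 0)
  expect_false(estimate_mosaic(list(copy_number = 4, mean_ratio = 2))$supported)
  expect_true(is.na(estimate_mosaic(list(copy_number = 0, mean_ratio = 0))$fraction))
  # table annotation: constitutive events carry no mosaic annotation
  calls <- rbind(one_call(copy_number = 3L, mean_ratio = 1.29),
                 one_call(copy_number = 1L, mean_ratio = 0.5))
  out <- add_mosaic_fractions(calls)
  expect_equal(out$mosaic_fraction, c(0.58, NA))
})
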