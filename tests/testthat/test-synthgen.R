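test_that("attenuation maps are monotone and correctly inverted", {
  target <- c(0, 0.05, 0.2, 0.6, 0.95)
  expect_equal(lognormal_corr(lognormal_rho(target)), target, tolerance = 1e-10)
  expect_equal(folded_corr(folded_rho(target)), target, tolerance = 1e-3)
  expect_true(all(diff(lognormal_corr(seq(-1, 1, 0.01))) > 0))
  expect_true(all(diff(folded_corr(seq(0, 1, 0.01))) > 0))
  expect_error(folded_rho(-0.2), "restricted")
})

test_that("absorbing chains yield constant state sequences", {
  m <- ground_truth_model(small_atlas(), K = 3,
                          transition_matrix = diag(3))
  s <- sample_state_sequence(m, 500, seed = 4)
  expect_length(s, 500)
  expect_equal(unique(s), s[1])
})

test_that("sampled transition frequencies match the generating chain", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  m <- ground_truth_model(small_atlas(), K = 2, transition_matrix = A)
  s <- sample_state_sequence(m, 100000, seed = 7)
  emp <- bf_transitions(s, 2)
  for (i in 1:2) {
    n_i <- sum(s[-length(s)] == i)
    se <- sqrt(A[i, 1] * (1 - A[i, 1]) / n_i)
    expect_lt(max(abs(emp[i, ] - A[i, ])), 3 * se)
  }
  # occupancy converges to the stationary distribution (uniform here)
  fo <- bf_occupancy(s, 2)
  expect_lt(max(abs(fo - 0.5)), 0.02)
})

test_that("state sampling is reproducible and validates its chain", {
  m <- ground_truth_model(small_atlas(), K = 3)
  expect_identical(sample_state_sequence(m, 1000, seed = 5),
                   sample_state_sequence(m, 1000, seed = 5))
  bad <- m
  bad$transition_matrix[1, 1] <- 2
  expect_error(sample_state_sequence(bad, 10, seed = 1), "stochastic")
})

test_that("uncorrelated states produce uncorrelated envelopes", {
  atlas <- small_atlas()
  m <- ground_truth_model(atlas, K = 1, within_on = 0, within_off = 0,
                          between = 0, between_on = 0)
  rec <- generate_recording(atlas, m, 60, 250, seed = 2)
  expect_true(all(rec$parcel_series > 0))
  cc <- cor(t(rec$parcel_series))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("state-restricted envelope correlations hit the block targets", {
  atlas <- small_atlas()
  m <- ground_truth_model(atlas, K = 2, within_on = 0.6, within_off = 0.1,
                          between = 0.05)
  rec <- generate_recording(atlas, m, 120, 250, seed = 9)
  net <- as.integer(atlas$network_labels)
  for (k in 1:2) {
    idx <- which(rec$true_states == k)
    cc <- cor(t(rec$parcel_series[, idx]))
    hot <- net == k
    hot_block <- cc[hot, hot][upper.tri(cc[hot, hot])]
    cold <- net == 3
    cold_block <- cc[cold, cold][upper.tri(cc[cold, cold])]
    expect_lt(abs(mean(hot_block) - 0.6), 0.05)
    expect_lt(abs(mean(cold_block) - 0.1), 0.05)
  }
})

test_that("oscillatory recordings demodulate to the generated envelope", {
  atlas <- small_atlas()
  m <- ground_truth_model(atlas, K = 1, within_on = 0.3, within_off = 0.3,
                          between = 0.1)
  rec <- generate_recording(atlas, m, 20, 250, seed = 3,
                            mode = "oscillatory")
  env <- hilbert_envelope(rec$parcel_series, 250)
  # the carrier is amplitude-modulated by a smoothed positive envelope:
  # demodulation must return a positive, slowly-varying signal whose
  # mean matches the lognormal envelope mean (exp(sigma^2/2) ~ 1.046)
  interior <- 300:4700
  expect_true(all(env[, interior] > 0))
  expect_lt(abs(mean(env[, interior]) - exp(0.3^2 / 2)), 0.05)
  expect_error(generate_recording(atlas, m, 5, 15, seed = 1,
                                  mode = "oscillatory"), "carrier")
})

test_that("cohort generation is deterministic with correct bookkeeping", {
  cfg <- cohort_config(groups = list(OAC = list(n = 15, group_effect = 1),
                                     YAC = list(n = 15, group_effect = 1.15),
                                     TCOA = list(n = 15, group_effect = 1.3)),
                       atlas = small_atlas(), K = 2,
                       duration_s = 1, fs = 50, seed = 11)
  coh <- generate_cohort(cfg)
  expect_length(coh, 45)
  expect_equal(unname(table(vapply(coh, function(r) r$group, ""))),
               c(15L, 15L, 15L), ignore_attr = TRUE)
  expect_false(anyDuplicated(names(coh)) > 0)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$OAC_03$parcel_series, coh2$OAC_03$parcel_series)
  expect_identical(coh$TCOA_15$true_states, coh2$TCOA_15$true_states)
})

test_that("duplicate subject ids are rejected", {
  cfg <- cohort_config(groups = list(A = list(n = 2, group_effect = 1),
                                     A = list(n = 2, group_effect = 1)),
                       atlas = small_atlas(), K = 2,
                       duration_s = 1, fs = 50, seed = 1)
  expect_error(generate_cohort(cfg), "duplicate")
})

test_that("doubling the duration shrinks the Monte-Carlo error ~ sqrt(2)", {
  atlas <- small_atlas()
  m <- ground_truth_model(atlas, K = 1, within_on = 0.3, within_off = 0.3,
                          between = 0.1)
  net <- as.integer(atlas$network_labels)
  est <- function(dur, seed) {
    rec <- generate_recording(atlas, m, dur, 100, seed = seed)
    cc <- cor(t(rec$parcel_series))
    mean(cc[net == 1, net == 1][upper.tri(cc[net == 1, net == 1])])
  }
  se1 <- sd(vapply(1:40, function(i) est(4, 100 + i), numeric(1)))
  se2 <- sd(vapply(1:40, function(i) est(8, 200 + i), numeric(1)))
  ratio <- se1 / se2
  expect_gt(ratio, sqrt(2) / 1.5)
  expect_lt(ratio, sqrt(2) * 1.5)
})

test_that("group statistics are calibrated under a null cohort", {
  atlas <- small_atlas()
  m <- ground_truth_model(atlas, K = 1, within_on = 0.3, within_off = 0.3,
                          between = 0.05)
  net <- as.integer(atlas$network_labels)
  pvals <- vapply(1:100, function(rep) {
    vals <- vapply(1:16, function(s) {
      rec <- generate_recording(atlas, m, 4, 50, seed = 1000 * rep + s)
      cc <- cor(t(rec$parcel_series))
      mean(cc[net == 1, net == 1][upper.tri(cc[net == 1, net == 1])])
    }, numeric(1))
    U <- mannwhitney_u(vals[1:8], vals[9:16])
    as.numeric(exact_p(U, 8, 8))
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
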