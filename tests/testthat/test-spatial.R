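test_that("state segmentation produces maximal constant runs", {
  w <- segment_states(c(1, 1, 2, 2, 1))
  expect_equal(w$state, c(1, 2, 1))
  expect_equal(w$start, c(1, 3, 5))
  expect_equal(w$end, c(3, 5, 6))
  expect_equal(sum(w$end - w$start), 5)        # partition contract
  expect_true(all(diff(w$state) != 0))
  w1 <- segment_states(rep(2, 10))
  expect_equal(nrow(w1), 1L)
})

test_that("a single all-covering state reduces to static connectivity", {
  set.seed(50)
  env <- matrix(rnorm(6 * 300), 6, 300)
  fc <- compute_state_fc(env, segment_states(rep(1, 300)), K = 1,
                         min_len = 25)
  expect_equal(fc$matrices[[1]], cor(t(env)), ignore_attr = TRUE)
  expect_equal(fc$support, 300L)
})

test_that("short windows are excluded and absent states are missing", {
  set.seed(51)
  env <- matrix(rnorm(4 * 100), 4, 100)
  s <- c(rep(1, 48), rep(2, 4), rep(1, 48))   # state 2 visit below min_len
  fc <- compute_state_fc(env, segment_states(s), K = 3, min_len = 25)
  expect_null(fc$matrices[[2]])
  expect_null(fc$matrices[[3]])
  expect_equal(fc$support, c(96L, 0L, 0L))
  # the state-1 average ignores the short middle visit entirely
  manual <- (cor(t(env[, 1:48])) + cor(t(env[, 53:100]))) / 2
  expect_equal(fc$matrices[[1]], manual, ignore_attr = TRUE)
})

test_that("state-restricted connectivity recovers the generative targets", {
  atlas <- small_atlas()
  m <- ground_truth_model(atlas, K = 2, within_on = 0.6, within_off = 0.1,
                          between = 0.05)
  rec <- generate_recording(atlas, m, 90, 250, seed = 8)
  seqo <- state_sequence(rec$true_states, K = 2, fs = 250)
  fc <- compute_state_fc(rec$parcel_series, segment_states(seqo), K = 2)
  nm <- network_means(fc$matrices[[1]], atlas)
  expect_lt(abs(nm$within["VIN"] - 0.6), 0.05)
  expect_lt(abs(nm$within["DAN"] - 0.1), 0.05)
})

test_that("a zero-variance parcel yields missing correlations, not failure", {
  set.seed(52)
  env <- matrix(rnorm(4 * 80), 4, 80)
  env[3, ] <- 2.5
  fc <- expect_no_error(compute_state_fc(env, segment_states(rep(1, 80)),
                                         K = 1, min_len = 25))
  expect_true(all(is.na(fc$matrices[[1]][3, -3])))
  expect_equal(fc$matrices[[1]][3, 3], 1)
  expect_false(anyNA(fc$matrices[[1]][-3, -3]))
})

test_that("network means match block construction and a loop oracle", {
  atlas <- small_atlas()
  net <- as.integer(atlas$network_labels)
  blockm <- outer(net, net, function(a, b) ifelse(a == b, 0.4, 0))
  diag(blockm) <- 1
  nm <- network_means(blockm, atlas)
  expect_equal(unname(nm$within), rep(0.4, 7))
  expect_equal(unname(nm$between), rep(0, 21))
  nm_id <- network_means(diag(21), atlas)
  expect_equal(unname(nm_id$within), rep(0, 7))

  set.seed(53)
  S <- matrix(rnorm(21 * 21), 21); S <- (S + t(S)) / 2; diag(S) <- 1
  nm2 <- network_means(S, atlas)
  # explicit double loop
  for (a in 1:7) {
    vals <- c()
    for (i in 1:21) for (j in 1:21)
      if (i < j && net[i] == a && net[j] == a) vals <- c(vals, S[i, j])
    expect_equal(unname(nm2$within[a]), mean(vals))
  }
  vals <- c()
  for (i in 1:21) for (j in 1:21)
    if (net[i] == 2 && net[j] == 5) vals <- c(vals, S[i, j])
  expect_equal(unname(nm2$between["SMN-LIN"]), mean(vals))

  # invariance to parcel permutation within a network
  perm <- seq_len(21); perm[1:3] <- c(2, 3, 1)
  expect_equal(network_means(S[perm, perm], atlas)$within, nm2$within)
})

test_that("transition magnitudes follow the weighted-difference formula", {
  ms <- list(c(net = 0.1), c(net = 0.3))
  tp <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  tm <- transition_magnitude(ms, tp, fo = c(0.5, 0.5))
  expect_equal(unname(tm), 0.2)      # equal weights, |0.3 - 0.1|

  # equal summaries give zero; adding a never-entered state changes nothing
  ms_eq <- list(c(a = 0.2, b = 0.4), c(a = 0.2, b = 0.4))
  expect_equal(unname(transition_magnitude(ms_eq, tp, c(0.5, 0.5))), c(0, 0))
  ms3 <- c(ms, list(c(net = 9)))
  tp3 <- rbind(cbind(tp * 0.99, 0.01), c(0.4, 0.4, 0.2))
  tm3 <- transition_magnitude(ms3, tp3, fo = c(0.5, 0.5, 0))
  expect_equal(unname(tm3), 0.2)

  # linear scaling of differences scales the magnitude
  ms_sc <- list(c(net = 0.1) * 3, c(net = 0.3) * 3)
  expect_equal(unname(transition_magnitude(ms_sc, tp, c(0.5, 0.5))),
               3 * 0.2)

  # asymmetric case against a hand-evaluated weighted mean
  tp2 <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE)
  fo2 <- c(0.7, 0.3)
  num <- 0.7 * 0.2 * 0.2 + 0.3 * 0.4 * 0.2
  den <- 0.7 * 0.2 + 0.3 * 0.4
  expect_equal(unname(transition_magnitude(ms, tp2, fo2)), num / den)

  expect_true(is.na(transition_magnitude(list(c(x = 1), NULL),
                                         tp, c(1, 0))))
})

test_that("subject-level connectivity is the occupancy-weighted mean", {
  atlas <- small_atlas()
  set.seed(54)
  mk <- function() {
    S <- matrix(rnorm(21 * 21, sd = 0.2), 21); S <- (S + t(S)) / 2
    diag(S) <- 1; S
  }
  fc <- structure(list(matrices = list(mk(), mk(), NULL),
                       support = c(100L, 60L, 0L)),
                  class = "state_fc")
  fo <- c(0.5, 0.3, 0.2)
  out <- subject_connectivity(fc, fo, atlas)
  w <- c(0.5, 0.3) / 0.8
  o1 <- network_means(fc$matrices[[1]], atlas)
  o2 <- network_means(fc$matrices[[2]], atlas)
  expect_equal(out$within, w[1] * o1$within + w[2] * o2$within)
  expect_equal(out$between, w[1] * o1$between + w[2] * o2$between)

  one <- structure(list(matrices = list(mk()), support = 10L),
                   class = "state_fc")
  expect_equal(subject_connectivity(one, 1, atlas)$within,
               network_means(one$matrices[[1]], atlas)$within)
  none <- structure(list(matrices = list(NULL), support = 0L),
                    class = "state_fc")
  expect_error(subject_connectivity(none, 1, atlas), "no state")
})
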