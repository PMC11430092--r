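pca_apply_oracle <- function(p, X) sweep(X, 2, p$center) %*% p$rotation

test_that("PCA keeps the smallest dimension reaching the retained variance", {
  set.seed(10)
  # one dominant direction
  u <- rnorm(2000)
  X <- cbind(u, u + 0.001 * rnorm(2000), 0.001 * rnorm(2000))
  expect_equal(pca_reduce(X, 0.95)$d, 1L)

  # isotropic case: compare against the sample-spectrum oracle
  X2 <- matrix(rnorm(3000 * 20), 3000, 20)
  ev <- eigen(cov(X2), symmetric = TRUE, only.values = TRUE)$values
  d_oracle <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  p <- pca_reduce(X2, 0.95)
  expect_equal(p$d, d_oracle)

  # reconstruction error bounded by the discarded variance
  Xc <- sweep(X2, 2, colMeans(X2))
  resid <- Xc - p$scores %*% t(p$rotation)
  expect_lte(sum(resid^2) / (nrow(X2) - 1),
             (1 - 0.95) * sum(ev) + 1e-9)
  expect_lt(max(abs(pca_apply_oracle(p, X2) - p$scores)), 1e-10)
})

test_that("a one-state HMM reduces to the sample moments", {
  set.seed(11)
  X <- matrix(rnorm(500 * 3), 500, 3) %*% matrix(c(1, .4, 0, 0, 1, .2,
                                                   0, 0, 1), 3, 3)
  fit <- fit_hmm(X, 1, hmm_config(n_restarts = 1, seed = 1))
  expect_equal(as.numeric(fit$state_means), colMeans(X), tolerance = 1e-6)
  ml_cov <- cov(X) * (nrow(X) - 1) / nrow(X)
  expect_equal(fit$state_covariances[, , 1], ml_cov, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("well-separated states are recovered and EM is monotone", {
  means <- rbind(c(0, 0), c(5, 0), c(0, 5))
  A <- matrix(0.05, 3, 3); diag(A) <- 0.9
  sim <- sample_gauss_hmm(2000, rep(1 / 3, 3), A, means, rep(1, 3), seed = 21)
  cfg <- hmm_config(n_restarts = 2, seed = 3)
  fit <- fit_hmm(sim$X, 3, cfg)
  expect_true(all(diff(fit$ll_trace) > -1e-6 * abs(fit$ll_trace[-1])))
  expect_lt(max(abs(rowSums(fit$transition_matrix) - 1)), 1e-10)
  dec <- decode(fit, sim$X)
  expect_gt(label_match_accuracy(dec, sim$states), 0.95)

  # transition-matrix recovery after permutation alignment
  tab <- table(dec, sim$states)
  perm <- apply(tab, 1, which.max)
  Ahat <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    Ahat[perm[i], perm[j]] <- fit$transition_matrix[i, j]
  expect_lt(max(abs(Ahat - A)), 0.05)

  # determinism: identical config and data reproduce identical parameters
  fit2 <- fit_hmm(sim$X, 3, cfg)
  expect_identical(fit$state_means, fit2$state_means)
  expect_identical(fit$log_likelihood, fit2$log_likelihood)
})

test_that("information criteria follow their closed forms", {
  set.seed(13)
  x <- matrix(rnorm(400, mean = 2, sd = 3), ncol = 1)
  fit <- fit_hmm(x, 1, hmm_config(n_restarts = 1, seed = 1))
  ic <- information_criteria(fit, x)
  mu <- mean(x); s2 <- mean((x - mu)^2)
  ll_closed <- sum(dnorm(x, mu, sqrt(s2), log = TRUE))
  expect_equal(unname(ic["p"]), 2)
  expect_equal(unname(ic["AIC"]), 4 - 2 * ll_closed, tolerance = 1e-6)
  expect_equal(unname(ic["BIC"]), 2 * log(400) - 2 * ll_closed,
               tolerance = 1e-6)
  expect_gt(ic["BIC"], ic["AIC"])   # ln(400) > 2

  # AIC difference identity between two models on the same data
  sim <- sample_gauss_hmm(600, c(.5, .5), matrix(c(.9, .1, .1, .9), 2),
                          rbind(0, 4), c(1, 1), seed = 5)
  f1 <- fit_hmm(sim$X, 1, hmm_config(n_restarts = 1, seed = 1))
  f2 <- fit_hmm(sim$X, 2, hmm_config(n_restarts = 1, seed = 1))
  ic1 <- information_criteria(f1, sim$X); ic2 <- information_criteria(f2, sim$X)
  expect_equal(ic2["AIC"] - ic1["AIC"],
               2 * (ic2["p"] - ic1["p"]) - 2 * (ic2["logLik"] - ic1["logLik"]),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("state-count selection picks the argmin of the averaged criterion", {
  sims <- lapply(1:2, function(i)
    sample_gauss_hmm(800, c(.5, .5), matrix(c(.95, .05, .05, .95), 2),
                     rbind(c(0, 0), c(4, 4)), c(1, 1), seed = 30 + i)$X)
  cfg <- hmm_config(K_range = 1:4, n_restarts = 1, em_max_iter = 40, seed = 2)
  # fits that collapse at over-specified K are excluded with a warning
  sel <- suppressWarnings(select_n_states(sims, cfg, reduce = FALSE))
  expect_s3_class(sel, "model_selection_result")
  expect_equal(sel$K_star, 2L)
  expect_equal(unname(sel$K_star),
               unname(cfg$K_range[which.min(sel$mean_criterion)]))
})

test_that("Viterbi decoding agrees with exhaustive path enumeration", {
  set.seed(31)
  for (trial in 1:4) {
    K <- 3; Tn <- 8
    A <- matrix(runif(K * K), K); A <- A / rowSums(A)
    pi0 <- rep(1 / K, K)
    mu <- matrix(rnorm(K, sd = 2), K, 1)
    X <- matrix(rnorm(Tn, sd = 1.5), Tn, 1)
    model <- structure(list(K = K, d = 1L, initial_probs = pi0,
                            transition_matrix = A, state_means = mu,
                            state_covariances = array(1, c(1, 1, K)),
                            log_likelihood = NA_real_),
                       class = "gaussian_hmm")
    paths <- as.matrix(expand.grid(rep(list(1:K), Tn)))
    lp <- apply(paths, 1, function(s) {
      lpv <- log(pi0[s[1]]) + dnorm(X[1], mu[s[1]], 1, log = TRUE)
      for (t in 2:Tn)
        lpv <- lpv + log(A[s[t - 1], s[t]]) +
          dnorm(X[t], mu[s[t]], 1, log = TRUE)
      lpv
    })
    best <- paths[which.max(lp), ]
    expect_equal(as.integer(decode(model, X)), unname(best))
  }
})

test_that("degenerate decode cases behave", {
  sim <- sample_gauss_hmm(200, 1, matrix(1), matrix(0, 1, 1), 1, seed = 1)
  fit <- fit_hmm(sim$X, 1, hmm_config(n_restarts = 1, seed = 1))
  expect_true(all(decode(fit, sim$X) == 1L))
  expect_error(fit_hmm(matrix(rnorm(50), 50, 1), 6), "at least 10")
})

test_that("the group-level fit decodes every subject in a shared space", {
  atlas <- small_atlas()
  m <- ground_truth_model(atlas, K = 2, stay_prob = 0.95)
  envs <- lapply(1:3, function(i)
    generate_recording(atlas, m, 20, 100, seed = 40 + i)$parcel_series)
  names(envs) <- paste0("s", 1:3)
  gf <- fit_group_hmm(envs, 2, hmm_config(n_restarts = 1, em_max_iter = 30,
                                          pca_max_dims = 10, seed = 1),
                      fs = 100)
  expect_length(gf$sequences, 3)
  expect_true(all(vapply(gf$sequences, length, integer(1)) == 2000L))
  expect_equal(attr(gf$sequences$s1, "K"), 2L)
})
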