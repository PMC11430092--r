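test_that("the U statistic equals the pairwise count", {
  expect_equal(mannwhitney_u(c(1, 2), c(3, 4)), 0)
  x <- rnorm(15)
  expect_equal(mannwhitney_u(x, x), 112.5)      # all tied pairs at 1/2
  set.seed(60)
  for (i in 1:20) {
    x <- sample(1:10, 8, replace = TRUE)        # ties on purpose
    y <- sample(1:10, 6, replace = TRUE)
    bf <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(mannwhitney_u(x, y), bf)
    expect_equal(mannwhitney_u(x, y),
                 unname(suppressWarnings(wilcox.test(x, y)$statistic)))
  }
})

test_that("exact p-values match exhaustive enumeration and pwilcox", {
  for (n1 in 2:7) {
    n2 <- n1
    for (U in 0:(n1 * n2)) {
      expect_equal(as.numeric(exact_p(U, n1, n2)),
                   bf_exact_p(U, n1, n2), tolerance = 1e-12)
    }
  }
  for (U in c(0, 13, 49, 82, 112, 200, 225)) {
    lo <- min(U, 225 - U)
    expect_equal(as.numeric(exact_p(U, 15, 15)),
                 min(1, 2 * pwilcox(lo, 15, 15)), tolerance = 1e-12)
  }
  # symmetry of the two-sided p
  for (U in c(3, 40, 100))
    expect_equal(as.numeric(exact_p(U, 15, 15)),
                 as.numeric(exact_p(225 - U, 15, 15)))
  expect_error(exact_p(13.4, 6, 6), "ties")
})

test_that("tied data fall back to the corrected normal approximation", {
  p <- exact_p(20.5, 6, 8, ties = TRUE, tie_sizes = c(2L, 3L))
  expect_equal(attr(p, "method"), "normal_ties")
  expect_true(p > 0 && p <= 1)
  # continuity-corrected normal approximation, the conventional
  # large-sample route, reproduces published table statistics
  expect_equal(signif(as.numeric(exact_p(13, 15, 15, method = "normal")), 3),
               4.02e-5)
  expect_equal(signif(as.numeric(exact_p(82, 15, 15, method = "normal")), 3),
               2.13e-1)
})

test_that("rank-biserial correlation is the linear function of U", {
  expect_equal(round(rank_biserial(13, 15, 15), 2), -0.88)
  expect_equal(round(rank_biserial(49, 15, 15), 2), -0.56)
  expect_equal(round(rank_biserial(163, 15, 15), 2), 0.45)
  expect_equal(rank_biserial(112.5, 15, 15), 0)
  set.seed(61)
  for (i in 1:10) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    U <- runif(1, 0, n1 * n2)
    expect_equal(rank_biserial(U, n1, n2), 2 * U / (n1 * n2) - 1)
  }
})

test_that("BH adjustment equals the direct step-up oracle", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(62)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bf_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15))
    # rejection set preserved against the raw step-up rule at random q
    q <- runif(1, 0.01, 0.3)
    m <- length(p)
    thresh <- max(c(0, which(sort(p) <= seq_len(m) / m * q)))
    rej_oracle <- p <= (if (thresh == 0) -1 else sort(p)[thresh])
    expect_equal(adj <= q, rej_oracle)
  }
})

test_that("assumption checks report normality and homoscedasticity", {
  ok <- 0
  for (i in 1:100) {
    set.seed(200 + i)
    r <- assumption_checks(rnorm(5000), rnorm(5000))
    if (r$shapiro$x["p"] > 0.001) ok <- ok + 1
  }
  expect_gte(ok, 99)
  x <- c(1.2, 3.1, 2.4, 5.5, 0.3)
  same <- assumption_checks(x, x)
  expect_equal(unname(same$levene["F"]), 0, tolerance = 1e-12)
  const <- expect_no_error(assumption_checks(rep(2, 5), rnorm(5)))
  expect_true(const$degenerate["x"])
  expect_true(is.na(const$shapiro$x["W"]))
})

test_that("outlier flags combine z-score and IQR fences", {
  f <- flag_outliers(c(1, 1, 1, 1, 100))
  expect_equal(which(f), 5L)
  expect_false(any(flag_outliers(seq(0, 1, length.out = 20))))
  set.seed(63)
  v <- c(rnorm(30), 9)
  expect_identical(flag_outliers(v), flag_outliers(v * 3.2 - 40))
})

test_that("group comparison tables carry the full statistic schema", {
  set.seed(64)
  subj <- sprintf("s%02d", 1:30)
  grp <- rep(c("OAC", "YAC"), each = 15)
  feats <- do.call(rbind, lapply(c("within_DMN", "within_VIN", "fo_state1"),
    function(f) data.frame(subject_id = subj, group = grp, feature = f,
                           value = rnorm(30) + (f == "within_DMN") *
                             (grp == "YAC") * 3)))
  out <- compare_groups(feats, c("OAC", "YAC"))
  expect_setequal(names(out), c("feature", "family", "median1", "median2",
                                "median_diff", "U", "p_value", "p_fdr",
                                "r_rb", "n1", "n2", "p_method"))
  expect_equal(nrow(out), 3)
  expect_equal(out$family, c("within", "within", "fo"))
  expect_equal(out$r_rb, 2 * out$U / 225 - 1)
  expect_equal(out$median_diff, out$median1 - out$median2)
  shifted <- out[out$feature == "within_DMN", ]
  expect_lt(shifted$r_rb, -0.8)      # first group far lower
  expect_lt(shifted$p_fdr, 0.01)
  expect_error(compare_groups(feats, c("OAC", "YAC"),
                              families = c(within_DMN = "w")),
               "without a family")
})

test_that("type-I error is calibrated over many null features", {
  set.seed(65)
  n_feat <- 200
  rows <- lapply(seq_len(n_feat), function(f)
    data.frame(subject_id = sprintf("s%02d", 1:30),
               group = rep(c("A", "B"), each = 15),
               feature = sprintf("null_f%03d", f),
               value = rnorm(30)))
  out <- compare_groups(do.call(rbind, rows), c("A", "B"))
  rate <- mean(out$p_value < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})
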