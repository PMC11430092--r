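#' Mann-Whitney U statistic
#'
#' `U` for the first sample: the number of pairs `(x_i, y_j)` with
#' `x_i > y_j`, counting ties as 1/2 (computed via midranks, which is
#' algebraically identical to the pairwise count).
#'
#' @param x,y Numeric vectors (both nonempty, finite).
#' @return The U statistic of `x`, in `[0, n1*n2]`.
#' @export
mannwhitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

# null counts of the Mann-Whitney U via the standard counting recurrence
# f(m, n, u) = f(m-1, n, u-n) + f(m, n-1, u); returns counts for u = 0..m*n
mw_null_counts <- function(n1, n2) {
  # f[[m+1]][[n+1]] is the count vector over u for sample sizes (m, n)
  f <- vector("list", n1 + 1L)
  for (m in 0:n1) {
    f[[m + 1L]] <- vector("list", n2 + 1L)
    for (n in 0:n2) {
      if (m == 0L || n == 0L) {
        f[[m + 1L]][[n + 1L]] <- 1
        next
      }
      umax <- m * n
      a <- c(rep(0, n), f[[m]][[n + 1L]],
             rep(0, umax - n - (m - 1L) * n))
      b <- c(f[[m + 1L]][[n]], rep(0, umax - m * (n - 1L)))
      f[[m + 1L]][[n + 1L]] <- a + b
    }
  }
  f[[n1 + 1L]][[n2 + 1L]]
}

#' P-value of the Mann-Whitney U statistic
#'
#' `method = "exact"` enumerates the null distribution of U by the
#' counting recurrence `f(n1, n2, u) = f(n1-1, n2, u-n2) + f(n1, n2-1, u)`
#' and returns the two-sided `min(1, 2 P(U <= min(U, n1 n2 - U)))`; it
#' requires an integer U (no ties). With ties present pass `ties = TRUE`
#' to fall back to the midrank normal approximation with tie correction;
#' `method = "normal"` requests the continuity-corrected normal
#' approximation directly (the conventional large-sample method, which is
#' what common software defaults to at these sample sizes).
#'
#' @param U The U statistic (first group).
#' @param n1,n2 Group sizes.
#' @param method `"exact"` (default) or `"normal"`.
#' @param ties Set TRUE when `U` was computed from tied data; forces the
#'   normal approximation and applies the tie correction.
#' @param tie_sizes Integer multiplicities of tied values (for the tie
#'   correction term); ignored unless `ties = TRUE`.
#' @return Two-sided p-value in (0, 1]. Attribute `method` records the
#'   path taken.
#' @export
exact_p <- function(U, n1, n2, method = c("exact", "normal"),
                    ties = FALSE, tie_sizes = integer()) {
  method <- match.arg(method)
  stopifnot(U >= -1e-9, U <= n1 * n2 + 1e-9)
  if (ties) method <- "normal"
  if (method == "exact") {
    if (abs(U - round(U)) > 1e-9)
      stop("non-integer U without ties flag; pass ties = TRUE")
    U <- round(U)
    counts <- mw_null_counts(n1, n2)
    total <- sum(counts)
    lo <- min(U, n1 * n2 - U)
    p <- min(1, 2 * sum(counts[seq_len(lo + 1L)]) / total)
    return(structure(p, method = "exact"))
  }
  n <- n1 + n2
  tie_term <- if (length(tie_sizes)) sum(tie_sizes^3 - tie_sizes) else 0
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  cc <- if (U > mu) -0.5 else if (U < mu) 0.5 else 0
  z <- (U - mu + cc) / sqrt(sigma2)
  structure(min(1, 2 * stats::pnorm(-abs(z))),
            method = if (ties) "normal_ties" else "normal")
}

#' Rank-biserial correlation from the U statistic
#'
#' \code{r = 2U/(n1 n2) - 1}; negative values mean the first group tends to be
#' lower.
#'
#' @inheritParams exact_p
#' @return Effect size in `[-1, 1]`.
#' @export
rank_biserial <- function(U, n1, n2) {
  stopifnot(U >= 0, U <= n1 * n2)
  2 * U / (n1 * n2) - 1
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), in the input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals > 0), all(pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Distributional assumption checks for a two-group comparison
#'
#' Shapiro-Wilk normality per group and the Brown-Forsythe variant of
#' Levene's test (centered at the median) for homoscedasticity. These are
#' reported for context only: the primary comparison is already
#' nonparametric. Constant (degenerate) vectors are flagged rather than
#' crashing the tests.
#'
#' @param x,y Numeric vectors, at least 3 values each.
#' @return List with `shapiro` (per group statistic/p or NA when
#'   degenerate), `levene` (statistic/p), and `degenerate` flags.
#' @export
assumption_checks <- function(x, y) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  deg <- c(x = stats::var(x) == 0, y = stats::var(y) == 0)
  sw <- lapply(list(x = x, y = y), function(v) {
    if (stats::var(v) == 0 || length(v) > 5000)
      return(c(W = NA_real_, p = NA_real_))
    t <- stats::shapiro.test(v)
    c(W = unname(t$statistic), p = t$p.value)
  })
  lev <- if (all(!deg) || stats::var(c(x, y)) > 0) {
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    lt <- car::leveneTest(c(x, y) ~ g, center = stats::median)
    c(F = lt[1, "F value"], p = lt[1, "Pr(>F)"])
  } else c(F = NA_real_, p = NA_real_)
  list(shapiro = sw, levene = lev, degenerate = deg)
}

#' Flag outliers by z-score and IQR fences
#'
#' A value is flagged when `|z| > 3` or it falls outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Flags only: no automatic removal.
#'
#' @param values Numeric vector (n >= 4).
#' @return Logical vector of flags.
#' @export
flag_outliers <- function(values) {
  stopifnot(length(values) >= 4)
  s <- stats::sd(values)
  z <- if (s > 0) abs(values - mean(values)) / s else rep(0, length(values))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  (z > 3) | values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Two-group comparisons over a tidy feature table
#'
#' Runs one Mann-Whitney comparison per dependent variable with
#' rank-biserial effect sizes, then applies the Benjamini-Hochberg
#' adjustment within each declared feature family (by default the family
#' is the part of the feature name before the first underscore, so the 7
#' within-network variables form one family, the 21 between-network
#' variables another, and each temporal feature type its own family).
#' `U` is reported for the first-listed group, so a negative `r` means
#' "first group lower". Missing values are dropped pairwise.
#'
#' @param features Data frame with columns `subject_id`, `group`,
#'   `feature`, `value`.
#' @param pairing Character vector of the two group labels, first group
#'   first.
#' @param families Named character vector mapping every feature to a
#'   family; by default derived from the feature name prefix. A feature
#'   without a family is an error.
#' @param method P-value method passed to [exact_p()]; tied data fall
#'   back to the corrected normal approximation automatically.
#' @return Data frame with one row per feature: `feature`, `family`,
#'   `median1`, `median2`, `median_diff`, `U`, `p_value`, `p_fdr`,
#'   `r_rb`, `n1`, `n2`, `p_method`.
#' @export
compare_groups <- function(features, pairing, families = NULL,
                           method = "exact") {
  stopifnot(all(c("subject_id", "group", "feature", "value") %in%
                  names(features)), length(pairing) == 2L)
  feats <- unique(features$feature)
  if (is.null(families)) {
    families <- stats::setNames(sub("_.*$", "", feats), feats)
  }
  missing_fam <- setdiff(feats, names(families))
  if (length(missing_fam))
    stop("features without a family: ", paste(missing_fam, collapse = ", "))
  rows <- lapply(feats, function(f) {
    sub <- features[features$feature == f, ]
    x <- sub$value[sub$group == pairing[1L]]
    y <- sub$value[sub$group == pairing[2L]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) == 0L || length(y) == 0L)
      stop("feature ", f, " missing one of the groups")
    U <- mannwhitney_u(x, y)
    has_ties <- anyDuplicated(c(x, y)) > 0L
    tie_sizes <- if (has_ties) as.integer(table(c(x, y))) else integer()
    p <- exact_p(U, length(x), length(y), method = method,
                 ties = has_ties, tie_sizes = tie_sizes)
    data.frame(feature = f, family = unname(families[f]),
               median1 = stats::median(x), median2 = stats::median(y),
               median_diff = stats::median(x) - stats::median(y),
               U = U, p_value = as.numeric(p), p_fdr = NA_real_,
               r_rb = rank_biserial(U, length(x), length(y)),
               n1 = length(x), n2 = length(y),
               p_method = attr(p, "method"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (fam in unique(out$family)) {
    idx <- out$family == fam
    out$p_fdr[idx] <- bh_fdr(out$p_value[idx])
  }
  rownames(out) <- NULL
  out
}
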