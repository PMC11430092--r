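#' Pool edge weights across windowed connectivity graphs
#'
#' Windowed graphs are undirected weighted graphs on a shared node set,
#' represented as symmetric N x N matrices (self-loops ignored). The edge
#' pool is the multiset of all upper-triangle weights of all windows.
#'
#' @param graphs List of symmetric N x N weight matrices.
#' @return Numeric vector of pooled signed edge weights.
#' @export
aggregate_edges <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  N <- nrow(graphs[[1L]])
  pool <- lapply(graphs, function(g) {
    g <- as.matrix(g)
    if (nrow(g) != N || ncol(g) != N)
      stop("inconsistent node sets across windows")
    if (any(!is.finite(g))) stop("non-finite edge weights")
    g[upper.tri(g)]
  })
  unlist(pool, use.names = FALSE)
}

#' Bootstrap median of absolute edge weights
#'
#' Draws `n_iter` bootstrap resamples (size n, with replacement) of the
#' pooled absolute edge weights and returns the median of the resample
#' medians, the robust normalization constant for the disparity filter.
#'
#' @param pool Numeric vector of pooled edge weights (see
#'   [aggregate_edges()]).
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return Object of class `bootstrap_result`: list with `M` (> 0),
#'   `n_iter`, `seed`, and the pool size `n`.
#' @export
bootstrap_median <- function(pool, n_iter = 10000L, seed = 1L) {
  pool <- abs(as.numeric(pool))
  n <- length(pool)
  if (n == 0L) stop("empty edge pool")
  if (all(pool == 0)) stop("all-zero edge pool: median must be positive")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  structure(list(M = cpp_boot_median(pool, as.integer(n_iter)),
                 n_iter = as.integer(n_iter),
                 seed = as.integer(seed), n = n),
            class = "bootstrap_result")
}

#' Disparity-filter edge retention for one window
#'
#' Weights are normalized by the bootstrap median `M`; for edge (u, v) the
#' disparity score at node u is
#' \deqn{s_u(v) = \frac{(|w_{uv}|/M)^2}{\sum_{k \sim u} (|w_{uk}|/M)^2},}
#' the squared normalized weight relative to the node's total squared
#' connectivity. The edge is retained iff `s_u(v) >= alpha` or
#' `s_v(u) >= alpha` (so a degree-1 node's only edge, with score 1, is
#' always kept). Retained edges keep their signed weight; squaring already
#' discards sign, but observed backbones retain negative correlations, so
#' sign must survive the filter.
#'
#' @param graph Symmetric N x N signed weight matrix (zero = no edge).
#' @param M Positive normalization constant (see [bootstrap_median()]).
#' @param alpha Retention threshold in (0, 1].
#' @return Filtered symmetric matrix; dropped edges are set to 0.
#'   Attribute `n_retained` carries the retained edge count.
#' @export
disparity_retention <- function(graph, M, alpha) {
  stopifnot(M > 0, alpha > 0, alpha <= 1)
  W <- as.matrix(graph)
  diag(W) <- 0
  P <- (abs(W) / M)^2
  rs <- rowSums(P)
  S <- P / ifelse(rs > 0, rs, 1)       # S[u, v] = s_u(v)
  keep <- (S >= alpha) | (t(S) >= alpha)
  keep[W == 0] <- FALSE
  out <- ifelse(keep, W, 0)
  structure(out, n_retained = sum(out[upper.tri(out)] != 0))
}

#' Search settings for the retention-threshold optimization
#'
#' @param alpha_start,alpha_end Search range (defaults 0.001 and 0.10).
#' @param tolerance Golden-section interval tolerance (default 1e-4).
#' @param grid_step Step of the safeguarding grid scan (default 0.001).
#' @return An `alpha_search` list.
#' @export
alpha_search <- function(alpha_start = 0.001, alpha_end = 0.10,
                         tolerance = 1e-4, grid_step = 0.001) {
  stopifnot(alpha_start > 0, alpha_start < alpha_end, alpha_end <= 1)
  structure(list(alpha_start = alpha_start, alpha_end = alpha_end,
                 tolerance = tolerance, grid_step = grid_step),
            class = "alpha_search")
}

.mean_retained <- function(graphs, M, alpha) {
  vapply(graphs, function(g) {
    f <- disparity_retention(g, M, alpha)
    e <- f[upper.tri(f)]
    e <- e[e != 0]
    if (length(e) == 0L) 0 else mean(e)
  }, numeric(1))
}

backbone_objective <- function(graphs, M, alpha) {
  C <- .mean_retained(graphs, M, alpha)
  mean(abs(diff(C)))
}

# per-window (edge weight, retention score) pairs; the score of edge (u,v)
# is max(s_u(v), s_v(u)) and does not depend on alpha, so the objective
# can be evaluated for many alphas without re-filtering
.retention_scores <- function(graphs, M) {
  lapply(graphs, function(g) {
    W <- as.matrix(g)
    diag(W) <- 0
    P <- (abs(W) / M)^2
    rs <- rowSums(P)
    S <- P / ifelse(rs > 0, rs, 1)
    S <- pmax(S, t(S))
    ut <- upper.tri(W)
    keep <- W[ut] != 0
    list(w = W[ut][keep], s = S[ut][keep])
  })
}

.objective_from_scores <- function(scores, alpha) {
  C <- vapply(scores, function(sc) {
    e <- sc$w[sc$s >= alpha]
    if (length(e) == 0L) 0 else mean(e)
  }, numeric(1))
  mean(abs(diff(C)))
}

#' Optimize the disparity-filter threshold
#'
#' Minimizes `J(alpha)`, the mean absolute difference in average retained
#' connectivity between consecutive windows, by golden-section search over
#' `[alpha_start, alpha_end]`. Golden-section assumes a unimodal
#' objective, which is not guaranteed here, so the result is always
#' cross-checked against a coarse grid scan and the better optimum is
#' returned. A constant objective returns `alpha_start` with a warning.
#'
#' @param graphs List of >= 2 windowed weight matrices.
#' @param M Positive normalization constant.
#' @param search An [alpha_search()].
#' @return List with `alpha_optimal`, the objective value `J`, and the
#'   evaluated grid (`grid_alpha`, `grid_J`).
#' @export
optimize_alpha <- function(graphs, M, search = alpha_search()) {
  stopifnot(length(graphs) >= 2L)
  scores <- .retention_scores(graphs, M)
  f <- function(a) .objective_from_scores(scores, a)
  ga <- seq(search$alpha_start, search$alpha_end, by = search$grid_step)
  gJ <- vapply(ga, f, numeric(1))
  if (max(gJ) - min(gJ) < 1e-15) {
    warning("objective is constant over the alpha range; returning alpha_start")
    return(list(alpha_optimal = search$alpha_start, J = gJ[1L],
                grid_alpha = ga, grid_J = gJ, constant = TRUE))
  }
  # golden-section search
  gr <- (sqrt(5) - 1) / 2
  a <- search$alpha_start; b <- search$alpha_end
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > search$tolerance) {
    if (fc < fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  a_gold <- (a + b) / 2
  J_gold <- f(a_gold)
  # safeguard: golden-section refinement inside the best coarse-grid cell
  # (the objective need not be unimodal over the whole range)
  j <- which.min(gJ)
  a <- max(search$alpha_start, ga[j] - search$grid_step)
  b <- min(search$alpha_end, ga[j] + search$grid_step)
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > search$tolerance) {
    if (fc < fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  # exact sweep over the objective's breakpoints (J is piecewise constant
  # in alpha, so this visits its global minimum); golden section and the
  # grid remain as cross-checks
  ev_s <- unlist(lapply(scores, `[[`, "s"), use.names = FALSE)
  ev_w <- rep(seq_along(scores) - 1L,
              vapply(scores, function(sc) length(sc$s), integer(1)))
  ev_wt <- unlist(lapply(scores, `[[`, "w"), use.names = FALSE)
  sweep <- cpp_alpha_sweep(ev_s, ev_w, ev_wt, length(scores),
                           search$alpha_start, search$alpha_end)
  cand_a <- c(sweep$alpha, a_gold, ga[j], (a + b) / 2)
  cand_J <- c(f(sweep$alpha), J_gold, gJ[j], f((a + b) / 2))
  best <- which.min(cand_J)
  list(alpha_optimal = cand_a[best], J = cand_J[best],
       grid_alpha = ga, grid_J = gJ, constant = FALSE)
}

#' Apply the shared backbone threshold to every window
#'
#' @param graphs List of windowed weight matrices.
#' @param M Positive normalization constant.
#' @param alpha Shared retention threshold (typically from
#'   [optimize_alpha()]).
#' @return List of filtered matrices; attribute `n_retained` holds the
#'   per-window retained edge counts.
#' @export
apply_backbone <- function(graphs, M, alpha) {
  out <- lapply(graphs, disparity_retention, M = M, alpha = alpha)
  structure(out,
            n_retained = vapply(out, attr, integer(1), which = "n_retained"),
            alpha = alpha, M = M)
}
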