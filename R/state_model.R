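#' Configuration for hidden Markov state modelling
#'
#' @param K_range Inclusive integer range of candidate state counts
#'   (default 3..12, within the span used in the M/EEG state-modelling
#'   literature).
#' @param pca_retained Fraction of variance the PCA reduction must retain
#'   (default 0.95).
#' @param pca_max_dims Hard cap on retained PCA dimensions (default `Inf`).
#' @param variance_floor_frac Covariance diagonals are floored at this
#'   fraction of the largest feature variance (default 1e-3).
#' @param em_max_iter Maximum EM iterations (default 100).
#' @param em_tol Relative log-likelihood convergence tolerance
#'   (default 1e-6).
#' @param n_restarts EM restarts from distinct k-means initializations;
#'   the best log-likelihood wins (default 5).
#' @param seed Integer seed driving the restarts.
#' @return A `hmm_config` list.
#' @export
hmm_config <- function(K_range = 3:12, pca_retained = 0.95,
                       pca_max_dims = Inf, variance_floor_frac = 1e-3,
                       em_max_iter = 100L, em_tol = 1e-6,
                       n_restarts = 5L, seed = 1L) {
  stopifnot(pca_retained > 0, pca_retained <= 1, min(K_range) >= 1)
  structure(list(K_range = as.integer(K_range),
                 pca_retained = pca_retained,
                 pca_max_dims = pca_max_dims,
                 variance_floor_frac = variance_floor_frac,
                 em_max_iter = as.integer(em_max_iter),
                 em_tol = em_tol,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "hmm_config")
}

#' PCA dimensionality reduction retaining a variance fraction
#'
#' @param X T x N matrix (time in rows).
#' @param retained Fraction of variance to retain.
#' @param max_dims Optional cap on the number of components.
#' @return List with `scores` (T x d), `rotation`, `center`, `sdev`, and
#'   `d`, the smallest component count whose cumulative explained variance
#'   reaches `retained` (capped at the numerical rank and `max_dims`).
#' @export
pca_reduce <- function(X, retained = 0.95, max_dims = Inf) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need T > N for PCA reduction")
  stopifnot(ncol(X) >= 2, retained > 0, retained <= 1)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  # T >> N: eigendecomposition of the covariance beats a full SVD
  e <- eigen(crossprod(Xc) / (nrow(X) - 1L), symmetric = TRUE)
  v <- pmax(e$values, 0)
  sdev <- sqrt(v)
  rank <- sum(sdev > max(sdev) * 1e-12)
  cum <- cumsum(v) / sum(v)
  d <- which(cum >= retained - 1e-12)[1L]
  if (is.na(d)) d <- rank
  d <- min(d, rank, max_dims)
  rotation <- e$vectors[, seq_len(d), drop = FALSE]
  list(scores = Xc %*% rotation, rotation = rotation,
       center = center, sdev = sdev, d = as.integer(d))
}

pca_apply <- function(pca, X) {
  sweep(as.matrix(X), 2L, pca$center) %*% pca$rotation
}

# EM initialization: k-means over short-window moment features. Brain
# states here are defined by covariance structure, which per-sample
# k-means cannot see; windowed means, log-variances and leading-dimension
# correlations separate mean-shifted and covariance-shifted states alike.
.km_init <- function(X, K, seed, window = 50L) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  Tn <- nrow(X); d <- ncol(X)
  gcov <- stats::cov(X)
  cl <- NULL
  if (K == 1L) {
    cl <- rep(1L, Tn)
  } else {
    w <- max(10L, min(window, Tn %/% (5L * K)))
    nw <- Tn %/% w
    dc <- min(8L, d)
    if (nw >= 2L * K) {
      feat <- t(vapply(seq_len(nw), function(i) {
        idx <- ((i - 1L) * w + 1L):(i * w)
        xi <- X[idx, , drop = FALSE]
        cc <- suppressWarnings(stats::cor(xi[, seq_len(dc), drop = FALSE]))
        cc[!is.finite(cc)] <- 0
        c(colMeans(xi), log(apply(xi, 2L, stats::var) + 1e-12),
          cc[upper.tri(cc)])
      }, numeric(2L * d + dc * (dc - 1L) / 2L)))
      km <- suppressWarnings(stats::kmeans(feat, centers = K,
                                           iter.max = 20L, nstart = 10L))
      cl <- rep(km$cluster, each = w)
      cl <- c(cl, rep(cl[length(cl)], Tn - length(cl)))
    } else {
      km <- suppressWarnings(stats::kmeans(X, centers = K,
                                           iter.max = 10L, nstart = 2L))
      cl <- km$cluster
    }
  }
  mu <- matrix(0, K, d)
  Sig <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    idx <- which(cl == k)
    if (length(idx) == 0L) idx <- seq_len(Tn)
    mu[k, ] <- colMeans(X[idx, , drop = FALSE])
    S <- if (length(idx) > d + 2L) stats::cov(X[idx, , drop = FALSE]) else gcov
    if (any(!is.finite(S))) S <- gcov
    Sig[, , k] <- S + diag(1e-6 * mean(diag(gcov)), d)
  }
  A <- matrix(if (K > 1L) 0.1 / (K - 1L) else 0, K, K)
  diag(A) <- if (K > 1L) 0.9 else 1
  list(pi = rep(1 / K, K), A = A, mu = mu, Sigma = Sig)
}

#' Fit a Gaussian hidden Markov model by expectation-maximization
#'
#' Full-covariance Gaussian emissions; Baum-Welch EM started from k-means
#' partitions, best of `n_restarts` by log-likelihood. Covariance
#' diagonals are floored at `variance_floor_frac` times the largest
#' feature variance. Restarts whose EM collapses an emptied state are
#' discarded; if every restart collapses an error naming `K` is raised.
#'
#' @param X T x d numeric matrix of observations.
#' @param K Number of hidden states.
#' @param cfg A [hmm_config()].
#' @return Object of class `gaussian_hmm` with `K`, `d`, `initial_probs`,
#'   `transition_matrix`, `state_means` (K x d), `state_covariances`
#'   (d x d x K), `log_likelihood`, and the per-iteration `ll_trace`.
#' @export
fit_hmm <- function(X, K, cfg = hmm_config()) {
  X <- as.matrix(X)
  K <- as.integer(K)
  Tn <- nrow(X)
  if (Tn < 10L * K) stop("need at least 10*K samples to fit K = ", K)
  floor_val <- cfg$variance_floor_frac * max(apply(X, 2L, stats::var))
  best <- NULL
  n_fail <- 0L
  for (r in seq_len(cfg$n_restarts)) {
    init <- .km_init(X, K, seed = cfg$seed + 7919L * r + 13L * K)
    fit <- tryCatch(
      cpp_hmm_em(X, init$pi, init$A, init$mu, init$Sigma,
                 cfg$em_max_iter, cfg$em_tol, floor_val),
      error = function(e) NULL)
    if (is.null(fit) || isTRUE(fit$degenerate)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  if (is.null(best))
    stop("all EM restarts collapsed an empty state for K = ", K)
  structure(list(K = K, d = ncol(X),
                 initial_probs = as.numeric(best$initial_probs),
                 transition_matrix = best$transition_matrix,
                 state_means = best$state_means,
                 state_covariances = best$state_covariances,
                 log_likelihood = best$log_likelihood,
                 ll_trace = as.numeric(best$ll_trace),
                 converged = isTRUE(best$converged),
                 n_restart_failures = n_fail),
            class = "gaussian_hmm")
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat("<gaussian_hmm> K =", x$K, ", d =", x$d,
      ", logLik =", format(x$log_likelihood), "\n")
  invisible(x)
}

#' Information criteria of a fitted Gaussian HMM
#'
#' Parameter count `p = (K-1) + K(K-1) + K d + K d(d+1)/2` (initial
#' distribution, transitions, means, covariances). `AIC = 2p - 2 lnL`,
#' `BIC = p ln(T) - 2 lnL`, with `lnL` evaluated on `X` under the model.
#'
#' @param model A `gaussian_hmm`.
#' @param X T x d matrix (must match the model dimension).
#' @return Named numeric vector with `AIC`, `BIC`, `logLik`, `p`.
#' @export
information_criteria <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("feature dimension mismatch")
  K <- model$K; d <- model$d; Tn <- nrow(X)
  ll <- cpp_hmm_loglik(X, model$initial_probs, model$transition_matrix,
                       model$state_means, model$state_covariances)
  p <- (K - 1) + K * (K - 1) + K * d + K * d * (d + 1) / 2
  c(AIC = 2 * p - 2 * ll, BIC = p * log(Tn) - 2 * ll, logLik = ll, p = p)
}

#' Select the state count by averaged AIC/BIC across subjects
#'
#' For each subject, the observation matrix is PCA-reduced (per subject)
#' and Gaussian HMMs are fitted for each candidate `K`; the selected
#' `K_star` minimizes the across-subject mean of `(AIC + BIC)/2`, with
#' ties broken toward the smaller `K`. Subjects failing to fit a given `K`
#' are excluded from that `K`'s mean with a warning; a `K` failing on more
#' than half the subjects is excluded entirely.
#'
#' @param datasets List of per-subject T x N matrices (time in rows); raw
#'   feature matrices are PCA-reduced according to `cfg`.
#' @param cfg A [hmm_config()].
#' @param reduce Apply the per-subject PCA reduction (default TRUE).
#' @return Object of class `model_selection_result` with per-subject
#'   `AIC`/`BIC` matrices (subjects x K), `mean_criterion`, and `K_star`.
#' @export
select_n_states <- function(datasets, cfg = hmm_config(), reduce = TRUE) {
  stopifnot(length(datasets) >= 1L)
  Ks <- cfg$K_range
  nS <- length(datasets)
  AIC <- BIC <- matrix(NA_real_, nS, length(Ks),
                       dimnames = list(names(datasets), paste0("K", Ks)))
  for (s in seq_len(nS)) {
    X <- as.matrix(datasets[[s]])
    if (reduce)
      X <- pca_reduce(X, cfg$pca_retained, cfg$pca_max_dims)$scores
    for (j in seq_along(Ks)) {
      scfg <- cfg; scfg$seed <- cfg$seed + 101L * s
      fit <- tryCatch(fit_hmm(X, Ks[j], scfg), error = function(e) NULL)
      if (is.null(fit)) {
        warning("subject ", s, ": no fit for K = ", Ks[j])
        next
      }
      ic <- information_criteria(fit, X)
      AIC[s, j] <- ic["AIC"]; BIC[s, j] <- ic["BIC"]
    }
  }
  crit <- (AIC + BIC) / 2
  ok <- colMeans(is.na(crit)) <= 0.5
  mean_crit <- colMeans(crit, na.rm = TRUE)
  mean_crit[!ok] <- NA_real_
  if (all(is.na(mean_crit))) stop("no state count could be scored")
  K_star <- Ks[which.min(mean_crit)]   # which.min takes the first minimum
  structure(list(K_range = Ks, AIC = AIC, BIC = BIC,
                 mean_criterion = mean_crit,
                 K_star = as.integer(K_star)),
            class = "model_selection_result")
}

#' @export
print.model_selection_result <- function(x, ...) {
  cat("<model_selection_result> K* =", x$K_star, "\n")
  print(round(x$mean_criterion, 1))
  invisible(x)
}

#' Decode the most probable state path (Viterbi)
#'
#' @param model A `gaussian_hmm`.
#' @param X T x d observation matrix.
#' @param fs Sampling rate carried on the sequence (Hz).
#' @return A `state_sequence`: integer labels in `1..K` with attributes
#'   `K` and `fs`.
#' @export
decode <- function(model, X, fs = NA_real_) {
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("feature dimension mismatch")
  labels <- cpp_hmm_viterbi(X, model$initial_probs, model$transition_matrix,
                            model$state_means, model$state_covariances)
  state_sequence(labels, K = model$K, fs = fs)
}

#' Construct a state sequence
#'
#' @param labels Integer vector of decoded states in `1..K`.
#' @param K State count.
#' @param fs Sampling rate (Hz).
#' @return Integer vector of class `state_sequence`.
#' @export
state_sequence <- function(labels, K, fs = NA_real_) {
  labels <- as.integer(labels)
  K <- as.integer(K)
  if (any(labels < 1L | labels > K)) stop("labels must lie in 1..K")
  structure(labels, K = K, fs = fs, class = "state_sequence")
}

#' Fit one group-level HMM on concatenated, standardized subject data
#'
#' Each subject's envelope matrix is z-scored per parcel, the subjects are
#' concatenated in time, one PCA transform and one HMM are fitted on the
#' pooled data, and every subject is decoded with the shared model, so
#' state labels are comparable across subjects.
#'
#' @param env_list List of per-subject N x T envelope matrices.
#' @param K State count (e.g. from [select_n_states()]).
#' @param cfg A [hmm_config()].
#' @param fs Sampling rate attached to the decoded sequences (Hz).
#' @return List with the fitted `model`, the shared `pca` transform, and
#'   `sequences`, a named list of per-subject `state_sequence`s.
#' @export
fit_group_hmm <- function(env_list, K, cfg = hmm_config(), fs = NA_real_) {
  std <- lapply(env_list, function(e) {
    X <- scale(t(as.matrix(e)))
    X[, !is.finite(colSums(X))] <- 0      # constant parcels
    X
  })
  Xall <- do.call(rbind, std)
  pca <- pca_reduce(Xall, cfg$pca_retained, cfg$pca_max_dims)
  model <- fit_hmm(pca$scores, K, cfg)
  offs <- c(0L, cumsum(vapply(std, nrow, integer(1))))
  sequences <- lapply(seq_along(std), function(i) {
    Xi <- pca$scores[(offs[i] + 1L):offs[i + 1L], , drop = FALSE]
    decode(model, Xi, fs = fs)
  })
  names(sequences) <- names(env_list)
  list(model = model, pca = pca, sequences = sequences)
}
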