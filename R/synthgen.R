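#' Correlation attenuation under the folded-normal envelope map
#'
#' Envelopes are simulated as absolute values of correlated standard
#' Gaussians. Folding attenuates correlation: if a Gaussian pair has
#' correlation `rho`, the folded pair has correlation
#' \deqn{g(\rho) = \frac{\sqrt{1-\rho^2} + \rho \asin \rho - 1}{\pi/2 - 1},}
#' which is monotone on \[0, 1\] with g(0) = 0, g(1) = 1. `folded_corr`
#' evaluates the map; `folded_rho` inverts it on a precomputed monotone
#' lookup so that a requested envelope-level correlation is achieved after
#' folding. Negative targets are rejected: folding cannot produce negative
#' envelope correlations.
#'
#' @param rho Gaussian-scale correlation(s) in \[-1, 1\].
#' @param target Envelope-scale correlation(s) in \[0, 1\].
#' @return Numeric vector of the same length as the input.
#' @export
folded_corr <- function(rho) {
  stopifnot(all(abs(rho) <= 1 + 1e-12))
  rho <- pmin(1, pmax(-1, rho))
  (sqrt(1 - rho^2) + rho * asin(rho) - 1) / (pi / 2 - 1)
}

#' @rdname folded_corr
#' @export
folded_rho <- function(target) {
  if (any(target < -1e-12) || any(target > 1 + 1e-12))
    stop("folded envelope correlations are restricted to [0, 1]")
  target <- pmin(1, pmax(0, target))
  grid <- .folded_lookup()
  stats::approx(grid$g, grid$rho, xout = target, rule = 2)$y
}

.folded_lookup_env <- new.env(parent = emptyenv())
.folded_lookup <- function() {
  if (is.null(.folded_lookup_env$grid)) {
    rho <- seq(0, 1, length.out = 4001)
    .folded_lookup_env$grid <- list(rho = rho, g = folded_corr(rho))
  }
  .folded_lookup_env$grid
}

#' Correlation attenuation under the lognormal envelope map
#'
#' The default envelope marginal is `exp(sigma * Z)` for standard Gaussian
#' `Z` (strictly positive, monotone in `Z`, mildly right-skewed like real
#' amplitude envelopes). A Gaussian pair with correlation `rho` maps to
#' lognormal correlation
#' \deqn{g(\rho) = \frac{e^{\sigma^2 \rho} - 1}{e^{\sigma^2} - 1},}
#' which is monotone and analytically invertible:
#' `rho = log(1 + c (e^{sigma^2} - 1)) / sigma^2`.
#'
#' @param rho Gaussian-scale correlation(s).
#' @param target Envelope-scale correlation(s).
#' @param sigma Lognormal shape parameter (default 0.3).
#' @return Numeric vector of the same length as the input.
#' @export
lognormal_corr <- function(rho, sigma = 0.3) {
  (exp(sigma^2 * rho) - 1) / (exp(sigma^2) - 1)
}

#' @rdname lognormal_corr
#' @export
lognormal_rho <- function(target, sigma = 0.3) {
  lo <- lognormal_corr(-1, sigma)
  if (any(target < lo - 1e-12) || any(target > 1 + 1e-12))
    stop("target correlation outside the achievable lognormal range")
  pmin(1, pmax(-1, log(1 + target * (exp(sigma^2) - 1)) / sigma^2))
}

#' Nearest positive-semidefinite projection by eigenvalue flooring
#'
#' Floors eigenvalues at `floor_at`, reconstructs, and rescales to unit
#' diagonal. Used to keep block-structured correlation targets valid after
#' the folded-normal inverse map and group-effect scaling.
#'
#' @param mat Symmetric matrix.
#' @param floor_at Eigenvalue floor (default 1e-10).
#' @return A PSD correlation matrix with unit diagonal.
#' @export
nearest_psd <- function(mat, floor_at = 1e-10) {
  mat <- (mat + t(mat)) / 2
  e <- eigen(mat, symmetric = TRUE)
  if (min(e$values) >= floor_at) {
    out <- mat
  } else {
    vals <- pmax(e$values, floor_at)
    out <- e$vectors %*% (vals * t(e$vectors))
  }
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Ground-truth generative model for synthetic cohorts
#'
#' Defines a hidden Markov switching process over `K` brain states, each
#' with its own parcel-by-parcel correlation structure built from
#' within-network and between-network block levels. By default state `k`
#' emphasizes the coupling of one canonical network (state 1 the first
#' network, and so on, cycling when `K` exceeds the network count): parcels
#' of the emphasized network correlate at `within_on`, other networks'
#' parcels at `within_off`, and cross-network pairs at `between`. These
#' levels are targets on the *envelope* scale; the Gaussian-scale matrices
#' pre-compensate the attenuation of the chosen marginal map (see
#' [lognormal_corr()] and [folded_corr()]).
#'
#' @param atlas A [parcel_atlas()].
#' @param K Number of hidden states (default 7).
#' @param within_on Envelope correlation among parcels of a state's
#'   emphasized network (default 0.60).
#' @param within_off Envelope correlation within non-emphasized networks
#'   (default 0.10).
#' @param between Background envelope correlation across networks
#'   (default 0.05).
#' @param between_on Envelope correlation between a state's emphasized
#'   network and its coupled partner(s) (default 0.30). Brain states must
#'   modulate cross-network coupling too — a state-invariant
#'   between-network level would carry no state-specific connectivity
#'   signal.
#' @param between_mode `"partner"` (default): each state couples its
#'   emphasized network to the next network in atlas order, so the 7
#'   cyclic network pairs are state-modulated; `"all"`: the emphasized
#'   network couples to every other network (a stronger global factor).
#' @param marginal Envelope marginal: `"lognormal"` (default,
#'   `exp(sigma_log * Z)`, see [lognormal_corr()]) or `"folded"`
#'   (`|Z|`, see [folded_corr()]). Both maps are monotone in the latent
#'   Gaussian and their correlation attenuation is inverted so the
#'   envelope-scale targets are met.
#' @param sigma_log Shape of the lognormal marginal (default 0.3).
#' @param stay_prob Self-transition probability; off-diagonal mass spread
#'   uniformly. Default 0.98 (mean dwell 50 samples, 200 ms at 250 Hz).
#' @param transition_matrix Optional explicit K-by-K row-stochastic matrix.
#' @param initial_probs Optional length-K simplex; default uniform.
#' @param carrier_freq_hz Carrier frequency for oscillatory recordings
#'   (default 10 Hz, alpha band).
#' @param group_effect Multiplicative scaling applied to all off-diagonal
#'   block levels (default 1); scaled levels are clipped to \[0, 0.95\]
#'   and the matrix re-projected to PSD.
#' @return Object of class `ground_truth_model` with the envelope-scale
#'   target matrices (`state_correlations`), the compensated Gaussian-scale
#'   matrices (`gauss_correlations`) and their Cholesky factors.
#' @export
ground_truth_model <- function(atlas = parcel_atlas(),
                               K = 7L,
                               within_on = 0.60,
                               within_off = 0.10,
                               between = 0.05,
                               between_on = 0.30,
                               between_mode = c("partner", "all"),
                               stay_prob = 0.98,
                               transition_matrix = NULL,
                               initial_probs = NULL,
                               carrier_freq_hz = 10,
                               group_effect = 1,
                               marginal = c("lognormal", "folded"),
                               sigma_log = 0.3) {
  marginal <- match.arg(marginal)
  between_mode <- match.arg(between_mode)
  validate_atlas(atlas)
  K <- as.integer(K)
  stopifnot(K >= 1L, group_effect >= 0)
  N <- atlas$n_parcels
  if (is.null(transition_matrix)) {
    if (K == 1L) {
      transition_matrix <- matrix(1, 1, 1)
    } else {
      transition_matrix <- matrix((1 - stay_prob) / (K - 1), K, K)
      diag(transition_matrix) <- stay_prob
    }
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == K))
    stop("transition_matrix must be K x K")
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop("transition_matrix rows must be probability vectors summing to 1")
  if (is.null(initial_probs)) initial_probs <- rep(1 / K, K)
  if (length(initial_probs) != K || any(initial_probs < 0) ||
      abs(sum(initial_probs) - 1) > 1e-12)
    stop("initial_probs must be a length-K simplex")

  net <- as.integer(atlas$network_labels)
  n_net <- length(atlas$network_names)
  same_net <- outer(net, net, "==")
  state_corr <- vector("list", K)
  gauss_corr <- vector("list", K)
  chols <- vector("list", K)
  clip <- function(x) pmin(0.95, pmax(0, x))
  for (k in seq_len(K)) {
    hot <- ((k - 1L) %% n_net) + 1L
    Ck <- matrix(clip(between * group_effect), N, N)
    Ck[same_net] <- clip(within_off * group_effect)
    partner <- if (between_mode == "partner") (hot %% n_net) + 1L else
      setdiff(seq_len(n_net), hot)
    pair_mask <- outer(net == hot, net %in% partner, "&")
    Ck[pair_mask | t(pair_mask)] <- clip(between_on * group_effect)
    hot_mask <- outer(net == hot, net == hot, "&")
    Ck[hot_mask] <- clip(within_on * group_effect)
    diag(Ck) <- 1
    Ck <- nearest_psd(Ck)
    Rk <- Ck
    off <- row(Rk) != col(Rk)
    Rk[off] <- if (marginal == "lognormal")
      lognormal_rho(Ck[off], sigma_log) else folded_rho(Ck[off])
    Rk <- nearest_psd(Rk)
    ch <- tryCatch(chol(Rk + diag(1e-10, N)),
                   error = function(e)
                     stop("state correlation matrix ", k, " is not PSD"))
    state_corr[[k]] <- Ck
    gauss_corr[[k]] <- Rk
    chols[[k]] <- ch
  }
  structure(list(K_true = K,
                 atlas = atlas,
                 initial_probs = initial_probs,
                 transition_matrix = transition_matrix,
                 state_correlations = state_corr,
                 gauss_correlations = gauss_corr,
                 chol_factors = chols,
                 carrier_freq_hz = carrier_freq_hz,
                 group_effect = group_effect,
                 marginal = marginal,
                 sigma_log = sigma_log,
                 between_mode = between_mode,
                 levels = c(within_on = within_on, within_off = within_off,
                            between = between, between_on = between_on),
                 stay_prob = stay_prob),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat("<ground_truth_model> K =", x$K_true,
      "states on", x$atlas$n_parcels, "parcels; group_effect =",
      x$group_effect, "\n")
  invisible(x)
}

#' Sample a hidden-state sequence from the generative Markov chain
#'
#' @param model A [ground_truth_model()].
#' @param T Number of samples (>= 1).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Integer vector of length `T` with states in `1..K`.
#' @examples
#' m <- ground_truth_model(parcel_atlas(), K = 2)
#' s <- sample_state_sequence(m, 100, seed = 1)
#' @export
sample_state_sequence <- function(model, T, seed) {
  stopifnot(inherits(model, "ground_truth_model"), T >= 1)
  A <- model$transition_matrix
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12))
    stop("transition matrix rows must be stochastic")
  K <- model$K_true
  T <- as.integer(T)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  s <- integer(T)
  s[1L] <- sample.int(K, 1L, prob = model$initial_probs)
  if (T > 1L) {
    u <- stats::runif(T - 1L)
    cumA <- t(apply(A, 1L, cumsum))
    for (t in 2L:T) {
      s[t] <- findInterval(u[t - 1L], cumA[s[t - 1L], ],
                           left.open = TRUE) + 1L
    }
  }
  s
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# deterministic, seed-sized hash of a subject id (for per-subject seeds)
stable_id_hash <- function(id) {
  v <- utf8ToInt(id)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 1000003
  as.integer(h)
}

#' Simulate one subject's parcel-level recording
#'
#' In `envelope` mode each sample is an independent draw of correlated
#' standard Gaussians (correlation given by the active state's
#' Gaussian-scale matrix) passed through the model's monotone marginal map
#' (lognormal by default, folded normal as an option), so the
#' instantaneous cross-parcel correlation of the envelopes matches the
#' state's envelope-scale target (the map's attenuation is
#' pre-compensated; see [lognormal_corr()] and [folded_corr()]). In `oscillatory`
#' mode the envelope is low-pass smoothed (moving average, ~100 ms) and
#' multiplied onto a carrier sinusoid at `carrier_freq_hz` with a random
#' phase per parcel, so Hilbert demodulation recovers the smoothed
#' envelope.
#'
#' @param atlas A [parcel_atlas()].
#' @param model A [ground_truth_model()] built on the same atlas.
#' @param duration_s Duration in seconds (>= 1).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param mode `"envelope"` or `"oscillatory"`.
#' @param subject_id,group Metadata carried on the recording.
#' @return Object of class `subject_recording`: list with `subject_id`,
#'   `group`, `fs`, `parcel_series` (N x T matrix), `true_states`
#'   (length-T integers in 1..K), and `mode`.
#' @export
generate_recording <- function(atlas, model, duration_s, fs, seed,
                               mode = c("envelope", "oscillatory"),
                               subject_id = "subj", group = "none") {
  mode <- match.arg(mode)
  validate_atlas(atlas)
  stopifnot(inherits(model, "ground_truth_model"), duration_s >= 1, fs > 0)
  if (atlas$n_parcels != model$atlas$n_parcels)
    stop("atlas and model disagree on parcel count")
  if (mode == "oscillatory" && fs <= 2 * model$carrier_freq_hz)
    stop("oscillatory mode needs fs > 2 * carrier_freq_hz")
  N <- atlas$n_parcels
  T <- as.integer(round(duration_s * fs))
  states <- sample_state_sequence(model, T, seed = seed)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed) + 1L)
  env <- matrix(0, nrow = N, ncol = T)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    k <- r$values[i]
    n <- r$lengths[i]
    Z <- matrix(stats::rnorm(n * N), n, N) %*% model$chol_factors[[k]]
    env[, starts[i]:ends[i]] <- if (model$marginal == "lognormal")
      t(exp(model$sigma_log * Z)) else t(abs(Z))
  }
  if (mode == "oscillatory") {
    w <- max(1L, as.integer(round(0.1 * fs)))
    if (w > 1L) {
      kern <- rep(1 / w, w)
      env <- t(apply(env, 1L, function(x)
        stats::filter(c(rep(x[1], w), x, rep(x[length(x)], w)),
                      kern, sides = 2)[(w + 1):(w + length(x))]))
    }
    phases <- stats::runif(N, 0, 2 * pi)
    tt <- (seq_len(T) - 1) / fs
    carrier <- cos(outer(phases, 2 * pi * model$carrier_freq_hz * tt, "+"))
    series <- env * carrier
  } else {
    series <- env
  }
  if (any(!is.finite(series))) stop("non-finite values in simulated series")
  structure(list(subject_id = subject_id,
                 group = group,
                 fs = fs,
                 parcel_series = series,
                 true_states = states,
                 mode = mode,
                 seed = as.integer(seed)),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat("<subject_recording>", x$subject_id, "(", x$group, "):",
      nrow(x$parcel_series), "parcels x", ncol(x$parcel_series),
      "samples @", x$fs, "Hz,", x$mode, "mode\n")
  invisible(x)
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the study conditions the pipeline targets: three groups
#' of 15 subjects (YAC, OAC, TCOA) with multiplicative group effects on the
#' connectivity block levels ordered TCOA > YAC > OAC.
#'
#' @param groups Named list; each element a list with `n` (subjects) and
#'   `group_effect` (connectivity scaling).
#' @param atlas A [parcel_atlas()].
#' @param K Hidden-state count.
#' @param duration_s,fs Recording length (s) and sampling rate (Hz).
#' @param mode Simulation mode, see [generate_recording()].
#' @param seed Master seed; per-subject seeds are derived as
#'   `seed + stable hash(subject_id)`.
#' @param ... Further arguments to [ground_truth_model()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(groups = list(
                            OAC  = list(n = 15L, group_effect = 1.00),
                            YAC  = list(n = 15L, group_effect = 1.15),
                            TCOA = list(n = 15L, group_effect = 1.30)),
                          atlas = parcel_atlas(), K = 7L,
                          duration_s = 60, fs = 250,
                          mode = "envelope", seed = 1L, ...) {
  stopifnot(all(vapply(groups, function(g) g$n >= 2L, logical(1))))
  structure(list(groups = groups, atlas = atlas, K = K,
                 duration_s = duration_s, fs = fs, mode = mode,
                 seed = as.integer(seed), model_args = list(...)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Independent subjects per group share the model topology (state count,
#' transition structure, atlas); the per-group `group_effect` scales the
#' connectivity block levels. Subject seeds are derived deterministically
#' from the master seed, so a fixed master seed reproduces the cohort
#' bitwise.
#'
#' @param config A [cohort_config()].
#' @return List of [generate_recording()] objects, one per subject.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- unlist(lapply(names(config$groups), function(g)
    sprintf("%s_%02d", g, seq_len(config$groups[[g]]$n))))
  if (anyDuplicated(ids)) stop("duplicate subject_ids in cohort")
  out <- list()
  for (g in names(config$groups)) {
    spec <- config$groups[[g]]
    model <- do.call(ground_truth_model,
                     c(list(atlas = config$atlas, K = config$K,
                            group_effect = spec$group_effect),
                       config$model_args))
    for (i in seq_len(spec$n)) {
      sid <- sprintf("%s_%02d", g, i)
      out[[sid]] <- generate_recording(
        config$atlas, model, config$duration_s, config$fs,
        seed = config$seed + stable_id_hash(sid),
        mode = config$mode, subject_id = sid, group = g)
    }
  }
  out
}
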