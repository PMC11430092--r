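#' Segment a state sequence into maximal constant-state windows
#'
#' @param seq A [state_sequence()] (or integer vector).
#' @return Data frame with columns `state`, `start`, `end`: 1-based,
#'   half-open `[start, end)` sample intervals that partition the
#'   recording; consecutive rows always carry different states.
#' @export
segment_states <- function(seq) {
  s <- as.integer(as.vector(seq))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start = ends - r$lengths + 1L,
             end = ends + 1L)
}

#' State-wise functional connectivity over state-defined windows
#'
#' For every state visit of at least `min_len` samples, the Pearson
#' correlation matrix across parcels is computed over that window; each
#' state's connectivity is the duration-weighted average of its visit
#' matrices. Windows shorter than `min_len` are excluded. A parcel with
#' zero variance inside a window contributes missing values for that
#' window only.
#'
#' @param env N x T (orthogonalized) envelope matrix.
#' @param windows Output of [segment_states()]; total length must be T.
#' @param K State count (default: max state in `windows`).
#' @param min_len Minimum window length in samples (default 25, i.e.
#'   100 ms at 250 Hz; correlations over shorter envelope stretches are
#'   numerically meaningless).
#' @return Object of class `state_fc`: list with `matrices` (length-K list
#'   of N x N correlation matrices, `NULL` where a state has no usable
#'   window) and `support` (samples contributing per state).
#' @export
compute_state_fc <- function(env, windows, K = max(windows$state),
                             min_len = 25L) {
  env <- as.matrix(env)
  Tn <- ncol(env)
  if (max(windows$end) - 1L != Tn)
    stop("windows do not cover the envelope length")
  K <- as.integer(K)
  N <- nrow(env)
  acc <- vector("list", K)
  wsum <- matrix(0, 1, K)
  support <- integer(K)
  for (i in seq_len(nrow(windows))) {
    len <- windows$end[i] - windows$start[i]
    if (len < min_len) next
    k <- windows$state[i]
    seg <- t(env[, windows$start[i]:(windows$end[i] - 1L), drop = FALSE])
    C <- suppressWarnings(stats::cor(seg))
    diag(C) <- 1
    W <- ifelse(is.na(C), 0, len)
    C[is.na(C)] <- 0
    if (is.null(acc[[k]])) {
      acc[[k]] <- list(num = C * W, den = W)
    } else {
      acc[[k]]$num <- acc[[k]]$num + C * W
      acc[[k]]$den <- acc[[k]]$den + W
    }
    support[k] <- support[k] + len
  }
  mats <- lapply(seq_len(K), function(k) {
    if (is.null(acc[[k]])) return(NULL)
    M <- acc[[k]]$num / acc[[k]]$den
    M[acc[[k]]$den == 0] <- NA_real_
    diag(M) <- 1
    M
  })
  structure(list(matrices = mats, support = support, min_len = min_len),
            class = "state_fc")
}

#' Within- and between-network connectivity means
#'
#' Reduces an N x N connectivity matrix to 7 within-network means (mean of
#' the off-diagonal entries among each network's parcels) and 21
#' between-network means (mean over all cross-network parcel pairs),
#' enumerating each unordered network pair once.
#'
#' @param fc Symmetric N x N matrix with unit diagonal.
#' @param atlas A [parcel_atlas()].
#' @return List with named numeric vectors `within` (length 7) and
#'   `between` (length `choose(7, 2)` = 21, names like `"VIN-SMN"`).
#' @export
network_means <- function(fc, atlas) {
  validate_atlas(atlas)
  fc <- as.matrix(fc)
  stopifnot(nrow(fc) == atlas$n_parcels, ncol(fc) == atlas$n_parcels)
  nets <- atlas$network_names
  lab <- as.character(atlas$network_labels)
  within <- vapply(nets, function(nm) {
    idx <- which(lab == nm)
    sub <- fc[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  pairs <- utils::combn(nets, 2L)
  between <- apply(pairs, 2L, function(p) {
    mean(fc[lab == p[1L], lab == p[2L]])
  })
  names(between) <- paste(pairs[1L, ], pairs[2L, ], sep = "-")
  list(within = within, between = between)
}

#' Transition magnitude of network-level connectivity
#'
#' Occupancy- and transition-weighted mean absolute difference of a
#' network summary `m` across state transitions:
#' \deqn{TM = \frac{\sum_{i \ne j} fo_i\, tp_{ij}\, |m_j - m_i|}
#'            {\sum_{i \ne j} fo_i\, tp_{ij}},}
#' evaluated elementwise over the 7 within-network and 21 between-network
#' summaries. States with missing summaries (or occupancy 0) are excluded
#' from both sums; with fewer than two contributing states the magnitude
#' is undefined (`NA`).
#'
#' @param state_summaries List of per-state summary vectors (each a named
#'   numeric vector, e.g. the `within` component of [network_means()];
#'   `NULL` for missing states).
#' @param tp K x K transition-probability matrix.
#' @param fo Length-K fractional occupancy.
#' @return Named numeric vector of nonnegative transition magnitudes.
#' @export
transition_magnitude <- function(state_summaries, tp, fo) {
  K <- length(fo)
  stopifnot(length(state_summaries) == K, all(dim(tp) == K))
  present <- which(!vapply(state_summaries, is.null, logical(1)) & fo > 0)
  if (length(present) == 0L) stop("no state summaries present")
  template <- state_summaries[[present[1L]]]
  if (length(present) < 2L)
    return(stats::setNames(rep(NA_real_, length(template)), names(template)))
  num <- den <- 0
  out <- 0 * template
  for (i in present) for (j in present) {
    if (i == j) next
    w <- fo[i] * tp[i, j]
    if (!is.finite(w)) next
    out <- out + w * abs(state_summaries[[j]] - state_summaries[[i]])
    den <- den + w
  }
  if (den == 0)
    return(stats::setNames(rep(NA_real_, length(template)), names(template)))
  out / den
}

#' Subject-level network connectivity summary
#'
#' Occupancy-weighted average of the per-state network means, renormalized
#' over the states whose connectivity is available.
#'
#' @param state_fc A [compute_state_fc()] result.
#' @param fo Length-K fractional occupancy.
#' @param atlas A [parcel_atlas()].
#' @return List with `within` (7) and `between` (21) named vectors.
#' @export
subject_connectivity <- function(state_fc, fo, atlas) {
  K <- length(state_fc$matrices)
  stopifnot(length(fo) == K)
  present <- which(!vapply(state_fc$matrices, is.null, logical(1)) & fo > 0)
  if (length(present) == 0L) stop("no state has usable connectivity")
  w <- fo[present] / sum(fo[present])
  sums <- lapply(present, function(k) network_means(state_fc$matrices[[k]], atlas))
  within <- Reduce(`+`, Map(function(s, wi) wi * s$within, sums, w))
  between <- Reduce(`+`, Map(function(s, wi) wi * s$between, sums, w))
  list(within = within, between = between)
}
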