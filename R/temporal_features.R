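#' Fractional occupancy of each state
#'
#' Proportion of the total observation time spent in each state; unvisited
#' states get 0. The per-state counts sum exactly to the sequence length,
#' so the fractions sum to 1 exactly.
#'
#' @param seq A [state_sequence()] (or integer vector).
#' @param K State count; taken from the sequence attribute if missing.
#' @return Numeric length-K vector summing to 1.
#' @export
fractional_occupancy <- function(seq, K = attr(seq, "K")) {
  K <- .check_labels(seq, K)
  tabulate(as.integer(seq), nbins = K) / length(seq)
}

.check_labels <- function(seq, K) {
  if (is.null(K)) stop("state count K is required")
  K <- as.integer(K)
  if (any(as.integer(seq) < 1L) || any(as.integer(seq) > K))
    stop("labels must lie in 1..K")
  K
}

#' Mean lifetime (dwell time) of each state
#'
#' Average length of the maximal runs of each state, in seconds.
#' Boundary-truncated first and last runs are included. States never
#' visited are `NA` (undefined, never zero).
#'
#' @inheritParams fractional_occupancy
#' @param fs Sampling rate (Hz).
#' @return Numeric length-K vector of seconds (`NA` for unvisited states).
#' @export
mean_lifetime <- function(seq, K = attr(seq, "K"), fs = attr(seq, "fs")) {
  K <- .check_labels(seq, K)
  stopifnot(fs > 0)
  r <- rle(as.integer(as.vector(seq)))
  out <- rep(NA_real_, K)
  for (k in unique(r$values))
    out[k] <- mean(r$lengths[r$values == k]) / fs
  out
}

#' Mean interval between consecutive visits to each state
#'
#' For each state, the gaps between the end of one visit and the start of
#' the next (exclusive of the visit durations themselves), averaged and
#' converted to seconds. States with fewer than two visits are `NA`.
#'
#' @inheritParams mean_lifetime
#' @return Numeric length-K vector of seconds.
#' @export
mean_interval <- function(seq, K = attr(seq, "K"), fs = attr(seq, "fs")) {
  K <- .check_labels(seq, K)
  stopifnot(fs > 0)
  r <- rle(as.integer(as.vector(seq)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- rep(NA_real_, K)
  for (k in unique(r$values)) {
    idx <- which(r$values == k)
    if (length(idx) >= 2L)
      out[k] <- mean(starts[idx[-1L]] - ends[idx[-length(idx)]] - 1L) / fs
  }
  out
}

#' Empirical transition probability matrix of a state sequence
#'
#' Counts consecutive label pairs and normalizes each visited state's row;
#' self-transitions are included by default. With `include_self = FALSE`
#' the diagonal is zeroed and rows renormalized over the off-diagonal
#' mass. Rows of unvisited states (or, without self-transitions, states
#' that never leave) are `NA`.
#'
#' @inheritParams fractional_occupancy
#' @param include_self Keep self-transitions (default TRUE).
#' @return K x K matrix with rows of visited states summing to 1.
#' @export
transition_matrix <- function(seq, K = attr(seq, "K"), include_self = TRUE) {
  K <- .check_labels(seq, K)
  s <- as.integer(as.vector(seq))
  if (length(s) < 2L) stop("need at least 2 samples")
  counts <- matrix(0, K, K)
  from <- s[-length(s)]; to <- s[-1L]
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  if (!include_self) diag(counts) <- 0
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' All temporal features of a decoded state sequence
#'
#' Convenience wrapper bundling [fractional_occupancy()],
#' [mean_lifetime()], [mean_interval()] and [transition_matrix()].
#'
#' @inheritParams mean_lifetime
#' @return A `temporal_features` list.
#' @export
temporal_features <- function(seq, K = attr(seq, "K"), fs = attr(seq, "fs")) {
  structure(list(fractional_occupancy = fractional_occupancy(seq, K),
                 mean_lifetime_s = mean_lifetime(seq, K, fs),
                 mean_interval_s = mean_interval(seq, K, fs),
                 transition_probs = transition_matrix(seq, K)),
            class = "temporal_features")
}
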