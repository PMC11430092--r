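#' Anti-aliased downsampling of parcel time series
#'
#' Applies a zero-phase low-pass FIR filter (Hamming-window design, cutoff
#' at 0.8 of the target Nyquist) before resampling each parcel's series to
#' `fs_target`. Edges are protected by constant padding, so a DC signal
#' passes unchanged. Upsampling is refused.
#'
#' @param series N x T numeric matrix (parcels in rows).
#' @param fs_in Input sampling rate (Hz).
#' @param fs_target Target sampling rate (Hz), default 250.
#' @return N x T' matrix with `T' = round(T * fs_target / fs_in)`.
#' @export
downsample <- function(series, fs_in, fs_target = 250) {
  series <- as.matrix(series)
  if (fs_in < fs_target) stop("fs_in < fs_target: upsampling not supported")
  if (any(!is.finite(series))) stop("non-finite values in input")
  if (fs_in == fs_target) return(series)
  Tn <- ncol(series)
  Tp <- as.integer(round(Tn * fs_target / fs_in))
  ntaps <- 129L
  # cutoff: 0.8 * new Nyquist, normalized to the input Nyquist
  wc <- 0.8 * fs_target / fs_in
  b <- signal::fir1(ntaps - 1L, wc, type = "low")
  b <- b / sum(b)                  # exact unit DC gain
  pad <- ntaps
  delay <- (ntaps - 1L) / 2L
  filt_row <- function(x) {
    xp <- c(rep(x[1L], pad), x, rep(x[Tn], pad))
    y <- stats::filter(xp, b, method = "convolution", sides = 1L)
    y[(pad + delay + 1L):(pad + delay + Tn)]
  }
  low <- t(apply(series, 1L, filt_row))
  idx <- as.integer(round(seq(1L, Tn, length.out = Tp)))
  low[, idx, drop = FALSE]
}

#' Amplitude envelope via the analytic signal
#'
#' Computes the modulus of the Hilbert analytic signal per parcel. The
#' first and last 5% of samples are flagged as boundary-affected
#' (attribute `boundary`), since the discrete Hilbert transform assumes
#' periodicity.
#'
#' @param series N x T numeric matrix, `T >= 16`.
#' @param fs Sampling rate (Hz), carried on the result.
#' @return Object of class `envelope_matrix`: an N x T nonnegative matrix
#'   with attributes `fs` and `boundary` (logical length-T mask).
#' @export
hilbert_envelope <- function(series, fs) {
  series <- as.matrix(series)
  if (any(!is.finite(series))) stop("non-finite values in input")
  Tn <- ncol(series)
  if (Tn < 16L) stop("need at least 16 samples")
  h <- numeric(Tn)
  if (Tn %% 2L == 0L) {
    h[1L] <- 1; h[Tn / 2L + 1L] <- 1; h[2L:(Tn / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((Tn + 1L) / 2L)] <- 2
  }
  env <- t(apply(series, 1L, function(x) {
    Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / Tn)
  }))
  nb <- max(1L, floor(0.05 * Tn))
  boundary <- rep(FALSE, Tn)
  boundary[c(seq_len(nb), (Tn - nb + 1L):Tn)] <- TRUE
  structure(env, fs = fs, boundary = boundary, class = "envelope_matrix")
}

#' Orthogonalize amplitude envelopes across parcels
#'
#' Removes shared variance between parcel envelopes (the residual
#' signature of source leakage) by making the demeaned parcel rows exactly
#' pairwise orthogonal over time. The default is QR orthogonalization
#' (sequential, order-preserving Householder QR of the time-by-parcel
#' matrix); `method = "symmetric"` uses the closest-orthogonal-matrix
#' (Loewdin / polar) variant, which treats parcels symmetrically.
#'
#' Each output component is rescaled to the magnitude of its triangular
#' factor (QR) or its original column norm (symmetric), so an already
#' orthogonal input is returned unchanged. Exactly collinear parcel pairs
#' do not fail: the Householder factorization still yields mutually
#' orthogonal components, the offending columns' scales are floored, and a
#' collinearity event is recorded in the `regularized` attribute (a column
#' is flagged when its triangular diagonal falls below 1e-8 of the
#' largest, i.e. condition number above 1e8).
#'
#' @param env N x T matrix (rows = parcels); `T > N` required.
#' @param method `"qr"` (default) or `"symmetric"`.
#' @return N x T matrix of orthogonalized, demeaned envelopes with
#'   attribute `regularized` (integer indices of collinear parcels).
#' @export
orthogonalize <- function(env, method = c("qr", "symmetric")) {
  method <- match.arg(method)
  X <- t(as.matrix(env))            # T x N, parcels in columns
  Tn <- nrow(X); N <- ncol(X)
  if (Tn <= N) stop("need more time samples than parcels (T > N)")
  if (any(!is.finite(X))) stop("non-finite values in input")
  X <- sweep(X, 2L, colMeans(X))
  if (method == "qr") {
    qq <- qr(X, LAPACK = TRUE)      # Householder with column pivoting
    piv <- qq$pivot
    Q <- qr.Q(qq)
    Rd <- diag(qr.R(qq))
    flagged <- piv[abs(Rd) < 1e-8 * max(abs(Rd))]
    scale <- abs(Rd)
    scale[abs(Rd) < 1e-8 * max(abs(Rd))] <- max(1e-8 * max(abs(Rd)), 1e-300)
    sgn <- ifelse(Rd < 0, -1, 1)
    Y <- matrix(0, Tn, N)
    Y[, piv] <- Q %*% diag(scale * sgn, N)   # back to input parcel order
  } else {
    sv <- svd(X)
    flagged <- which(sv$d < 1e-8 * max(sv$d))
    norms <- sqrt(colSums(X^2))
    Y <- (sv$u %*% t(sv$v)) %*% diag(norms, N)
  }
  out <- t(Y)
  fs <- attr(env, "fs")
  structure(out, fs = fs, regularized = flagged)
}
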