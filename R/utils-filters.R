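# Zero-phase narrowband filtering and analytic-signal extraction.
#
# All band-pass filtering in the package goes through a single primitive: the
# squared magnitude response of an order-`order` Butterworth filter applied in
# the frequency domain to a mirror-padded signal.  This is numerically
# equivalent to forward-backward ("filtfilt") time-domain filtering -- the
# forward-backward cascade has transfer function |H(f)|^2 and zero phase --
# but runs as one FFT per column, which matters for the 96-band filter bank.

#' Squared magnitude response of a Butterworth band-pass filter
#'
#' For `low <= 0` the response degenerates to a pure low-pass at `high`.
#'
#' @param f vector of (non-negative) frequencies in Hz.
#' @param low,high band edges in Hz.
#' @param order filter order of the one-way filter; the forward-backward
#'   cascade applied by [bp_filter()] has response `mag2 = |H|^2`.
#' @return numeric vector of gains in `[0, 1]`.
#' @keywords internal
butter_mag2 <- function(f, low, high, order = 4) {
  stopifnot(high > 0, high > low)
  if (low <= 0) {
    return(1 / (1 + (f / high)^(2 * order)))
  }
  f0sq <- low * high
  bw <- high - low
  g <- ifelse(f == 0, Inf, (f^2 - f0sq) / (f * bw))
  1 / (1 + g^(2 * order))
}

# mirror-pad rows of a matrix (no edge duplication); possibly asymmetric
.mirror_pad <- function(x, p_left, p_right = p_left) {
  n <- nrow(x)
  p_left <- min(p_left, n - 1L)
  p_right <- min(p_right, n - 1L)
  parts <- list()
  if (p_left > 0) parts <- c(parts, list(x[(p_left + 1):2, , drop = FALSE]))
  parts <- c(parts, list(x))
  if (p_right > 0) parts <- c(parts, list(x[(n - 1):(n - p_right), , drop = FALSE]))
  do.call(rbind, parts)
}

# choose mirror padding of at least p_min per side such that the padded
# length is highly composite (fast FFT); returns c(left, right)
.pad_lengths <- function(n, p_min) {
  p_min <- min(p_min, n - 1L)
  N <- stats::nextn(n + 2L * p_min, c(2, 3, 5))
  extra <- N - n - 2L * p_min
  left <- p_min + extra %/% 2L
  right <- p_min + (extra - extra %/% 2L)
  c(min(left, n - 1L), min(right, n - 1L))
}

.fold_freqs <- function(N, sfreq) {
  f <- (seq_len(N) - 1) * sfreq / N
  pmin(f, sfreq - f)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each column of `x` (time along rows) with the squared-magnitude
#' Butterworth response in the frequency domain after mirror padding, i.e. the
#' zero-phase equivalent of forward-backward filtering.
#'
#' @param x numeric vector or matrix (time x series).
#' @param sfreq sampling rate in Hz.
#' @param low,high band edges in Hz; `low <= 0` gives a low-pass.
#' @param order one-way Butterworth order (default 4).
#' @param pad_sec mirror padding on each side, in seconds (default 1).
#' @return filtered object of the same shape as `x`.
#' @export
bp_filter <- function(x, sfreq, low, high, order = 4, pad_sec = 1) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  p <- .pad_lengths(n, as.integer(round(pad_sec * sfreq)))
  xp <- .mirror_pad(x, p[1], p[2])
  N <- nrow(xp)
  mask <- butter_mag2(.fold_freqs(N, sfreq), low, high, order)
  # the mask is real and frequency-symmetric, so filtering is a real linear
  # map: pack column pairs into one complex FFT and split Re/Im afterwards
  nc <- ncol(xp)
  y <- matrix(NA_real_, N, nc)
  i1 <- seq(1L, nc, by = 2L)
  i2 <- i1 + 1L
  has2 <- i2 <= nc
  z <- xp[, i1, drop = FALSE] + 0i
  z[, has2] <- z[, has2, drop = FALSE] + 1i * xp[, i2[has2], drop = FALSE]
  z <- stats::mvfft(stats::mvfft(z) * mask, inverse = TRUE) / N
  y[, i1] <- Re(z)
  y[, i2[has2]] <- Im(z[, has2, drop = FALSE])
  y <- y[(p[1] + 1):(p[1] + n), , drop = FALSE]
  if (vec) drop(y) else y
}

#' Band-limited analytic signal
#'
#' Same filtering as [bp_filter()], followed in the same FFT pass by the
#' analytic-signal construction (negative frequencies zeroed, positive
#' doubled).  `Mod()` of the result is the band envelope, `Arg()` the
#' instantaneous phase.
#'
#' @inheritParams bp_filter
#' @return complex vector/matrix of the same shape as `x`.
#' @export
analytic_bp <- function(x, sfreq, low, high, order = 4, pad_sec = 1) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  p <- .pad_lengths(n, as.integer(round(pad_sec * sfreq)))
  xp <- .mirror_pad(x, p[1], p[2])
  N <- nrow(xp)
  mask <- butter_mag2(.fold_freqs(N, sfreq), low, high, order)
  amask <- numeric(N)
  amask[1L] <- 1
  if (N %% 2 == 0) {
    amask[N / 2 + 1L] <- 1
    if (N > 2) amask[2:(N / 2)] <- 2
  } else {
    amask[2:((N + 1) / 2)] <- 2
  }
  X <- stats::mvfft(xp) * (mask * amask)
  z <- stats::mvfft(X, inverse = TRUE) / N
  z <- z[(p[1] + 1):(p[1] + n), , drop = FALSE]
  if (vec) drop(z) else z
}

#' Savitzky-Golay smoothing with mirror-padded edges
#'
#' Least-squares local-polynomial smoothing (order 3, window 31 samples by
#' default, matching standard EOG preprocessing).  The trace is mirror-padded
#' by half a window so that the output has the input length with no phase
#' shift and the interior equals plain SG convolution.
#'
#' @param trace numeric vector.
#' @param order polynomial order (default 3).
#' @param window window length in samples; must be odd and `> order`.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_eog <- function(trace, order = 3, window = 31) {
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window <= order) stop("`window` must exceed `order`")
  if (length(trace) <= window) stop("trace shorter than the smoothing window")
  h <- (window - 1L) %/% 2L
  xp <- drop(.mirror_pad(matrix(trace, ncol = 1L), h, h))
  sm <- signal::sgolayfilt(xp, p = order, n = window)
  sm[(h + 1):(h + length(trace))]
}
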