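#' Design a Butterworth filter as second-order sections
#'
#' Computes the digital poles of an analog Butterworth prototype through the
#' bilinear transform and returns the filter as a cascade of biquads
#' (second-order sections). The SOS form stays numerically stable at the very
#' low normalized cutoffs this pipeline needs (e.g. a 7th-order high-pass at
#' 0.15 Hz with fs = 250 Hz), where expanded transfer-function polynomials
#' are unusable.
#'
#' @param order filter order (number of analog poles).
#' @param fc cutoff frequency in Hz (-3 dB point).
#' @param fs sampling frequency in Hz.
#' @param type `"low"` or `"high"`.
#' @return numeric matrix with one row per section and columns
#'   `b0 b1 b2 a0 a1 a2` (`a0` is always 1). Each section is normalized to
#'   unit gain at DC (low-pass) or Nyquist (high-pass).
#' @examples
#' sos <- butter_sos(7, 0.15, 250, "high")
#' nrow(sos) # ceiling(7/2) sections
#' @export
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  K <- 2 * fs
  wc <- K * tan(pi * fc / fs)           # pre-warped analog cutoff (rad/s)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # prototype poles, Re < 0
  sp <- if (type == "low") wc * p else wc / p
  zp <- (K + sp) / (K - sp)             # bilinear transform
  # digital zeros: all at -1 (low-pass) or +1 (high-pass)
  z0 <- if (type == "low") -1 else 1
  # pair complex-conjugate poles into biquads; odd order leaves one real pole
  idx <- order(abs(Im(zp)), decreasing = TRUE)
  zp <- zp[idx]
  sections <- list()
  used <- rep(FALSE, order)
  for (i in seq_len(order)) {
    if (used[i]) next
    if (abs(Im(zp[i])) > 1e-12) {
      jm <- which(!used & abs(zp - Conj(zp[i])) < 1e-8)[1]
      used[c(i, jm)] <- TRUE
      a1 <- -2 * Re(zp[i]); a2 <- Re(zp[i] * Conj(zp[i]))
      b <- c(1, -2 * z0, 1)
      a <- c(1, a1, a2)
    } else {
      used[i] <- TRUE
      b <- c(1, -z0, 0)
      a <- c(1, -Re(zp[i]), 0)
    }
    # normalize section gain at the passband anchor (z = 1 for LP, -1 for HP)
    zr <- if (type == "low") 1 else -1
    num <- sum(b * c(1, zr^-1, zr^-2))
    den <- sum(a * c(1, zr^-1, zr^-2))
    b <- b * abs(den / num)
    sections[[length(sections) + 1]] <- c(b, a)
  }
  out <- do.call(rbind, sections)
  colnames(out) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  out
}

#' Frequency response magnitude of an SOS filter
#'
#' @param sos matrix from [butter_sos()].
#' @param f frequencies in Hz.
#' @param fs sampling frequency in Hz.
#' @return numeric vector `|H(f)|` of the single-pass response.
#' @export
sos_freq_response <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs)
  H <- rep(1 + 0i, length(z))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    H <- H * num / den
  }
  abs(H)
}

# Odd (antisymmetric) reflection padding, forward-backward SOS filtering,
# trim. Doubling the pass squares the magnitude response and cancels the
# phase response, so the net group delay is zero.
sos_filtfilt <- function(sos, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen < 1L)
    stop("signal too short for zero-phase filtering (need > 1 sample of padding)")
  pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  xe <- c(pre, x, post)
  y <- sos_filter(sos, xe)
  y <- rev(sos_filter(sos, rev(y)))
  y[seq(padlen + 1L, padlen + n)]
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies a high-pass/low-pass Butterworth pair, each run
#' forward-backward over odd-reflection padding, to every row of a
#' channel-by-sample matrix. The padding length is 3 cycles of the high-pass
#' cutoff (the slowest transient), capped at the signal length; a signal
#' shorter than twice the padding is rejected rather than silently truncated.
#'
#' @param x numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param fs sampling frequency in Hz.
#' @param f_lo,f_hi band edges in Hz (high-pass and low-pass cutoffs).
#' @param order per-stage Butterworth order.
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, fs, f_lo, f_hi, order = 4L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  stopifnot(f_lo > 0, f_lo < f_hi, f_hi < fs / 2)
  padlen <- ceiling(3 * fs / f_lo)
  if (ncol(x) <= padlen || ncol(x) <= 3L * order)
    stop("input too short for stable zero-phase filtering at f_lo = ", f_lo,
         " Hz: need more than ", padlen, " samples (3 cycles of the ",
         "high-pass cutoff), got ", ncol(x))
  hp <- butter_sos(order, f_lo, fs, "high")
  lp <- butter_sos(order, f_hi, fs, "low")
  for (r in seq_len(nrow(x))) {
    y <- sos_filtfilt(hp, x[r, ], padlen)
    x[r, ] <- sos_filtfilt(lp, y, padlen)
  }
  if (vec) drop(x) else x
}
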