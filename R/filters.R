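# Zero-phase low-pass filtering.
#
# No DSP package ships in this environment, so the Butterworth design
# (analog prototype poles -> prewarp -> bilinear transform) and the
# forward-backward filter are implemented directly; coefficients were
# verified against an independent reference implementation during
# development (see tests).

# Coefficients of prod(z - r_i), descending powers.
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0 + 0i) - ri * c(0 + 0i, coef)
  coef
}

#' Digital Butterworth low-pass coefficients
#'
#' Designs an order-`order` low-pass Butterworth filter at `cutoff_hz` for
#' sampling rate `fs` via the bilinear transform, normalized to unit DC gain.
#'
#' @param order Filter order (default 4).
#' @param cutoff_hz -3 dB cutoff frequency, Hz; must be below Nyquist.
#' @param fs Sampling rate, Hz.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(order = 4L, cutoff_hz, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop_vw("cutoff must lie in (0, Nyquist) = (0, %g) Hz", fs / 2,
            class = "vasowave_config_error")
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p <- warped * complex(modulus = 1, argument = theta)
  fs2 <- 2 * fs
  pz <- (fs2 + p) / (fs2 - p)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)   # unit gain at DC
  list(b = b, a = a)
}

# Causal IIR filter (direct form I, zero initial state) built on the
# C-level stats::filter primitives.
lin_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  v <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  v <- v[nb:length(xp)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forward and backward with odd-reflection edge padding,
#' giving zero phase shift (event timing is preserved) and squared magnitude
#' response.
#'
#' @param b,a Filter coefficients from [butter_lowpass()].
#' @param x Numeric signal (gap-free).
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 30L * (length(a) - 1L))
  if (pad < 3L * (length(a) - 1L))
    stop_vw("signal too short (%d points) for zero-phase filtering", n,
            class = "vasowave_insufficient_data")
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- lin_filter(b, a, xp)
  y <- rev(lin_filter(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}
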