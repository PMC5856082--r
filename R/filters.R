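## Zero-phase IIR low-pass filtering.
##
## No signal-processing package is assumed: the Butterworth design
## (analog prototype + bilinear transform with prewarping), the direct-form
## II transposed filter, the steady-state initial conditions, and the
## forward-backward (zero-phase) pass with odd-reflection padding are
## implemented here and validated against an independent reference in the
## test suite.

## Butterworth low-pass coefficients, normalized cutoff Wn in (0, 1)
## (1 = Nyquist).  Returns list(b, a).
butter_lowpass <- function(order, Wn) {
  if (Wn <= 0 || Wn >= 1) ff_config_error("normalized cutoff must be in (0, 1)")
  fs2 <- 4                      # 2 * (virtual fs = 2), bilinear constant
  warped <- fs2 * tan(pi * Wn / 2)
  k <- seq_len(order)
  p <- warped * exp(1i * pi * (2 * k - 1) / (2 * order) + 1i * pi / 2)
  gain <- warped^order
  pz <- (fs2 + p) / (fs2 - p)          # bilinear transform of poles
  gain_z <- gain / Re(prod(fs2 - p))   # zeros at s = Inf -> z = -1
  a <- Re(poly_from_roots(pz))
  b <- gain_z * Re(poly_from_roots(rep(-1 + 0i, order)))
  list(b = b, a = a)
}

## Monic polynomial coefficients from roots (descending powers).
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf) * ri
  cf
}

## Direct-form II transposed IIR filter with initial state zi.
lfilter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b))) / a[1]
  a <- c(a, numeric(nf - length(a))) / a[1]
  z <- if (is.null(zi)) numeric(nf - 1) else zi
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2)
      z[1:(nf - 2)] <- b[2:(nf - 1)] * xi + z[2:(nf - 1)] - a[2:(nf - 1)] * yi
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  list(y = y, z = z)
}

## Steady-state initial conditions for a unit-step input
## (companion-matrix solve), so transients die at the signal edges.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b))) / a[1]
  a <- c(a, numeric(nf - length(a))) / a[1]
  m <- nf - 1
  comp_t <- rbind(-a[2:nf], cbind(diag(1, m - 1), numeric(m - 1)))
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(m) - t(comp_t), B)
}

## Forward-backward filtering with odd-reflection padding; zero phase,
## squared magnitude response.
filtfilt <- function(b, a, x) {
  n <- length(x)
  padlen <- 3 * max(length(a), length(b))
  if (n <= padlen)
    ff_contract_error(sprintf(
      "signal too short to filter: %d samples <= pad length %d", n, padlen))
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])$y
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1])$y
  rev(y)[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a channel forward and backward with a Butterworth low-pass
#' (default order 4), giving zero phase distortion, unit DC gain, and the
#' squared magnitude response of the one-pass filter.  Edge transients are
#' suppressed by odd-reflection padding.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz; must be below `fs/2`.
#' @param order filter order of the one-pass design.
#' @return filtered vector, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff, order = 4) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    ff_config_error("cutoff must lie strictly between 0 and fs/2")
  ba <- butter_lowpass(order, cutoff / (fs / 2))
  filtfilt(ba$b, ba$a, x)
}
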