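#' Gaussian-derivative mother wavelet
#'
#' Returns the real mother wavelet obtained by taking the `p`-th derivative
#' of a Gaussian, \eqn{\psi_p(t) \propto d^p/dt^p\, e^{-t^2}}, normalised to
#' unit L2 norm on its effective support. For `p = 6` this is the wavelet
#' conventionally called "gaus6"; it is real-valued, admissible (zero mean)
#' and well localised in both time and frequency, which is why it is a
#' common choice for EEG scalograms.
#'
#' The p-th derivative of \eqn{e^{-t^2}} equals
#' \eqn{(-1)^p H_p(t) e^{-t^2}} where \eqn{H_p} is the physicists' Hermite
#' polynomial, computed here by the three-term recurrence. The sign is
#' irrelevant for scalogram energy and for Pearson correlation and is kept
#' as the recurrence produces it.
#'
#' @param p derivative order (integer >= 1); default 6.
#' @return A function of one numeric argument evaluating \eqn{\psi_p(t)}.
#' @examples
#' psi <- gaus_wavelet(6)
#' t <- seq(-5, 5, length.out = 1e4)
#' sum(psi(t)^2) * diff(t[1:2])   # ~ 1 (unit energy)
#' @export
gaus_wavelet <- function(p = 6) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 1, p == as.integer(p))
  p <- as.integer(p)
  hermite_coefs <- function(n) {
    # physicists' Hermite H_n, coefficient vector in increasing powers
    h0 <- 1
    if (n == 0) return(h0)
    h1 <- c(0, 2)
    if (n == 1) return(h1)
    for (k in 2:n) {
      hk <- 2 * c(0, h1) - 2 * (k - 1) * c(h0, 0, 0)
      h0 <- h1
      h1 <- hk
    }
    h1
  }
  coefs <- hermite_coefs(p)
  raw <- function(t) {
    pow <- outer(t, seq_along(coefs) - 1, "^")
    drop(pow %*% coefs) * exp(-t^2) * (-1)^p
  }
  # unit-energy normalisation, computed once on a dense grid over the
  # effective support [-WAVELET_SUPPORT, WAVELET_SUPPORT]
  grid <- seq(-WAVELET_SUPPORT, WAVELET_SUPPORT, length.out = 20001L)
  nrm <- sqrt(sum(raw(grid)^2) * (grid[2] - grid[1]))
  function(t) raw(t) / nrm
}

# Effective support half-width of the Gaussian-derivative family (the
# envelope e^{-t^2} is below 1e-10 outside |t| > 5).
WAVELET_SUPPORT <- 5

#' Centre frequency of a Gaussian-derivative wavelet
#'
#' Peak of the wavelet's magnitude spectrum, in cycles per unit of the
#' mother-wavelet time variable. At scale `a` and sampling interval
#' `1/fs` the scalogram row responds maximally near
#' `wavelet_center_frequency(p) * fs / a` Hz. Computed numerically from a
#' dense sampling of the wavelet (FFT magnitude argmax with parabolic
#' refinement), matching the pragmatic convention of wavelet toolboxes.
#'
#' @param p derivative order.
#' @return Centre frequency in cycles per unit time (scalar).
#' @export
wavelet_center_frequency <- function(p = 6) {
  psi <- gaus_wavelet(p)
  n <- 2^13
  dt <- 2 * WAVELET_SUPPORT / n
  t <- seq(-WAVELET_SUPPORT, WAVELET_SUPPORT - dt, length.out = n)
  npad <- 2^20   # zero-pad for fine frequency resolution
  spec <- Mod(stats::fft(c(psi(t), numeric(npad - n))))[seq_len(npad %/% 2)]
  n <- npad
  i <- which.max(spec)
  # parabolic interpolation around the discrete peak
  if (i > 1 && i < length(spec)) {
    y1 <- spec[i - 1]; y2 <- spec[i]; y3 <- spec[i + 1]
    d <- (y1 - y3) / (2 * (y1 - 2 * y2 + y3))
    i <- i + d
  }
  (i - 1) / (n * dt)
}
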