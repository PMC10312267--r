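#' Canonical haemodynamic response kernel
#'
#' Fixed double-gamma impulse response (peak 6 s, undershoot 16 s,
#' peak-to-undershoot ratio 6), normalised to unit integral. The same
#' kernel is used by the generator (convolution of neural states) and by
#' the spectral forward model (its transfer function), which keeps the
#' forward and inverse models consistent. Haemodynamics are fixed, not
#' estimated.
#'
#' @param dt Sampling step (s).
#' @param length_s Kernel support (s); default 32.
#' @return Numeric vector of kernel weights at `seq(0, length_s, by = dt)`.
#' @export
hrf_kernel <- function(dt, length_s = 32) {
  stopifnot(dt > 0)
  t <- seq(0, length_s, by = dt)
  # shape/scale gammas: peak at (shape-1)*scale
  h <- dgamma(t, shape = 7, scale = 1) - dgamma(t, shape = 17, scale = 1) / 6
  h / sum(h * dt)
}

#' Haemodynamic transfer function
#'
#' Continuous Fourier transform of [hrf_kernel()] evaluated at the given
#' frequencies, used as the scalar gain `h(f)` in the spectral forward
#' model.
#'
#' @param freq Frequencies (Hz).
#' @param dt Internal sampling step for the kernel (default 0.05 s).
#' @return Complex vector, one value per frequency.
#' @export
hrf_transfer <- function(freq, dt = 0.05) {
  k <- hrf_kernel(dt)
  t <- seq_along(k) * dt - dt
  vapply(freq, function(f) sum(k * exp(-2i * pi * f * t)) * dt, complex(1))
}
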