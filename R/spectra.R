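#' Frequency grid for spectral estimation
#'
#' Default grid: `n` logarithmically spaced points from
#' `max(1/window-length, fmin_floor_hz)` to `min(fmax_hz, Nyquist)`. This
#' covers the band over which the haemodynamic model is informative; the
#' default floor of 1/128 Hz matches the conventional 128 s high-pass cut
#' below which slow drifts and estimator bias dominate the spectrum.
#'
#' @param tr_s Sampling interval (s).
#' @param window_s Record length (s); its reciprocal bounds the lowest
#'   frequency from below.
#' @param n Number of grid points.
#' @param fmax_hz Upper bound (Hz), capped at Nyquist.
#' @param fmin_floor_hz Lower-bound floor (Hz).
#' @return An object of class `frequency_grid` (list with `frequencies`).
#' @export
frequency_grid <- function(tr_s, window_s, n = 32, fmax_hz = 0.25,
                           fmin_floor_hz = 1 / 128) {
  stopifnot(tr_s > 0, window_s > tr_s, n >= 2)
  nyq <- 1 / (2 * tr_s)
  fmax <- min(fmax_hz, nyq)
  fmin <- max(1 / window_s, fmin_floor_hz)
  stopifnot(fmin < fmax)
  f <- exp(seq(log(fmin), log(fmax), length.out = n))
  new_frequency_grid(f, tr_s)
}

#' @rdname frequency_grid
#' @param frequencies Explicit strictly-increasing positive frequencies
#'   (Hz) for a custom grid.
#' @export
new_frequency_grid <- function(frequencies, tr_s = NULL) {
  frequencies <- as.numeric(frequencies)
  if (any(diff(frequencies) <= 0)) stop("frequencies must be strictly increasing", call. = FALSE)
  if (any(frequencies <= 0)) stop("frequencies must be > 0", call. = FALSE)
  if (!is.null(tr_s) && max(frequencies) > 1 / (2 * tr_s) + 1e-12) {
    stop("grid exceeds the Nyquist frequency", call. = FALSE)
  }
  structure(list(frequencies = frequencies), class = "frequency_grid")
}

#' Cross-spectral density container
#'
#' A Hermitian complex region-by-region matrix per frequency, stored as a
#' `nfreq x p x p` complex array. Diagonals must be real and non-negative
#' (within tolerance).
#'
#' @param grid A [frequency_grid()].
#' @param matrices Complex array `nfreq x p x p`.
#' @param tol Hermitian/positivity tolerance.
#' @return An object of class `cross_spectrum`.
#' @export
cross_spectrum <- function(grid, matrices, tol = 1e-10) {
  stopifnot(inherits(grid, "frequency_grid"))
  d <- dim(matrices)
  if (length(d) != 3 || d[2] != d[3] || d[1] != length(grid$frequencies)) {
    stop("matrices must be an nfreq x p x p array", call. = FALSE)
  }
  scale <- max(abs(matrices), 1)
  for (k in seq_len(d[1])) {
    M <- matrices[k, , ]
    if (max(Mod(M - Conj(t(M)))) > tol * scale) {
      stop(sprintf("matrix at frequency index %d is not Hermitian", k), call. = FALSE)
    }
    if (any(Re(diag(M)) < -tol * scale)) {
      stop(sprintf("negative diagonal power at frequency index %d", k), call. = FALSE)
    }
  }
  structure(list(grid = grid, matrices = matrices), class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  d <- dim(x$matrices)
  cat(sprintf("<cross_spectrum> %d regions at %d frequencies (%.4g-%.4g Hz)\n",
              d[2], d[1], min(x$grid$frequencies), max(x$grid$frequencies)))
  invisible(x)
}

detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}

#' Fit a multivariate autoregression
#'
#' Least-squares MAR of the stated order on the (mean- and
#' linear-trend-corrected) timeseries. Order 0 returns no coefficients and
#' the sample covariance as innovation covariance.
#'
#' @param ts A [region_timeseries()] or a numeric time-by-region matrix.
#' @param order AR order (>= 0).
#' @param tr_s Sampling interval, required when `ts` is a bare matrix.
#' @return List with `coef` (array `order x p x p`; lag-k predictor matrix
#'   at `[k, , ]`), `noise_cov` (innovation covariance), `order`, `tr_s`,
#'   class `mar_fit`.
#' @export
fit_mar <- function(ts, order = 8, tr_s = NULL) {
  if (inherits(ts, "region_timeseries")) {
    Y <- ts$values
    tr_s <- ts$tr_s
  } else {
    Y <- as.matrix(ts)
    if (is.null(tr_s)) stop("tr_s required for matrix input", call. = FALSE)
  }
  p <- ncol(Y)
  n <- nrow(Y)
  if (order < 0) stop("order must be >= 0", call. = FALSE)
  if (n <= order * p + 1) stop("too few samples for this order", call. = FALSE)
  Y <- apply(Y, 2, detrend)

  if (order == 0) {
    S <- crossprod(Y) / (n - 1)
    return(structure(list(coef = array(0, c(0, p, p)), noise_cov = S,
                          order = 0L, tr_s = tr_s), class = "mar_fit"))
  }
  rows <- (order + 1):n
  X <- do.call(cbind, lapply(seq_len(order), function(k) Y[rows - k, , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient autoregression design; try a lower order", call. = FALSE)
  }
  B <- qr.coef(qx, Y[rows, , drop = FALSE])        # (order*p) x p
  resid <- Y[rows, , drop = FALSE] - X %*% B
  S <- crossprod(resid) / (length(rows) - order * p)
  S <- (S + t(S)) / 2
  coef <- array(0, c(order, p, p))
  for (k in seq_len(order)) {
    # row i of the lag-k matrix maps Y_{t-k} to region i
    coef[k, , ] <- t(B[((k - 1) * p + 1):(k * p), , drop = FALSE])
  }
  structure(list(coef = coef, noise_cov = S, order = as.integer(order),
                 tr_s = tr_s), class = "mar_fit")
}

#' Cross-spectral density from a MAR fit
#'
#' Evaluates the parametric one-sided spectrum
#' `S(f) = 2 dt H(f) Sigma H(f)^H` with `H(f)` the MAR transfer function
#' `(I - sum_k A_k exp(-2 pi i f k dt))^{-1}`.
#'
#' @param mar A `mar_fit`.
#' @param grid A [frequency_grid()].
#' @return A [cross_spectrum()].
#' @export
mar_to_csd <- function(mar, grid) {
  stopifnot(inherits(mar, "mar_fit"), inherits(grid, "frequency_grid"))
  dtt <- mar$tr_s
  if (max(grid$frequencies) > 1 / (2 * dtt) + 1e-12) {
    stop("grid exceeds the Nyquist frequency for this sampling interval", call. = FALSE)
  }
  p <- ncol(mar$noise_cov)
  nf <- length(grid$frequencies)
  out <- array(complex(real = 0), c(nf, p, p))
  for (k in seq_len(nf)) {
    f <- grid$frequencies[k]
    Af <- diag(p) + 0i
    for (l in seq_len(mar$order)) {
      Af <- Af - mar$coef[l, , ] * exp(-2i * pi * f * l * dtt)
    }
    H <- solve(Af)
    S <- 2 * dtt * H %*% mar$noise_cov %*% Conj(t(H))
    out[k, , ] <- (S + Conj(t(S))) / 2
  }
  cross_spectrum(grid, out, tol = 1e-8)
}

#' Cross-spectral features of one subject
#'
#' Convenience wrapper: detrended MAR fit of the stated order, then the
#' parametric cross-spectrum on the default grid for the record.
#'
#' @param ts A [region_timeseries()].
#' @param order MAR order (default 8).
#' @param grid Optional [frequency_grid()]; defaults to
#'   [frequency_grid()] over the record length.
#' @param n_freq,fmax_hz Grid settings when `grid` is `NULL`.
#' @return A [cross_spectrum()].
#' @export
csd_features <- function(ts, order = 8, grid = NULL, n_freq = 32, fmax_hz = 0.25) {
  stopifnot(inherits(ts, "region_timeseries"))
  if (is.null(grid)) {
    grid <- frequency_grid(ts$tr_s, nrow(ts$values) * ts$tr_s,
                           n = n_freq, fmax_hz = fmax_hz)
  }
  mar_to_csd(fit_mar(ts, order = order), grid)
}
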