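#' Block-design input vector
#'
#' Builds the exogenous input u(t), sampled at the TR, for a block design:
#' an initial countdown, then `n_blocks` cycles of stimulus (u = 1),
#' behavioural response and fixation (u = 0). The vector is zero-padded (or
#' truncated) to `floor(duration_s / tr_s)` samples, since the scheduled
#' block sequence and the run length are independent settings.
#'
#' @param config A [sim_config()].
#' @return Numeric 0/1 vector of length `floor(duration_s / tr_s)`.
#' @export
make_block_schedule <- function(config) {
  validate_sim_config(config)
  nt <- n_samples(config)
  u <- numeric(nt)
  if (config$n_blocks == 0 || nt == 0) return(u)
  t <- (seq_len(nt) - 1) * config$tr_s
  cycle <- config$block_s + config$response_s + config$fixation_s
  for (b in seq_len(config$n_blocks)) {
    on <- config$countdown_s + (b - 1) * cycle
    u[t >= on & t < on + config$block_s] <- 1
  }
  u
}

#' Input power spectrum of a sampled schedule
#'
#' Power of the deterministic input at arbitrary frequencies, from the
#' discrete-time Fourier transform of the (mean-corrected) input vector,
#' normalised per unit time so it is commensurate with the stochastic
#' one-sided spectral densities used elsewhere.
#'
#' @param u Input vector sampled at `tr_s`.
#' @param freq Frequencies (Hz) at which to evaluate.
#' @param tr_s Sampling interval (s).
#' @return Numeric vector of input power at each frequency.
#' @export
schedule_power <- function(u, freq, tr_s) {
  stopifnot(tr_s > 0, all(freq > 0))
  if (length(u) == 0 || all(u == 0)) return(numeric(length(freq)))
  u <- u - mean(u)
  t <- (seq_along(u) - 1) * tr_s
  total_t <- length(u) * tr_s
  vapply(freq, function(f) {
    U <- sum(u * exp(-2i * pi * f * t)) * tr_s
    2 * Mod(U)^2 / total_t
  }, numeric(1))
}
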