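## Spectral DCM: parameter packing, priors, forward prediction, and
## variational-Laplace inversion.

# fixed base constants of the spectral noise model: one-sided power-law
# densities amplitude * f^(-exponent), amplitudes/exponents scaled by
# exp(log-parameter) around these bases
dcm_spectral_bases <- function() {
  c(av0 = 1, bv0 = 1, ae0 = 4, be0 = 0.5)
}

#' Parameter vector layout of the spectral DCM
#'
#' Fixed documented order: A off-diagonals row-major (for each row i, the
#' entries j != i left to right), then the self-connection log-scaling
#' values, then the driving weights C, then the four spectral parameters
#' (log-amplitude and log-exponent of the neural fluctuations, then of the
#' observation noise).
#'
#' @param p Number of regions.
#' @return List of index vectors `A`, `self`, `C`, `spectral`, total
#'   length `n`, and `a_block` (the A off-diagonals plus self-connections,
#'   the "invariant connectivity" block the quality indices are based on).
#' @export
dcm_par_layout <- function(p) {
  nA <- p * (p - 1)
  list(A = seq_len(nA),
       self = nA + seq_len(p),
       C = nA + p + seq_len(p),
       spectral = nA + 2L * p + 1:4,
       a_block = seq_len(nA + p),
       n = nA + 2L * p + 4L)
}

#' DCM parameter set
#'
#' @param graph A [connectivity_graph()].
#' @param neural_log_amplitude,neural_log_exponent Log-scaling of the
#'   endogenous fluctuation spectrum around its base (amplitude 1,
#'   exponent 1).
#' @param observation_log_amplitude,observation_log_exponent Log-scaling
#'   of the observation-noise spectrum around its base (amplitude 4,
#'   exponent 0.5).
#' @return An object of class `dcm_parameters`.
#' @export
dcm_parameters <- function(graph, neural_log_amplitude = 0,
                           neural_log_exponent = 0,
                           observation_log_amplitude = 0,
                           observation_log_exponent = 0) {
  stopifnot(inherits(graph, "connectivity_graph"))
  spectral <- c(neural_log_amplitude, neural_log_exponent,
                observation_log_amplitude, observation_log_exponent)
  if (any(!is.finite(spectral))) stop("non-finite spectral parameters", call. = FALSE)
  structure(list(graph = graph, spectral = spectral), class = "dcm_parameters")
}

#' Convert between DCM parameters and the flat vector
#'
#' @param params A [dcm_parameters()].
#' @return `vectorize_parameters` returns a numeric vector in
#'   [dcm_par_layout()] order; `parameters_from_vector` inverts it.
#' @export
vectorize_parameters <- function(params) {
  stopifnot(inherits(params, "dcm_parameters"))
  g <- params$graph
  p <- n_regions(g)
  offd <- as.numeric(t(g$off_diagonal))[as.numeric(t(diag(p))) == 0]
  c(offd, g$self_log_scale, g$driving_weights, params$spectral)
}

#' @rdname vectorize_parameters
#' @param theta Numeric vector in layout order.
#' @param p Number of regions.
#' @export
parameters_from_vector <- function(theta, p) {
  lay <- dcm_par_layout(p)
  stopifnot(length(theta) == lay$n)
  A <- matrix(0, p, p)
  idx <- 1
  for (i in seq_len(p)) for (j in seq_len(p)) if (j != i) {
    A[i, j] <- theta[idx]; idx <- idx + 1
  }
  g <- connectivity_graph(A, theta[lay$self], theta[lay$C],
                          check_stability = FALSE)
  dcm_parameters(g, theta[lay$spectral][1], theta[lay$spectral][2],
                 theta[lay$spectral][3], theta[lay$spectral][4])
}

#' Shrinkage priors over DCM parameters
#'
#' Zero-mean multivariate normal prior in vector layout order: between-
#' region coupling N(0, 1/64) Hz (the shrinkage prior: absent evidence,
#' no connectivity), self-connection log-scaling N(0, 1/256), driving
#' weights N(0, 1/64) and spectral parameters N(0, 1/64).
#'
#' @param n_regions Number of regions.
#' @param a_variance,self_variance,c_variance,spectral_variance Prior
#'   variances per block (configurable defaults).
#' @param mean Optional prior mean vector (defaults to zero).
#' @return An object of class `dcm_priors` (fields `mean`, `covariance`).
#' @export
dcm_priors <- function(n_regions, a_variance = 1 / 64,
                       self_variance = 1 / 256, c_variance = 1 / 64,
                       spectral_variance = 1 / 64, mean = NULL) {
  lay <- dcm_par_layout(n_regions)
  v <- numeric(lay$n)
  v[lay$A] <- a_variance
  v[lay$self] <- self_variance
  v[lay$C] <- c_variance
  v[lay$spectral] <- spectral_variance
  if (is.null(mean)) mean <- numeric(lay$n)
  stopifnot(length(mean) == lay$n)
  structure(list(mean = as.numeric(mean), covariance = diag(v),
                 n_regions = as.integer(n_regions)),
            class = "dcm_priors")
}

# stacked data vector matching the C++ ordering: per frequency, Re of the
# upper triangle incl. diagonal (column-major), then Im of the strict
# upper triangle
stack_csd <- function(cs) {
  m <- cs$matrices
  nf <- dim(m)[1]; p <- dim(m)[2]
  ur <- which(upper.tri(matrix(0, p, p), diag = TRUE))
  ui <- which(upper.tri(matrix(0, p, p)))
  out <- numeric(nf * (length(ur) + length(ui)))
  idx <- 0
  for (k in seq_len(nf)) {
    G <- m[k, , ]
    out[idx + seq_along(ur)] <- Re(G[ur]); idx <- idx + length(ur)
    out[idx + seq_along(ui)] <- Im(G[ui]); idx <- idx + length(ui)
  }
  out
}

#' Predicted cross-spectral density
#'
#' Evaluates the spectral forward model
#' `G_y(f) = K(f) G_v(f) K(f)^H + G_e(f)` with transfer
#' `K(f) = h(f) (2 pi i f I - A_eff)^{-1}` (haemodynamic gain `h` times the
#' resolvent of the effective coupling), power-law neural fluctuation
#' spectrum `G_v` (plus driving-weighted deterministic input power when
#' supplied) and power-law observation spectrum `G_e`.
#'
#' @param params A [dcm_parameters()] or a bare parameter vector (then `p`
#'   must be given).
#' @param grid A [frequency_grid()].
#' @param input_power Optional vector of deterministic input power at each
#'   grid frequency (see [schedule_power()]); `NULL` for none.
#' @param p Number of regions when `params` is a bare vector.
#' @return A [cross_spectrum()].
#' @export
predict_csd <- function(params, grid, input_power = NULL, p = NULL) {
  if (inherits(params, "dcm_parameters")) {
    p <- n_regions(params$graph)
    theta <- vectorize_parameters(params)
  } else {
    theta <- as.numeric(params)
    if (is.null(p)) stop("p required for bare parameter vectors", call. = FALSE)
  }
  freq <- grid$frequencies
  if (is.null(input_power)) input_power <- numeric(length(freq))
  stopifnot(length(input_power) == length(freq))
  b <- dcm_spectral_bases()
  h <- hrf_transfer(freq)
  cube <- csd_predict_cube_cpp(theta, p, freq, h, input_power,
                               b["av0"], b["bv0"], b["ae0"], b["be0"])
  m <- array(complex(real = 0), c(length(freq), p, p))
  for (k in seq_along(freq)) m[k, , ] <- cube[, , k]
  cross_spectrum(grid, m, tol = 1e-8)
}

ldet <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) stop("matrix not positive definite", call. = FALSE)
  2 * sum(log(diag(ch)))
}

# KL( N(mq, Sq) || N(mp, Sp) ) in nats
gaussian_kl_core <- function(mq, Sq, mp, Sp) {
  d <- length(mq)
  Sp_inv <- solve(Sp)
  dm <- mq - mp
  0.5 * (sum(diag(Sp_inv %*% Sq)) + sum(dm * (Sp_inv %*% dm)) - d +
           ldet(Sp) - ldet(Sq))
}

default_vl_settings <- function() {
  list(max_iterations = 64L, tol_nats = 0.01, consecutive = 4L,
       hyper_prior_mean = 6, hyper_prior_var = 1 / 128,
       damping_init = 1, damping_max = 1e8, fd_step = 1e-4)
}

#' Invert a spectral DCM by variational Laplace
#'
#' Gauss-Newton ascent with Levenberg-Marquardt damping on the variational
#' free energy of a Gaussian observation model over the stacked real and
#' imaginary cross-spectrum parts, with a single error log-precision
#' hyperparameter (prior N(6, 1/128)) updated alongside. The observed
#' spectrum is rescaled once so its average (log) diagonal power matches
#' the prior-mean prediction, which fixes the arbitrary units of BOLD
#' data; the scale is recorded on the output. Accepted-step free energy is
#' non-decreasing by construction (rejected steps raise the damping).
#'
#' @param observed A [cross_spectrum()].
#' @param priors A [dcm_priors()] for the matching number of regions.
#' @param settings Optional list overriding max_iterations (64), tol_nats
#'   (0.01), consecutive accepted small steps for convergence (4),
#'   hyper_prior_mean/var, damping_init and fd_step.
#' @param input_power Optional deterministic input power per grid
#'   frequency (task runs).
#' @param feature_weights Optional per-frequency feature noise SDs (data
#'   units, from [calibrate_feature_noise()]); when supplied the residual
#'   at each frequency is standardised by its measured sampling noise
#'   instead of by raw spectral power. [fit_subject_dcm()] supplies these
#'   by default.
#' @return An object of class `dcm_posterior`: fields `mean`,
#'   `covariance`, `free_energy`, `accuracy`, `complexity` (KL of the
#'   posterior from the prior; `free_energy = accuracy - complexity`
#'   exactly), `n_iterations`, `converged`, `f_trace` (accepted-step free
#'   energies), `lambda` (noise log-precision), `scale`, plus the priors
#'   and data needed to re-invert.
#' @export
variational_laplace <- function(observed, priors, settings = list(),
                                input_power = NULL, feature_weights = NULL) {
  stopifnot(inherits(observed, "cross_spectrum"), inherits(priors, "dcm_priors"))
  s <- utils::modifyList(default_vl_settings(), settings)
  p <- dim(observed$matrices)[2]
  if (p != priors$n_regions) stop("region count mismatch between data and priors", call. = FALSE)
  freq <- observed$grid$frequencies
  if (is.null(input_power)) input_power <- numeric(length(freq))
  b <- dcm_spectral_bases()
  h <- hrf_transfer(freq)
  lay <- dcm_par_layout(p)

  raw_fwd <- function(theta) {
    csd_predict_stack_cpp(theta, p, freq, h, input_power,
                          b["av0"], b["bv0"], b["ae0"], b["be0"])
  }
  raw_jac <- function(theta) {
    csd_jacobian_cpp(theta, p, freq, h, input_power,
                     b["av0"], b["bv0"], b["ae0"], b["be0"], s$fd_step)
  }
  fwd <- function(theta) wvec * raw_fwd(theta)
  jac <- function(theta) wvec * raw_jac(theta)

  mu0 <- priors$mean
  S0 <- priors$covariance
  P0 <- solve(S0)
  ldS0 <- ldet(S0)

  # diagonal positions within each stacked p^2 frequency block
  diag_in_blk <- cumsum(seq_len(p))
  nblk <- p * (p + 1) / 2 + p * (p - 1) / 2
  diag_pos <- as.numeric(outer(diag_in_blk, (seq_along(freq) - 1) * nblk, `+`))
  obs_stack <- stack_csd(observed)
  obs_pow <- pmax(obs_stack[diag_pos], 1e-12)
  pred_pow <- pmax(raw_fwd(mu0)[diag_pos], 1e-12)
  # match units on the lower third of the grid, where the neural signal
  # dominates: gross level mismatches are then absorbed by the scalar
  # scale and by the observation-noise amplitude rather than contorting
  # the coupling parameters
  hi <- rep(seq_along(freq) <= length(freq) / 3, each = p)
  scale <- exp(mean(log(pred_pow[hi])) - mean(log(obs_pow[hi])))
  if (is.null(feature_weights)) {
    # per-frequency standardisation: spectra span orders of magnitude
    # over the grid, so each frequency block (p^2 stacked entries) is
    # divided by the geometric-mean observed diagonal power at that
    # frequency, leaving one homoscedastic log-precision hyperparameter
    gm_k <- exp(colMeans(matrix(log(obs_pow * scale), p, length(freq))))
    wvec <- rep(1 / gm_k, each = nblk)
  } else {
    # measured reliability weighting: feature_weights holds the
    # split-half sampling noise SD per frequency (raw data units; see
    # calibrate_feature_noise); frequencies whose features are mostly
    # estimator noise are downweighted accordingly
    stopifnot(length(feature_weights) == length(freq),
              all(feature_weights > 0))
    wvec <- rep(1 / (feature_weights * scale), each = nblk)
  }
  y <- obs_stack * scale * wvec
  N <- length(y)

  vL <- s$hyper_prior_var
  etaL <- s$hyper_prior_mean

  eval_point <- function(mu, lambda) {
    g <- fwd(mu)
    J <- jac(mu)
    r <- y - g
    rss <- sum(r^2)
    # coordinate ascent on the noise log-precision (Newton, few steps)
    for (it in 1:8) {
      Pp <- exp(lambda) * crossprod(J) + P0
      Sg <- tryCatch(chol2inv(chol(Pp)), error = function(e) NULL)
      if (is.null(Sg)) return(NULL)
      trJSJ <- sum((J %*% Sg) * J)
      grad <- -0.5 * exp(lambda) * (rss + trJSJ) + 0.5 * N - (lambda - etaL) / vL
      hess <- -0.5 * exp(lambda) * (rss + trJSJ) - 1 / vL
      step <- grad / hess
      lambda <- min(max(lambda - step, -8), 16)
      if (abs(step) < 1e-6) break
    }
    Pp <- exp(lambda) * crossprod(J) + P0
    Sg <- tryCatch(chol2inv(chol(Pp)), error = function(e) NULL)
    if (is.null(Sg)) return(NULL)
    trJSJ <- sum((J %*% Sg) * J)
    varL <- 1 / (0.5 * exp(lambda) * (rss + trJSJ) + 1 / vL)
    acc <- -0.5 * exp(lambda) * (rss + trJSJ) + 0.5 * N * lambda -
      0.5 * N * log(2 * pi)
    dm <- mu - mu0
    klt <- 0.5 * (sum(diag(P0 %*% Sg)) + sum(dm * (P0 %*% dm)) - lay$n +
                    ldS0 - ldet(Sg))
    kll <- 0.5 * (varL / vL + (lambda - etaL)^2 / vL - 1 + log(vL / varL))
    Fv <- acc - klt - kll
    if (!is.finite(Fv)) stop("non-finite free energy", call. = FALSE)
    list(mu = mu, lambda = lambda, J = J, r = r, Sigma = Sg, P = Pp,
         F = Fv, kl_theta = klt)
  }

  cur <- eval_point(mu0, etaL)
  if (is.null(cur)) stop("prior-point evaluation failed (singular precision)", call. = FALSE)
  f_trace <- cur$F
  nu <- s$damping_init
  n_small <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < s$max_iterations) {
    iter <- iter + 1L
    grad <- exp(cur$lambda) * crossprod(cur$J, cur$r) - P0 %*% (cur$mu - mu0)
    H <- cur$P
    step <- tryCatch(
      solve(H + nu * diag(diag(H)), grad),
      error = function(e) NULL
    )
    cand <- if (is.null(step)) NULL else eval_point(cur$mu + as.numeric(step), cur$lambda)
    if (!is.null(cand) && cand$F >= cur$F) {
      dF <- cand$F - cur$F
      cur <- cand
      f_trace <- c(f_trace, cur$F)
      nu <- max(nu / 2, 1e-8)
      n_small <- if (dF < s$tol_nats) n_small + 1L else 0L
      if (n_small >= s$consecutive) { converged <- TRUE; break }
    } else {
      nu <- nu * 2
      if (nu > s$damping_max) break
    }
  }
  if (!converged) {
    warning("variational Laplace did not converge within the iteration cap")
  }
  complexity <- cur$kl_theta
  post <- structure(
    list(mean = as.numeric(cur$mu), covariance = (cur$Sigma + t(cur$Sigma)) / 2,
         free_energy = cur$F, accuracy = cur$F + complexity,
         complexity = complexity, n_iterations = iter, converged = converged,
         f_trace = f_trace, lambda = cur$lambda, scale = scale,
         priors = priors, n_regions = p,
         data = list(observed = observed, input_power = input_power,
                     settings = s, feature_weights = feature_weights)),
    class = "dcm_posterior"
  )
  post
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("<dcm_posterior> %d regions, %d parameters | F = %.2f nats (accuracy %.2f - complexity %.2f) | %s in %d iterations\n",
              x$n_regions, length(x$mean), x$free_energy, x$accuracy,
              x$complexity, if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Accuracy/complexity split of the free energy
#'
#' Complexity is the Gaussian KL divergence of the posterior from the
#' prior (closed form); accuracy is `free_energy + complexity`, so the
#' identity `free_energy = accuracy - complexity` holds by construction.
#'
#' @param posterior A `dcm_posterior`.
#' @param priors A [dcm_priors()]; defaults to the priors stored on the
#'   posterior.
#' @return Named list `accuracy`, `complexity` (nats).
#' @export
free_energy_decomposition <- function(posterior, priors = posterior$priors) {
  stopifnot(inherits(posterior, "dcm_posterior"))
  complexity <- gaussian_kl_core(posterior$mean, posterior$covariance,
                                 priors$mean, priors$covariance)
  list(accuracy = posterior$free_energy + complexity, complexity = complexity)
}

#' Split-half calibration of the feature sampling noise
#'
#' The cross-spectral features handed to the inversion are smooth
#' parametric estimates whose sampling error varies over orders of
#' magnitude across the grid, so an unweighted Gaussian error model
#' either drowns the reliable frequencies or lets the unreliable ones
#' (the deep spectral valley under the haemodynamic rolloff) be chased
#' with spurious parameter displacements. This measures the actual
#' sampling noise by computing MAR spectra on the two halves of the
#' record: the per-frequency spread of their difference, halved, is an
#' estimate of the full-record feature noise SD at that frequency
#' (smoothed across neighbouring frequencies on the log scale).
#'
#' @param ts A [region_timeseries()].
#' @param order MAR order.
#' @param grid A [frequency_grid()].
#' @return List with `freq_sd` (noise SD per grid frequency, data units)
#'   and `log_precision` (residual log precision of the weighted
#'   features, close to zero by construction), or `NULL` when the record
#'   is too short to split.
#' @export
calibrate_feature_noise <- function(ts, order = 8, grid = NULL) {
  stopifnot(inherits(ts, "region_timeseries"))
  n <- nrow(ts$values)
  p <- ncol(ts$values)
  if (is.null(grid)) {
    grid <- frequency_grid(ts$tr_s, n * ts$tr_s)
  }
  half <- n %/% 2
  if (half <= order * p + 1) return(NULL)
  halves <- list(ts$values[seq_len(half), , drop = FALSE],
                 ts$values[half + seq_len(half), , drop = FALSE])
  feats <- vapply(halves, function(Y) {
    stack_csd(mar_to_csd(fit_mar(Y, order = order, tr_s = ts$tr_s), grid))
  }, numeric(length(grid$frequencies) * p^2))
  blk <- p^2
  noise <- matrix((feats[, 1] - feats[, 2]) / 2, blk)
  sd_k <- apply(noise, 2, function(v) sqrt(mean(v^2)))
  # geometric running mean over +/- 2 neighbouring frequencies
  ls <- log(pmax(sd_k, 1e-12))
  sm <- vapply(seq_along(ls), function(k) {
    mean(ls[max(1, k - 2):min(length(ls), k + 2)])
  }, numeric(1))
  freq_sd <- exp(sm)
  v <- stats::var(as.numeric(noise) / rep(freq_sd, each = blk))
  # the stacked features are a deterministic function of far fewer MAR
  # estimates (order*p^2 coefficients + p(p+1)/2 innovation terms), so an
  # i.i.d. error model over all grid points overcounts the information in
  # the data; discount the residual precision by the overcounting ratio
  n_feat <- length(grid$frequencies) * blk
  d_mar <- order * p^2 + p * (p + 1) / 2
  kappa <- max(n_feat / d_mar, 1)
  list(freq_sd = freq_sd,
       log_precision = min(max(-log(v) - log(kappa), -6), 4))
}

#' Fit one subject's spectral DCM from its timeseries
#'
#' Convenience wrapper: spectral features via [csd_features()], then
#' [variational_laplace()] under shrinkage priors. For task runs, pass the
#' input vector so its deterministic power enters the forward model and
#' the driving weights are informed.
#'
#' @param ts A [region_timeseries()].
#' @param schedule Optional input vector sampled at the TR (`NULL` for
#'   rest).
#' @param priors Optional [dcm_priors()].
#' @param order MAR order.
#' @param grid Optional [frequency_grid()].
#' @param settings Inversion settings (see [variational_laplace()]).
#' @return A `dcm_posterior`.
#' @export
fit_subject_dcm <- function(ts, schedule = NULL, priors = NULL, order = 8,
                            grid = NULL, settings = list()) {
  stopifnot(inherits(ts, "region_timeseries"))
  p <- ncol(ts$values)
  if (is.null(priors)) priors <- dcm_priors(p)
  cs <- csd_features(ts, order = order, grid = grid)
  upow <- if (is.null(schedule) || all(schedule == 0)) NULL else {
    schedule_power(schedule, cs$grid$frequencies, ts$tr_s)
  }
  cal <- calibrate_feature_noise(ts, order = order, grid = cs$grid)
  fw <- NULL
  if (!is.null(cal)) {
    fw <- cal$freq_sd
    if (is.null(settings$hyper_prior_mean)) {
      settings$hyper_prior_mean <- cal$log_precision
    }
  }
  variational_laplace(cs, priors, settings = settings, input_power = upow,
                      feature_weights = fw)
}
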