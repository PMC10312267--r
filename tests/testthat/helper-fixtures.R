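# Shared fixtures and independent oracles for the test suite.

# small stable three-region graph with directed coupling in the
# 0.2-0.4 Hz range
toy_graph3 <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 0.3
  A[2, 1] <- -0.2
  A[2, 3] <- 0.4
  A[3, 1] <- 0.25
  connectivity_graph(A, numeric(3))
}

toy_grid <- function(n = 16, tr_s = 0.72) {
  frequency_grid(tr_s, 207, n = n)
}

# Gaussian density, manual (no extra packages)
dmvn <- function(x, m, S) {
  d <- length(m)
  Si <- solve(S)
  dx <- x - m
  exp(-0.5 * sum(dx * (Si %*% dx))) / sqrt((2 * pi)^d * det(S))
}

# Brute-force KL(q || p) for 1-D/2-D Gaussians by Simpson quadrature on a
# wide box around q; independent of the closed form under test.
kl_quadrature <- function(mq, Sq, mp, Sp, n_nodes = 401, width = 9) {
  d <- length(mq)
  simpson_weights <- function(n) {
    w <- rep(c(4, 2), length.out = n - 2)
    c(1, w, if (n %% 2 == 1) 1 else stop("need odd n")) / 3
  }
  sdq <- sqrt(diag(as.matrix(Sq)))
  if (d == 1) {
    x <- seq(mq - width * sdq, mq + width * sdq, length.out = n_nodes)
    hx <- x[2] - x[1]
    q <- vapply(x, function(v) dmvn(v, mq, as.matrix(Sq)), numeric(1))
    p <- vapply(x, function(v) dmvn(v, mp, as.matrix(Sp)), numeric(1))
    ok <- q > 1e-300
    sum((q * log(q / p))[ok] * simpson_weights(n_nodes)[ok]) * hx
  } else if (d == 2) {
    x1 <- seq(mq[1] - width * sdq[1], mq[1] + width * sdq[1], length.out = n_nodes)
    x2 <- seq(mq[2] - width * sdq[2], mq[2] + width * sdq[2], length.out = n_nodes)
    h1 <- x1[2] - x1[1]; h2 <- x2[2] - x2[1]
    w <- simpson_weights(n_nodes)
    Sqi <- solve(Sq); Spi <- solve(Sp)
    cq <- 1 / sqrt((2 * pi)^2 * det(as.matrix(Sq)))
    cp <- 1 / sqrt((2 * pi)^2 * det(as.matrix(Sp)))
    total <- 0
    for (i in seq_len(n_nodes)) {
      dx1 <- x1[i] - mq[1]; dp1 <- x1[i] - mp[1]
      dx2 <- x2 - mq[2]; dp2 <- x2 - mp[2]
      qq <- cq * exp(-0.5 * (Sqi[1, 1] * dx1^2 + 2 * Sqi[1, 2] * dx1 * dx2 +
                               Sqi[2, 2] * dx2^2))
      pp <- cp * exp(-0.5 * (Spi[1, 1] * dp1^2 + 2 * Spi[1, 2] * dp1 * dp2 +
                               Spi[2, 2] * dp2^2))
      ok <- qq > 1e-300
      total <- total + w[i] * sum((qq * log(qq / pp) * w)[ok]) * h1 * h2
    }
    total
  } else stop("only 1-D/2-D supported")
}

# random SPD matrix with eigenvalues bounded away from zero
random_spd <- function(d, scale = 1) {
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  Q %*% diag(runif(d, 0.3, 2) * scale, d) %*% t(Q)
}

# direct conjugate-Gaussian evidence for a single scalar observation
# y ~ N(theta, s2), theta ~ N(m0, v0)
gauss_evidence_1d <- function(y, s2, m0, v0) {
  dnorm(y, m0, sqrt(s2 + v0), log = TRUE)
}

# synthetic subject posteriors without running inversions: identical
# priors, controlled means/covariances
fake_posterior <- function(mean_vec, cov, priors, p) {
  structure(
    list(mean = mean_vec, covariance = cov, free_energy = -10,
         accuracy = -8, complexity = 2, n_iterations = 1L, converged = TRUE,
         f_trace = -10, lambda = 6, scale = 1, priors = priors,
         n_regions = p, data = NULL),
    class = "dcm_posterior"
  )
}

fake_group <- function(n, p = 3, mean_fn = function(s) NULL, post_var = 1e-3,
                       seed = 1) {
  set.seed(seed)
  priors <- dcm_priors(p)
  lay <- dcm_par_layout(p)
  lapply(seq_len(n), function(s) {
    m <- mean_fn(s)
    if (is.null(m)) m <- priors$mean
    fake_posterior(m, diag(post_var, lay$n), priors, p)
  })
}

# quick synthetic posterior: fit a tiny DCM to model-generated features
quick_posterior <- function(p = 2, seed = 1, jitter = 0.1, n_freq = 12) {
  set.seed(seed)
  priors <- dcm_priors(p)
  lay <- dcm_par_layout(p)
  theta <- priors$mean
  theta[lay$A] <- rnorm(length(lay$A), 0, jitter)
  grid <- frequency_grid(0.72, 207, n = n_freq)
  obs <- predict_csd(theta, grid, p = p)
  suppressWarnings(variational_laplace(obs, priors))
}
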