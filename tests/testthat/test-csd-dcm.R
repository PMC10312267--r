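test_that("parameter vectorisation round-trips in the documented order", {
  g <- toy_graph3()
  g$driving_weights <- c(0, 0, 0.3)
  params <- dcm_parameters(g, 0.1, -0.2, 0.3, 0.05)
  theta <- vectorize_parameters(params)
  lay <- dcm_par_layout(3)
  expect_equal(lay$n, 3 * 2 + 3 + 3 + 4)
  # row-major off-diagonals: (1,2) (1,3) (2,1) (2,3) (3,1) (3,2)
  expect_equal(theta[lay$A], c(0.3, 0, -0.2, 0.4, 0.25, 0))
  expect_equal(theta[lay$C], c(0, 0, 0.3))
  expect_equal(theta[lay$spectral], c(0.1, -0.2, 0.3, 0.05))
  back <- parameters_from_vector(theta, 3)
  expect_equal(back$graph$off_diagonal, g$off_diagonal)
  expect_equal(back$spectral, params$spectral)
})

test_that("shrinkage priors carry the documented variances", {
  pr <- dcm_priors(5)
  lay <- dcm_par_layout(5)
  v <- diag(pr$covariance)
  expect_equal(unique(v[lay$A]), 1 / 64)
  expect_equal(unique(v[lay$self]), 1 / 256)
  expect_equal(unique(v[lay$spectral]), 1 / 64)
  expect_equal(pr$mean, numeric(lay$n))
})

test_that("the predicted spectrum matches a closed-form scalar oracle", {
  # single free region cannot exist (>= 2 regions); use a 2-region graph
  # with zero cross-coupling so each diagonal entry is exactly the scalar
  # formula |h|^2 * a_v f^-b / ((2 pi f)^2 + a^2) + a_e f^-b_e
  s <- c(0.2, -0.3)
  g <- connectivity_graph(matrix(0, 2, 2), s)
  params <- dcm_parameters(g, 0.15, -0.1, 0.2, 0.1)
  f <- c(0.01, 0.03, 0.08, 0.15, 0.25)
  grid <- new_frequency_grid(f, 0.72)
  pred <- predict_csd(params, grid)
  h2 <- Mod(hrf_transfer(f))^2
  for (i in 1:2) {
    a <- 0.5 * exp(s[i])
    gv <- 1 * exp(0.15) * f^(-1 * exp(-0.1))
    ge <- 4 * exp(0.2) * f^(-0.5 * exp(0.1))
    oracle <- h2 * gv / ((2 * pi * f)^2 + a^2) + ge
    expect_equal(Re(pred$matrices[cbind(1:5, i, i)]), oracle,
                 tolerance = 1e-10)
    expect_equal(Im(pred$matrices[cbind(1:5, i, i)]), numeric(5),
                 tolerance = 1e-12)
  }
})

test_that("silencing the neural path leaves only observation noise", {
  g <- connectivity_graph(matrix(0, 2, 2), numeric(2))
  params <- dcm_parameters(g, neural_log_amplitude = -40)
  grid <- toy_grid(8)
  pred <- predict_csd(params, grid)
  ge <- 4 * grid$frequencies^(-0.5)
  for (k in seq_len(8)) {
    expect_equal(pred$matrices[k, , ], diag(ge[k], 2) + 0i, tolerance = 1e-10)
  }
})

test_that("predictions are Hermitian with nonnegative real diagonals", {
  set.seed(5)
  for (rep in 1:5) {
    lay <- dcm_par_layout(3)
    theta <- rnorm(lay$n, 0, 0.15)
    grid <- toy_grid(10)
    pred <- predict_csd(theta, grid, p = 3)
    for (k in c(1, 5, 10)) {
      M <- pred$matrices[k, , ]
      expect_equal(M, Conj(t(M)), tolerance = 1e-12)
      expect_true(all(Re(diag(M)) >= 0))
    }
  }
})

test_that("the finite-difference Jacobian agrees with an independent routine", {
  skip_if_not_installed("pracma")
  set.seed(6)
  p <- 2
  lay <- dcm_par_layout(p)
  theta <- rnorm(lay$n, 0, 0.1)
  grid <- toy_grid(6)
  freq <- grid$frequencies
  h <- hrf_transfer(freq)
  b <- bdcfmri:::dcm_spectral_bases()
  fwd <- function(th) {
    bdcfmri:::csd_predict_stack_cpp(th, p, freq, h, numeric(6),
                                    b["av0"], b["bv0"], b["ae0"], b["be0"])
  }
  J <- bdcfmri:::csd_jacobian_cpp(theta, p, freq, h, numeric(6),
                                  b["av0"], b["bv0"], b["ae0"], b["be0"], 1e-4)
  J_ref <- pracma::jacobian(fwd, theta)
  expect_lt(max(abs(J - J_ref)) / max(abs(J_ref)), 1e-5)
})

test_that("inversion of prior-mean data stays at the prior mean", {
  priors <- dcm_priors(2)
  grid <- toy_grid(12)
  obs <- predict_csd(priors$mean, grid, p = 2)
  post <- suppressWarnings(variational_laplace(obs, priors))
  lay <- dcm_par_layout(2)
  expect_true(all(abs(post$mean[lay$A] - priors$mean[lay$A]) < 0.02))
  expect_true(all(diff(post$f_trace) >= -1e-9))
})

test_that("accepted-step free energy is non-decreasing on real fits", {
  post <- quick_posterior(p = 2, seed = 7, jitter = 0.15)
  expect_true(all(diff(post$f_trace) >= -1e-9))
  expect_true(post$free_energy > -Inf)
  expect_true(isSymmetric(post$covariance))
  expect_gt(min(eigen(post$covariance, only.values = TRUE)$values), 0)
})

test_that("known coupling is recovered from ten minutes of data", {
  g <- toy_graph3()
  lay <- dcm_par_layout(3)
  truth <- vectorize_parameters(dcm_parameters(g))
  cors <- vapply(1:4, function(s) {
    cfg <- sim_config(n_regions = 3, n_subjects = 1, duration_s = 600,
                      seed = s)
    ts1 <- simulate_bold(g, NULL, cfg, seed = 1000 + s)
    post <- suppressWarnings(fit_subject_dcm(ts1))
    cor(truth[lay$A], post$mean[lay$A])
  }, numeric(1))
  expect_gte(mean(cors), 0.7)
})

test_that("free energy decomposes into accuracy minus complexity", {
  post <- quick_posterior(p = 2, seed = 8, jitter = 0.1)
  dec <- free_energy_decomposition(post)
  expect_gte(dec$complexity, 0)
  expect_equal(post$free_energy, dec$accuracy - dec$complexity,
               tolerance = 1e-9)
  expect_equal(dec$complexity, post$complexity, tolerance = 1e-6)

  # posterior equal to the prior has zero complexity
  pr <- dcm_priors(2)
  fake <- post
  fake$mean <- pr$mean
  fake$covariance <- pr$covariance
  expect_equal(free_energy_decomposition(fake, pr)$complexity, 0,
               tolerance = 1e-10)
})

test_that("data without connectivity do not induce coupling estimates", {
  # pure noise: endogenous fluctuations and observation noise, but zero
  # between-region coupling; the shrinkage prior should keep nearly all
  # coupling estimates within one prior SD of zero
  g0 <- connectivity_graph(matrix(0, 3, 3), numeric(3))
  lay <- dcm_par_layout(3)
  prior_sd <- sqrt(1 / 64)
  fracs <- vapply(1:3, function(s) {
    cfg <- sim_config(n_regions = 3, n_subjects = 1, duration_s = 1200,
                      seed = s)
    ts1 <- simulate_bold(g0, NULL, cfg, seed = 40 + s)
    post <- suppressWarnings(fit_subject_dcm(ts1))
    mean(abs(post$mean[lay$A]) < prior_sd)
  }, numeric(1))
  expect_gte(mean(fracs), 0.9)
})

test_that("relabelling regions permutes the posterior consistently", {
  g <- toy_graph3()
  cfg <- sim_config(n_regions = 3, n_subjects = 1, duration_s = 300)
  ts1 <- simulate_bold(g, NULL, cfg, seed = 10)
  perm <- c(2, 3, 1)
  post <- suppressWarnings(fit_subject_dcm(ts1))
  post_p <- suppressWarnings(fit_subject_dcm(
    region_timeseries(ts1$values[, perm], ts1$tr_s)))
  # compare coupling matrices entry-wise under the relabelling
  to_A <- function(mu) {
    pr <- parameters_from_vector(mu, 3)
    effective_coupling(pr$graph)
  }
  A1 <- to_A(post$mean)
  A2 <- to_A(post_p$mean)
  # iterative optimisation stops within tol_nats of the optimum, so allow
  # a correspondingly small numerical discrepancy
  expect_lt(max(abs(A2 - A1[perm, perm])), 0.02)
})
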