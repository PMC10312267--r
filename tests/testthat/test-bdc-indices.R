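test_that("parameter certainty follows the negative-entropy closed form", {
  # unit determinant of 2 pi e Sigma gives exactly zero nats
  expect_equal(parameter_certainty(matrix(1 / (2 * pi * exp(1)))), 0,
               tolerance = 1e-12)

  # diagonal covariances factorise into per-parameter contributions
  v <- c(0.5, 0.02, 1.3)
  expect_equal(parameter_certainty(diag(v)),
               sum(vapply(v, function(x) parameter_certainty(matrix(x)),
                          numeric(1))),
               tolerance = 1e-10)

  # invariance under orthogonal rotation
  set.seed(10)
  for (rep in 1:5) {
    S <- random_spd(5)
    Q <- qr.Q(qr(matrix(rnorm(25), 5)))
    expect_equal(parameter_certainty(Q %*% S %*% t(Q)),
                 parameter_certainty(S), tolerance = 1e-9)
  }

  expect_error(parameter_certainty(diag(c(1, -0.5))), "positive definite")
})

test_that("Gaussian information gain matches quadrature and closed forms", {
  # identical beliefs carry no information gain
  b <- gaussian_belief(c(0, 1), diag(2))
  expect_equal(information_gain_parameters(b, b), 0, tolerance = 1e-12)

  # unit-variance mean shift of 1 gives exactly half a nat
  expect_equal(information_gain_parameters(gaussian_belief(0, matrix(1)),
                                           gaussian_belief(1, matrix(1))),
               0.5, tolerance = 1e-12)

  # brute-force quadrature oracle on random 1-D and 2-D pairs
  set.seed(11)
  for (rep in 1:10) {
    mq <- rnorm(1); mp <- rnorm(1)
    Sq <- matrix(runif(1, 0.3, 2)); Sp <- matrix(runif(1, 0.3, 2))
    kl <- information_gain_parameters(gaussian_belief(mp, Sp),
                                      gaussian_belief(mq, Sq))
    expect_equal(kl, kl_quadrature(mq, Sq, mp, Sp), tolerance = 1e-6)
  }
  for (rep in 1:10) {
    mq <- rnorm(2, 0, 0.5); mp <- rnorm(2, 0, 0.5)
    Sq <- random_spd(2); Sp <- random_spd(2)
    kl <- information_gain_parameters(gaussian_belief(mp, Sp),
                                      gaussian_belief(mq, Sq))
    expect_equal(kl, kl_quadrature(mq, Sq, mp, Sp), tolerance = 1e-6)
  }

  expect_error(information_gain_parameters(gaussian_belief(0, matrix(1)), b),
               "dimensions")
})

test_that("KL properties hold on randomised beliefs", {
  set.seed(12)
  for (rep in 1:20) {
    d <- sample(2:5, 1)
    q <- gaussian_belief(rnorm(d), random_spd(d))
    p <- gaussian_belief(rnorm(d), random_spd(d))
    expect_gte(information_gain_parameters(p, q), 0)
    expect_equal(information_gain_parameters(q, q), 0, tolerance = 1e-10)
  }
  # shrinking the posterior covariance with fixed displaced mean strictly
  # increases both certainty and information gain (posterior tighter than
  # prior, the regime a fitted model lives in)
  q <- gaussian_belief(c(0.4, -0.2, 0.1), random_spd(3, scale = 1 / 300))
  p <- gaussian_belief(numeric(3), diag(3) / 64)
  for (c_shrink in c(0.8, 0.5, 0.2)) {
    q2 <- gaussian_belief(q$mean, c_shrink * q$covariance)
    expect_gt(parameter_certainty(q2$covariance),
              parameter_certainty(q$covariance))
    expect_gt(information_gain_parameters(p, q2),
              information_gain_parameters(p, q))
  }
})

test_that("model spaces enumerate leave-one-out reductions", {
  sp5 <- build_model_space(5)
  expect_length(sp5$masks, 21)  # 1 full + 20 single-connection drops
  expect_equal(sp5$prior_model_probabilities, rep(1 / 21, 21))
  expect_equal(sum(sp5$prior_model_probabilities), 1)
  expect_true(all(vapply(sp5$masks, function(m) all(diag(m) == 1), logical(1))))

  sp2 <- build_model_space(2)
  expect_length(sp2$masks, 3)

  custom <- list(matrix(c(1, 0, 1, 1), 2, 2))
  spc <- build_model_space(2, scheme = "custom", custom_masks = custom)
  expect_length(spc$masks, 2)  # full model added automatically
  bad <- list(matrix(c(0, 1, 1, 1), 2, 2))
  expect_error(build_model_space(2, "custom", custom_masks = bad),
               "self-connections")
  expect_error(build_model_space(2, "custom", custom_masks = c(custom, custom)),
               "duplicate")
})

test_that("Bayesian model reduction is exact for conjugate Gaussians", {
  # no reduction: evidence unchanged and posterior intact
  set.seed(13)
  post <- gaussian_belief(c(0.5, -0.2), random_spd(2, 0.1))
  prior <- gaussian_belief(c(0, 0), diag(2) / 4)
  same <- bayesian_model_reduction(post, prior, prior)
  expect_equal(same$delta_evidence, 0, tolerance = 1e-9)
  expect_equal(same$posterior$mean, post$mean, tolerance = 1e-9)
  expect_equal(same$posterior$covariance, post$covariance, tolerance = 1e-9)

  # 1-D conjugate oracle: y ~ N(theta, s2), theta ~ N(m0, v0)
  for (rep in 1:8) {
    y <- rnorm(1); s2 <- runif(1, 0.2, 2)
    m0 <- rnorm(1, 0, 0.5); v0 <- runif(1, 0.3, 2)
    mr <- rnorm(1, 0, 0.5); vr <- runif(1, 0.05, 2)
    post_prec <- 1 / v0 + 1 / s2
    post_mean <- (m0 / v0 + y / s2) / post_prec
    red <- bayesian_model_reduction(
      gaussian_belief(post_mean, matrix(1 / post_prec)),
      gaussian_belief(m0, matrix(v0)),
      gaussian_belief(mr, matrix(vr)))
    direct <- gauss_evidence_1d(y, s2, mr, vr) - gauss_evidence_1d(y, s2, m0, v0)
    expect_equal(red$delta_evidence, direct, tolerance = 1e-8)
  }

  # switching off a strongly supported connection costs more evidence
  prior1 <- gaussian_belief(0, matrix(1 / 64))
  off <- gaussian_belief(0, matrix(1e-6))
  post_far <- gaussian_belief(5 * 0.02, matrix(0.02^2))   # 5 SD from zero
  post_ctr <- gaussian_belief(0, matrix(0.02^2))
  expect_lt(bayesian_model_reduction(post_far, prior1, off)$delta_evidence,
            bayesian_model_reduction(post_ctr, prior1, off)$delta_evidence)
})

test_that("information gain over models spans [0, ln M]", {
  # uniform evidences: posterior equals the prior, zero gain
  expect_equal(bdcfmri:::discrete_kl_uniform(rep(1 / 21, 21)), 0,
               tolerance = 1e-12)
  # a 30-nat dominant model saturates at ln M
  logev <- c(30, rep(0, 20))
  prob <- bdcfmri:::softmax(logev)
  expect_equal(bdcfmri:::discrete_kl_uniform(prob), log(21), tolerance = 1e-6)
  # random evidence vector against a direct formula evaluation
  set.seed(14)
  logev <- rnorm(21, 0, 2)
  prob <- bdcfmri:::softmax(logev)
  direct <- sum(prob * log(prob * 21))
  expect_equal(bdcfmri:::discrete_kl_uniform(prob), direct, tolerance = 1e-9)
  expect_true(all(prob > 0) && abs(sum(prob) - 1) < 1e-12)
})

test_that("model gain from a PEB belief is bounded and sane", {
  p <- 3
  lay <- dcm_par_layout(p)
  posts <- lapply(1:4, function(s) {
    priors <- dcm_priors(p)
    m <- priors$mean
    m[lay$A] <- c(0.3, 0, -0.2, 0.25, 0.1, 0)
    structure(list(mean = m, covariance = diag(1e-3, lay$n),
                   free_energy = -5, priors = priors, n_regions = p,
                   converged = TRUE),
              class = "dcm_posterior")
  })
  peb <- fit_peb(posts)
  space <- build_model_space(p)
  ig <- information_gain_models(peb, space)
  expect_gte(ig$info_gain, 0)
  expect_lte(ig$info_gain, log(length(space$masks)))
  expect_equal(sum(ig$posterior_probabilities), 1, tolerance = 1e-12)
  # the full model must not be dominated by a reduction that removes a
  # strongly supported connection
  drop1 <- which(space$names == "drop_1<-2")
  expect_gt(ig$log_evidence[1], ig$log_evidence[drop1])
})

test_that("evidence labels follow the nats thresholds", {
  expect_equal(label_evidence(0.23), "insufficient")
  expect_equal(label_evidence(1.1), "positive")
  expect_equal(label_evidence(4), "strong")
  expect_equal(label_evidence(5), "very strong")
  expect_equal(label_evidence(10.5), "very strong")
  expect_equal(label_evidence(c(0, 2.9, 3)),
               c("insufficient", "positive", "strong"))
  expect_error(label_evidence(-0.1), ">= 0")
})

test_that("self-comparison yields zero differences everywhere", {
  p <- 3
  posts <- fake_group(5, p, mean_fn = function(s) {
    m <- numeric(dcm_par_layout(p)$n)
    m[1] <- 0.2 + 0.01 * s
    m
  }, post_var = 1e-3)
  peb <- fit_peb(posts)
  rep_self <- compare_datasets(peb, peb, labels = c("a", "a_copy"))
  expect_equal(rep_self$differences$difference_nats, numeric(3),
               tolerance = 1e-9)
  expect_true(all(rep_self$differences$evidence == "insufficient"))
  expect_true(all(rep_self$differences$difference_nats >= 0))
})

test_that("comparison is invariant to dataset order", {
  p <- 3
  mk <- function(shift, seed) fit_peb(fake_group(5, p, mean_fn = function(s) {
    m <- numeric(dcm_par_layout(p)$n)
    m[1:3] <- shift
    m
  }, post_var = 2e-3, seed = seed))
  peb_a <- mk(0.25, 1)
  peb_b <- mk(0.05, 2)
  r1 <- compare_datasets(peb_a, peb_b, labels = c("A", "B"))
  r2 <- compare_datasets(peb_b, peb_a, labels = c("B", "A"))
  m1 <- r1$differences[order(r1$differences$index), ]
  m2 <- r2$differences[order(r2$differences$index), ]
  expect_equal(m1$difference_nats, m2$difference_nats, tolerance = 1e-9)
  expect_equal(m1$best_dataset, m2$best_dataset)
})
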