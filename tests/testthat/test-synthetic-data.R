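test_that("group sampling is exact at zero spread and unbiased otherwise", {
  tpl <- default_connectivity_template()
  same <- sample_group_parameters(tpl, 3, between_subject_sd = 0, seed = 1)
  for (g in same) expect_equal(g$off_diagonal, tpl$off_diagonal)

  # Monte-Carlo check of the generative law: elementwise mean of sampled
  # off-diagonals within 3 standard errors of the template
  n <- 2000
  draws <- sample_group_parameters(tpl, n, between_subject_sd = 0.1, seed = 2)
  m <- Reduce(`+`, lapply(draws, function(g) g$off_diagonal)) / n
  se <- 0.1 / sqrt(n)
  off <- !diag(5)
  expect_true(all(abs(m[off] - tpl$off_diagonal[off]) < 3 * se + 1e-12))

  # enforced stability postcondition
  for (g in draws[1:50]) {
    expect_lt(max(Re(eigen(effective_coupling(g))$values)), 0)
  }

  expect_error(sample_group_parameters(tpl, 2, -0.1), ">= 0")
})

test_that("group sampling repairs unstable draws deterministically", {
  # near-critical template: large spread forces redraw/repair paths
  tpl <- default_connectivity_template()
  gs <- suppressMessages(sample_group_parameters(tpl, 20,
                                                 between_subject_sd = 0.5,
                                                 seed = 3))
  for (g in gs) expect_lt(max(Re(eigen(effective_coupling(g))$values)), 0)
  gs2 <- suppressMessages(sample_group_parameters(tpl, 20,
                                                  between_subject_sd = 0.5,
                                                  seed = 3))
  expect_identical(gs, gs2)
})

test_that("block schedule matches the stated design", {
  cfg <- sim_config(n_subjects = 1)
  u <- make_block_schedule(cfg)
  t <- (seq_along(u) - 1) * cfg$tr_s
  expect_equal(length(u), floor(cfg$duration_s / cfg$tr_s))
  # countdown: all samples before 8 s are off
  expect_true(all(u[t < 8] == 0))
  # five 20-s stimulus blocks, within one TR of the scheduled total
  expect_lt(abs(sum(u) * cfg$tr_s - cfg$n_blocks * cfg$block_s), cfg$tr_s)

  u0 <- make_block_schedule(sim_config(n_subjects = 1, n_blocks = 0))
  expect_true(all(u0 == 0))
  expect_error(sim_config(tr_s = 0), "tr_s")
  expect_error(sim_config(block_s = -1), "durations")
})

test_that("simulated BOLD is silent without excitation and deterministic", {
  g <- toy_graph3()
  cfg <- sim_config(n_regions = 3, n_subjects = 1, duration_s = 60,
                    neural_noise_amplitude = 0, observation_noise_amplitude = 0)
  ts0 <- simulate_bold(g, NULL, cfg, seed = 1)
  expect_true(all(ts0$values == 0))

  cfg2 <- sim_config(n_regions = 3, n_subjects = 1, duration_s = 60)
  a <- simulate_bold(g, NULL, cfg2, seed = 7)
  b <- simulate_bold(g, NULL, cfg2, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, simulate_bold(g, NULL, cfg2, seed = 8)$values))
})

test_that("neural fluctuations carry the configured spectral slope", {
  # single self-coupled region, long record; the neural input is 1/f^1.2
  # and the slope of the output periodogram in the pass-band of the
  # dynamics reflects it after removing the known transfer
  n <- 2^14
  dt <- 0.5
  set.seed(42)
  x <- powerlaw_noise(n, dt, amplitude = 1, exponent = 1.2)
  sp <- stats::spec.pgram(stats::ts(x, deltat = dt), plot = FALSE,
                          taper = 0, spans = 15)
  keep <- sp$freq > 0.002 & sp$freq < 0.8
  slope <- stats::coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2]
  expect_lt(abs(slope - (-1.2)), 0.2)
})

test_that("decoupled regions remain uncorrelated at the neural level", {
  # long-memory 1/f drive inflates the finite-sample variance of the
  # correlation between independent series, so probe independence with a
  # short-memory drive where 10^4 samples are genuinely informative
  g <- connectivity_graph(matrix(0, 3, 3), numeric(3))
  cfg <- sim_config(n_regions = 3, n_subjects = 1, duration_s = 7200,
                    neural_noise_exponent = 0.5,
                    observation_noise_amplitude = 0)
  ts1 <- simulate_bold(g, NULL, cfg, seed = 5)
  cc <- stats::cor(ts1$values)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.1))
})

test_that("zero-input runs are mean-free and the noise floor scales", {
  g <- toy_graph3()
  cfg <- sim_config(n_regions = 3, n_subjects = 1, duration_s = 1440)
  ts1 <- simulate_bold(g, NULL, cfg, seed = 2)
  # mean-correction is exact by construction; drift stays bounded
  expect_equal(colMeans(ts1$values), numeric(3), tolerance = 1e-10)

  # doubling the observation amplitude doubles the flat spectral floor
  floor_of <- function(amp) {
    cfgw <- sim_config(n_regions = 3, n_subjects = 1, duration_s = 1440,
                       neural_noise_amplitude = 0,
                       observation_noise_amplitude = amp,
                       observation_noise_exponent = 0)
    tsw <- simulate_bold(g, NULL, cfgw, seed = 9)
    sp <- stats::spec.pgram(stats::ts(tsw$values[, 1], deltat = cfgw$tr_s),
                            plot = FALSE, taper = 0)
    mean(sp$spec[sp$freq > 0.3])
  }
  r <- floor_of(2) / floor_of(1)
  expect_lt(abs(r - 2), 0.2)
})

test_that("the comparison pair mirrors the paired-acquisition design", {
  cfg <- sim_config(n_subjects = 4, seed = 11)
  pair <- generate_comparison_pair(cfg)
  expect_equal(length(pair$rest$subjects), 4)
  expect_equal(length(pair$task$subjects), 4)
  expect_equal(nrow(pair$rest$subjects[[1]]$values), 287)  # floor(207/0.72)
  expect_equal(nrow(pair$task$subjects[[1]]$values), 287)
  expect_true(all(pair$rest$schedule == 0))
  expect_gt(sum(pair$task$schedule), 0)
  # ground truth retained, scaled 2x between conditions, same deviations
  d_rest <- pair$rest$truth[[2]]$off_diagonal - pair$rest$template$off_diagonal
  d_task <- pair$task$truth[[2]]$off_diagonal - pair$task$template$off_diagonal
  expect_equal(d_rest, d_task, tolerance = 1e-12)
  expect_equal(pair$task$template$off_diagonal,
               2 * pair$rest$template$off_diagonal)

  # bitwise determinism of the whole dataset
  pair2 <- generate_comparison_pair(cfg)
  expect_identical(pair, pair2)
})

test_that("identical generative settings produce exchangeable conditions", {
  tpl <- default_connectivity_template(driving_weight = 0)
  cfg <- sim_config(n_subjects = 20, coupling_scale_task = 1, seed = 21)
  pair <- generate_comparison_pair(cfg, template = tpl)
  v_rest <- vapply(pair$rest$subjects, function(s) mean(apply(s$values, 2, var)),
                   numeric(1))
  v_task <- vapply(pair$task$subjects, function(s) mean(apply(s$values, 2, var)),
                   numeric(1))
  expect_gt(stats::ks.test(v_rest, v_task)$p.value, 0.01)
})

test_that("group datasets round-trip through TSV + JSON", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_subjects = 2, duration_s = 30, seed = 13)
  pair <- generate_comparison_pair(cfg)
  write_group_dataset(pair$task, dir)
  back <- read_group_dataset(dir)
  expect_equal(back$condition, "task")
  expect_equal(length(back$subjects), 2)
  expect_equal(back$subjects[[1]]$values, pair$task$subjects[[1]]$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$subjects[[2]]$tr_s, 0.72)
  expect_equal(back$truth[[1]]$off_diagonal,
               pair$task$truth[[1]]$off_diagonal, tolerance = 1e-12)
  expect_equal(back$schedule, pair$task$schedule)
})
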