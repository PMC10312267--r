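#' One subject's region-level BOLD timeseries
#'
#' @param values Numeric time-by-region matrix (arbitrary BOLD units).
#' @param tr_s Sampling interval (s).
#' @param subject_id Identifier string.
#' @param condition Condition label (e.g. `"rest"`, `"task"`).
#' @return An object of class `region_timeseries`.
#' @export
region_timeseries <- function(values, tr_s, subject_id = "sub-01",
                              condition = "rest") {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 regions", call. = FALSE)
  if (any(!is.finite(values))) stop("timeseries contains missing values", call. = FALSE)
  if (tr_s <= 0) stop("tr_s must be > 0", call. = FALSE)
  structure(list(values = values, tr_s = tr_s,
                 subject_id = subject_id, condition = condition),
            class = "region_timeseries")
}

#' @export
print.region_timeseries <- function(x, ...) {
  cat(sprintf("<region_timeseries> %s [%s]: %d samples x %d regions, TR %.3g s\n",
              x$subject_id, x$condition, nrow(x$values), ncol(x$values), x$tr_s))
  invisible(x)
}

#' Power-law noise by spectral synthesis
#'
#' Draws a zero-mean stationary series whose one-sided power spectral
#' density is `amplitude * f^(-exponent)` over (0, Nyquist]: spectral
#' amplitudes are shaped in the frequency domain, phases randomised, and
#' the result inverse-transformed. The zero-frequency bin is set to 0, so
#' the series is exactly mean-free.
#'
#' @param n Number of samples.
#' @param dt Sampling interval (s).
#' @param amplitude Spectral amplitude at 1 Hz.
#' @param exponent Spectral slope (0 = white, 1 = pink).
#' @return Numeric vector of length `n`.
#' @export
powerlaw_noise <- function(n, dt, amplitude, exponent) {
  if (n == 0 || amplitude == 0) return(numeric(n))
  nh <- n %/% 2
  f <- (1:nh) / (n * dt)
  sdev <- sqrt(n * amplitude * f^(-exponent) / (2 * dt))
  X <- complex(length.out = n)
  # bins 1..nh-1 paired with conjugates; Nyquist bin (even n) real
  k <- seq_len(max(nh - 1, 0))
  if (length(k)) {
    X[k + 1] <- sdev[k] * complex(real = rnorm(length(k)),
                                  imaginary = rnorm(length(k))) / sqrt(2)
    X[n - k + 1] <- Conj(X[k + 1])
  }
  if (n %% 2 == 0 && nh >= 1) {
    X[nh + 1] <- sqrt(2) * sdev[nh] * rnorm(1)
  } else if (nh >= 1 && n > 1) {
    X[nh + 1] <- sdev[nh] * complex(real = rnorm(1), imaginary = rnorm(1)) / sqrt(2)
    X[n - nh + 1] <- Conj(X[nh + 1])
  }
  Re(fft(X, inverse = TRUE)) / n
}

# draw per-subject off-diagonal deviations (Hz); matrix list
draw_deviations <- function(n_regions, n_subjects, sd) {
  lapply(seq_len(n_subjects), function(s) {
    D <- matrix(rnorm(n_regions^2, sd = sd), n_regions, n_regions)
    diag(D) <- 0
    D
  })
}

# apply the documented stability repair: shift the diagonal (via the self
# log-scaling values) so the largest eigenvalue real part becomes -0.1 Hz
stabilise_graph <- function(graph, margin = 0.05) {
  A <- effective_coupling(graph)
  mre <- max(Re(eigen(A, only.values = TRUE)$values))
  if (mre < -margin) return(graph)
  shift <- mre + 0.1
  d_new <- diag(A) - shift
  graph$self_log_scale <- log(-d_new / 0.5)
  message(sprintf("stabilised graph: diagonal shifted by -%.3f Hz", shift))
  graph
}

#' Sample per-subject connectivity graphs around a template
#'
#' Each subject's between-region coupling is the template plus independent
#' Gaussian deviations of standard deviation `between_subject_sd` (the
#' generative analogue of the unexplained between-subject variability in
#' the hierarchical group model). Draws violating the stability margin
#' (largest eigenvalue real part of the effective coupling above -0.05 Hz)
#' are redrawn up to `max_retries` times and then repaired by shifting the
#' self-connections.
#'
#' @param template A stable `connectivity_graph`.
#' @param n_subjects Number of subjects.
#' @param between_subject_sd SD (Hz) of the coupling deviations.
#' @param seed Integer seed.
#' @param max_retries Redraw budget per subject before the diagonal repair.
#' @return List of `connectivity_graph`, one per subject.
#' @export
sample_group_parameters <- function(template, n_subjects, between_subject_sd,
                                    seed = 1L, max_retries = 10L) {
  stopifnot(inherits(template, "connectivity_graph"))
  if (between_subject_sd < 0) stop("between_subject_sd must be >= 0", call. = FALSE)
  if (!is_stable(template)) stop("template graph is unstable", call. = FALSE)
  p <- n_regions(template)
  set.seed(seed)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    g <- NULL
    for (try in seq_len(max_retries + 1L)) {
      D <- matrix(rnorm(p^2, sd = between_subject_sd), p, p)
      diag(D) <- 0
      g <- connectivity_graph(template$off_diagonal + D,
                              template$self_log_scale,
                              template$driving_weights,
                              check_stability = FALSE)
      if (is_stable(g, margin = 0.05)) break
      g <- NULL
      if (between_subject_sd == 0) break  # redrawing cannot help
    }
    if (is.null(g)) {
      D <- matrix(rnorm(p^2, sd = between_subject_sd), p, p)
      diag(D) <- 0
      g <- stabilise_graph(connectivity_graph(template$off_diagonal + D,
                                              template$self_log_scale,
                                              template$driving_weights,
                                              check_stability = FALSE))
    }
    if (!is_stable(g)) {
      stop(sprintf("could not obtain a stable graph for subject %d", s),
           call. = FALSE)
    }
    out[[s]] <- g
  }
  out
}

#' Simulate one subject's BOLD run
#'
#' Integrates the linear neural dynamics `dz/dt = A_eff z + C u + v` by
#' exact matrix-exponential discretisation on a grid of `tr_s / 8`
#' (unconditionally stable for stable coupling), with `v` a power-law
#' endogenous fluctuation process per region; convolves the neural states
#' with the canonical haemodynamic kernel; downsamples to the TR; adds
#' power-law observation noise; and mean-corrects each region.
#'
#' @param graph A stable `connectivity_graph` (its `driving_weights` route
#'   the input).
#' @param schedule Input vector u(t) sampled at `tr_s`
#'   (see [make_block_schedule()]); recycled as all-zero when `NULL`.
#' @param config A [sim_config()] supplying TR, duration and noise levels.
#' @param seed Integer seed.
#' @param subject_id,condition Labels for the output.
#' @return A [region_timeseries()].
#' @export
simulate_bold <- function(graph, schedule, config, seed = 1L,
                          subject_id = "sub-01", condition = "rest") {
  stopifnot(inherits(graph, "connectivity_graph"))
  if (!is_stable(graph)) stop("graph is unstable", call. = FALSE)
  nt <- n_samples(config)
  if (is.null(schedule)) schedule <- numeric(nt)
  if (length(schedule) != nt) {
    stop("schedule length inconsistent with config duration/TR", call. = FALSE)
  }
  p <- n_regions(graph)
  up <- 8L
  dt <- config$tr_s / up
  nf <- nt * up

  set.seed(seed)
  A <- effective_coupling(graph)
  E <- as.matrix(Matrix::expm(A * dt))
  B <- solve(A, E - diag(p))   # integrates piecewise-constant forcing

  v <- vapply(seq_len(p), function(j) {
    powerlaw_noise(nf, dt, config$neural_noise_amplitude,
                   config$neural_noise_exponent)
  }, numeric(nf))
  v <- matrix(v, nf, p)
  u_fine <- rep(schedule, each = up)
  forcing <- v + outer(u_fine, graph$driving_weights)

  z <- matrix(0, nf, p)
  state <- numeric(p)
  for (t in seq_len(nf)) {
    state <- drop(E %*% state + B %*% forcing[t, ])
    z[t, ] <- state
  }
  if (any(!is.finite(z))) stop("NaN in neural integration", call. = FALSE)

  k <- hrf_kernel(dt)
  bold_fine <- apply(z, 2, function(x) {
    y <- stats::convolve(x, rev(k), type = "open")[seq_len(nf)]
    y * dt
  })
  bold <- bold_fine[seq(1, nf, by = up), , drop = FALSE]

  e <- vapply(seq_len(p), function(j) {
    powerlaw_noise(nt, config$tr_s, config$observation_noise_amplitude,
                   config$observation_noise_exponent)
  }, numeric(nt))
  y <- bold + matrix(e, nt, p)
  y <- sweep(y, 2, colMeans(y))
  if (any(!is.finite(y))) stop("NaN in simulated BOLD", call. = FALSE)
  region_timeseries(y, config$tr_s, subject_id, condition)
}

scale_graph <- function(graph, coupling_scale, driving = TRUE) {
  connectivity_graph(graph$off_diagonal * coupling_scale,
                     graph$self_log_scale,
                     if (driving) graph$driving_weights else numeric(n_regions(graph)),
                     check_stability = FALSE)
}

#' Generate a paired rest-like / task-like group dataset
#'
#' Emulates a paired-acquisition study: the same subjects are "scanned"
#' under a resting condition (no exogenous input, template coupling scaled
#' by `coupling_scale_rest`) and a block-design task condition (boxcar
#' input driving one designated region, coupling scaled by
#' `coupling_scale_task`). Subject-specific coupling deviations are shared
#' between conditions, and the ground-truth graphs are retained for
#' recovery tests.
#'
#' @param config A [sim_config()].
#' @param template Optional template `connectivity_graph`; defaults to
#'   [default_connectivity_template()].
#' @return List with elements `rest` and `task`, each a `group_dataset`
#'   (fields `subjects`, `truth`, `condition`).
#' @export
generate_comparison_pair <- function(config, template = NULL) {
  validate_sim_config(config)
  if (is.null(template)) {
    template <- default_connectivity_template(config$n_regions,
                                              config$driving_region)
  }
  rest_template <- scale_graph(template, config$coupling_scale_rest, driving = FALSE)
  task_template <- scale_graph(template, config$coupling_scale_task, driving = TRUE)

  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L + 2L * config$n_subjects)
  rest_graphs <- sample_group_parameters(rest_template, config$n_subjects,
                                         config$between_subject_sd, seed = seeds[1])
  set.seed(seeds[1])  # reuse the same deviations for the paired condition
  task_graphs <- sample_group_parameters(task_template, config$n_subjects,
                                         config$between_subject_sd, seed = seeds[1])

  u <- make_block_schedule(config)
  ids <- sprintf("sub-%02d", seq_len(config$n_subjects))
  rest <- lapply(seq_len(config$n_subjects), function(s) {
    simulate_bold(rest_graphs[[s]], NULL, config, seed = seeds[2 + s],
                  subject_id = ids[s], condition = "rest")
  })
  task <- lapply(seq_len(config$n_subjects), function(s) {
    simulate_bold(task_graphs[[s]], u, config,
                  seed = seeds[2 + config$n_subjects + s],
                  subject_id = ids[s], condition = "task")
  })
  list(
    rest = structure(list(subjects = rest, truth = rest_graphs,
                          condition = "rest", template = rest_template,
                          schedule = numeric(n_samples(config))),
                     class = "group_dataset"),
    task = structure(list(subjects = task, truth = task_graphs,
                          condition = "task", template = task_template,
                          schedule = u),
                     class = "group_dataset")
  )
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("<group_dataset> condition '%s': %d subjects, %d samples x %d regions\n",
              x$condition, length(x$subjects),
              nrow(x$subjects[[1]]$values), ncol(x$subjects[[1]]$values)))
  invisible(x)
}

#' Write / read a group dataset as TSV + JSON
#'
#' One TSV per subject (columns = region labels, rows = samples) with a
#' JSON sidecar (subject id, condition, TR), a ground-truth JSON of
#' coupling matrices, and a manifest JSON listing the members.
#'
#' @param dataset A `group_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_group_dataset` returns `dir` invisibly;
#'   `read_group_dataset` returns a `group_dataset`.
#' @export
write_group_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "group_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  members <- character(0)
  for (ts in dataset$subjects) {
    stem <- sprintf("%s_%s", ts$subject_id, ts$condition)
    vals <- as.data.frame(ts$values)
    names(vals) <- sprintf("region%02d", seq_len(ncol(ts$values)))
    utils::write.table(vals, file.path(dir, paste0(stem, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(subject_id = ts$subject_id, condition = ts$condition, tr_s = ts$tr_s),
      file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
    members <- c(members, stem)
  }
  truth <- lapply(dataset$truth, function(g) {
    list(off_diagonal = g$off_diagonal, self_log_scale = g$self_log_scale,
         driving_weights = g$driving_weights)
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), digits = NA)
  manifest <- list(condition = dataset$condition, members = members,
                   ground_truth = "ground_truth.json",
                   schedule = dataset$schedule)
  if (!is.null(dataset$template)) {
    manifest$template <- list(
      off_diagonal = dataset$template$off_diagonal,
      self_log_scale = dataset$template$self_log_scale,
      driving_weights = dataset$template$driving_weights)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_group_dataset
#' @export
read_group_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- lapply(manifest$members, function(stem) {
    side <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                                simplifyVector = TRUE)
    vals <- as.matrix(utils::read.table(file.path(dir, paste0(stem, ".tsv")),
                                        header = TRUE, sep = "\t"))
    region_timeseries(vals, side$tr_s, side$subject_id, side$condition)
  })
  truth_raw <- jsonlite::read_json(file.path(dir, manifest$ground_truth),
                                   simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
  truth <- lapply(truth_raw, function(g) {
    connectivity_graph(as.matrix(g$off_diagonal),
                       as.numeric(g$self_log_scale),
                       as.numeric(g$driving_weights),
                       check_stability = FALSE)
  })
  template <- NULL
  if (!is.null(manifest$template)) {
    template <- connectivity_graph(as.matrix(manifest$template$off_diagonal),
                                   as.numeric(manifest$template$self_log_scale),
                                   as.numeric(manifest$template$driving_weights),
                                   check_stability = FALSE)
  }
  structure(list(subjects = subjects, truth = truth,
                 condition = manifest$condition,
                 schedule = as.numeric(manifest$schedule),
                 template = template),
            class = "group_dataset")
}
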