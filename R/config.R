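#' Simulation configuration
#'
#' Collects every knob of the synthetic rest/task generator. Defaults mirror
#' the emulated acquisition: TR 0.72 s, runs of 207 s (287 samples), five
#' regions, fifty subjects, and a block design of an 8 s countdown followed
#' by five cycles of 20 s stimulus, 3 s response and 15 s fixation. The
#' stated schedule (198 s) and the run duration (207 s) are independent
#' fields; the input vector is zero-padded to the run length.
#'
#' Noise terms are power-law processes with one-sided spectrum
#' `amplitude * f^(-exponent)`: neural fluctuations default to 1/f
#' (exponent 1), observation noise to a whiter exponent of 0.5.
#' `between_subject_sd` is the standard deviation (Hz) of Gaussian
#' between-subject deviations around the template coupling; the default
#' 0.0625 Hz equals one prior standard deviation of the shrinkage prior
#' (sqrt(1/64)). `coupling_scale_rest`/`coupling_scale_task` multiply the
#' template off-diagonals per condition (task defaults to twice rest).
#'
#' @param n_regions Number of regions.
#' @param n_subjects Number of subjects per dataset.
#' @param tr_s Sampling interval (repetition time), seconds.
#' @param duration_s Run length, seconds.
#' @param neural_noise_amplitude,neural_noise_exponent Power-law parameters
#'   of the endogenous neural fluctuations.
#' @param observation_noise_amplitude,observation_noise_exponent Power-law
#'   parameters of the measurement noise.
#' @param between_subject_sd SD (Hz) of subject deviations in coupling.
#' @param coupling_scale_rest,coupling_scale_task Condition multipliers on
#'   the template between-region coupling.
#' @param countdown_s,block_s,response_s,fixation_s,n_blocks Block-design
#'   schedule: initial countdown, then `n_blocks` cycles of stimulus,
#'   response and fixation periods (seconds).
#' @param driving_region Region receiving the task input.
#' @param seed Integer seed making the generator deterministic.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_regions = 5,
                       n_subjects = 50,
                       tr_s = 0.72,
                       duration_s = 207,
                       neural_noise_amplitude = 1,
                       neural_noise_exponent = 1,
                       observation_noise_amplitude = 4,
                       observation_noise_exponent = 0.5,
                       between_subject_sd = 0.0625,
                       coupling_scale_rest = 1,
                       coupling_scale_task = 2,
                       countdown_s = 8,
                       block_s = 20,
                       response_s = 3,
                       fixation_s = 15,
                       n_blocks = 5,
                       driving_region = n_regions,
                       seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions), n_subjects = as.integer(n_subjects),
    tr_s = tr_s, duration_s = duration_s,
    neural_noise_amplitude = neural_noise_amplitude,
    neural_noise_exponent = neural_noise_exponent,
    observation_noise_amplitude = observation_noise_amplitude,
    observation_noise_exponent = observation_noise_exponent,
    between_subject_sd = between_subject_sd,
    coupling_scale_rest = coupling_scale_rest,
    coupling_scale_task = coupling_scale_task,
    countdown_s = countdown_s, block_s = block_s,
    response_s = response_s, fixation_s = fixation_s,
    n_blocks = as.integer(n_blocks),
    driving_region = as.integer(driving_region),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  durs <- c(cfg$duration_s, cfg$countdown_s, cfg$block_s,
            cfg$response_s, cfg$fixation_s)
  if (any(durs < 0)) stop("all durations must be >= 0", call. = FALSE)
  if (cfg$tr_s <= 0) stop("tr_s must be > 0", call. = FALSE)
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$n_regions < 2) stop("need at least 2 regions", call. = FALSE)
  if (cfg$between_subject_sd < 0) stop("between_subject_sd must be >= 0", call. = FALSE)
  if (cfg$n_blocks < 0) stop("n_blocks must be >= 0", call. = FALSE)
  if (cfg$neural_noise_amplitude < 0 || cfg$observation_noise_amplitude < 0) {
    stop("noise amplitudes must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

n_samples <- function(cfg) as.integer(floor(cfg$duration_s / cfg$tr_s))

#' Pipeline configuration
#'
#' Settings for the end-to-end experiment (simulate, per-subject spectral
#' DCM fits, group empirical-Bayes summary, Bayesian data comparison).
#' Serializable to/from YAML so a run is fully described by one file plus a
#' master seed.
#'
#' @param simulation A [sim_config()] (or a plain list of its fields).
#' @param mar_order Multivariate autoregression order for spectral
#'   estimation.
#' @param n_freq Number of frequency-grid points.
#' @param fmax_hz Upper frequency bound (Hz); capped at Nyquist.
#' @param max_iterations,tol_nats Inversion caps: maximum Gauss-Newton
#'   iterations and the free-energy increment (nats) under which steps
#'   count towards convergence.
#' @param model_space Model-space scheme, `"leave-one-out"` or `"custom"`.
#' @param output_dir Directory for artifacts.
#' @param seed Master seed for the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            mar_order = 8,
                            n_freq = 32,
                            fmax_hz = 0.25,
                            max_iterations = 64,
                            tol_nats = 0.01,
                            model_space = "leave-one-out",
                            output_dir = "results",
                            seed = 1L) {
  if (!inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  structure(
    list(simulation = simulation,
         mar_order = as.integer(mar_order),
         n_freq = as.integer(n_freq),
         fmax_hz = fmax_hz,
         max_iterations = as.integer(max_iterations),
         tol_nats = tol_nats,
         model_space = model_space,
         output_dir = output_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("simulation", "seed")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("config file missing required keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw$simulation <- do.call(sim_config, raw$simulation)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$simulation <- unclass(config$simulation)
  yaml::write_yaml(out, path)
  invisible(path)
}
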