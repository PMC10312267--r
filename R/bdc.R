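## Bayesian data comparison: parameter certainty, information gain over
## parameters, model space + Bayesian model reduction, information gain
## over models, evidence labels, and the dataset comparison report.

#' Parameter certainty (negative entropy), nats
#'
#' `S = -0.5 * ln det(2 pi e Sigma)`: the negative differential entropy of
#' a Gaussian belief with covariance `Sigma`. Higher values mean tighter
#' (more certain) group-level parameter estimates. Computed through a
#' Cholesky log-determinant.
#'
#' @param covariance Symmetric positive-definite matrix.
#' @return Negative entropy in nats.
#' @export
parameter_certainty <- function(covariance) {
  covariance <- as.matrix(covariance)
  ev_min <- min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop(sprintf("covariance is not positive definite (smallest eigenvalue %.3g)",
                 ev_min), call. = FALSE)
  }
  d <- nrow(covariance)
  -0.5 * (d * log(2 * pi * exp(1)) + ldet(covariance))
}

#' Gaussian belief container
#'
#' @param mean Mean vector.
#' @param covariance Covariance matrix.
#' @return List with class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  stopifnot(length(mean) == nrow(covariance), nrow(covariance) == ncol(covariance))
  structure(list(mean = mean, covariance = covariance), class = "gaussian_belief")
}

#' Information gain over parameters, nats
#'
#' Closed-form Kullback-Leibler divergence `KL(posterior || prior)` of two
#' multivariate Gaussian beliefs: how far the parameters moved from prior
#' to posterior after seeing the data. Non-negative; zero iff the beliefs
#' are identical.
#'
#' @param prior,posterior [gaussian_belief()] objects (or lists with
#'   `mean` and `covariance`).
#' @return KL divergence in nats.
#' @export
information_gain_parameters <- function(prior, posterior) {
  if (length(prior$mean) != length(posterior$mean)) {
    stop("prior and posterior dimensions differ", call. = FALSE)
  }
  gaussian_kl_core(posterior$mean, posterior$covariance,
                   prior$mean, prior$covariance)
}

#' Model space over between-region connections
#'
#' A set of equally plausible but hard-to-distinguish network
#' architectures, formed by switching individual between-region
#' connections off (restrictive priors). The default `"leave-one-out"`
#' scheme contains the full model plus one model per off-diagonal
#' connection with that connection switched off (21 models for 5
#' regions). Self-connections are always retained. Models carry uniform
#' prior probabilities.
#'
#' @param n_regions Number of regions (>= 2).
#' @param scheme `"leave-one-out"` or `"custom"`.
#' @param custom_masks For `"custom"`: list of binary region x region
#'   matrices, 1 = connection free, 0 = switched off (diagonal must be 1).
#' @return An object of class `model_space`: `masks` (list of binary
#'   matrices), `prior_model_probabilities`, `names`.
#' @export
build_model_space <- function(n_regions, scheme = c("leave-one-out", "custom"),
                              custom_masks = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_regions >= 2)
  full <- matrix(1, n_regions, n_regions)
  if (scheme == "leave-one-out") {
    masks <- list(full)
    nms <- "full"
    for (i in seq_len(n_regions)) for (j in seq_len(n_regions)) if (i != j) {
      m <- full
      m[i, j] <- 0
      masks <- c(masks, list(m))
      nms <- c(nms, sprintf("drop_%d<-%d", i, j))
    }
  } else {
    if (is.null(custom_masks)) stop("custom scheme requires custom_masks", call. = FALSE)
    masks <- lapply(custom_masks, function(m) {
      m <- as.matrix(m)
      stopifnot(all(dim(m) == n_regions), all(m %in% c(0, 1)))
      if (any(diag(m) == 0)) stop("masks must retain all self-connections", call. = FALSE)
      m
    })
    if (!any(vapply(masks, function(m) all(m == 1), logical(1)))) {
      masks <- c(list(full), masks)
    }
    keys <- vapply(masks, function(m) paste(m, collapse = ""), character(1))
    if (anyDuplicated(keys)) stop("duplicate masks in model space", call. = FALSE)
    nms <- c("full", sprintf("custom_%d", seq_len(length(masks) - 1)))
  }
  M <- length(masks)
  structure(list(masks = masks,
                 prior_model_probabilities = rep(1 / M, M),
                 names = nms, n_regions = as.integer(n_regions)),
            class = "model_space")
}

#' Bayesian model reduction
#'
#' Analytic posterior and log-evidence change when the prior of a fitted
#' linear-Gaussian model is replaced by a reduced prior (exact for
#' Gaussian beliefs): with posterior precision `P`, prior precision `P0`
#' and reduced-prior precision `Pr`, the reduced posterior has precision
#' `P + Pr - P0` and the evidence changes by the corresponding Gaussian
#' normalisation terms.
#'
#' @param posterior,prior,reduced_prior [gaussian_belief()] objects of
#'   matching dimension.
#' @return List with `posterior` (a `gaussian_belief`) and
#'   `delta_evidence` (nats; log-evidence of the reduced model minus the
#'   full model).
#' @export
bayesian_model_reduction <- function(posterior, prior, reduced_prior) {
  d <- length(posterior$mean)
  if (length(prior$mean) != d || length(reduced_prior$mean) != d) {
    stop("dimension mismatch between beliefs", call. = FALSE)
  }
  P <- chol2inv(chol(posterior$covariance))
  P0 <- chol2inv(chol(prior$covariance))
  Pr <- chol2inv(chol(reduced_prior$covariance))
  Pt <- P + Pr - P0
  cht <- tryCatch(chol(Pt), error = function(e) NULL)
  if (is.null(cht)) {
    kap <- tryCatch(kappa(Pt), error = function(e) NA_real_)
    stop(sprintf("reduced precision not positive definite (condition number %.3g)",
                 kap), call. = FALSE)
  }
  St <- chol2inv(cht)
  h <- P %*% posterior$mean + Pr %*% reduced_prior$mean - P0 %*% prior$mean
  mt <- St %*% h
  c_term <- sum(posterior$mean * (P %*% posterior$mean)) +
    sum(reduced_prior$mean * (Pr %*% reduced_prior$mean)) -
    sum(prior$mean * (P0 %*% prior$mean))
  dF <- 0.5 * (ldet(St) - ldet(posterior$covariance) +
                 ldet(prior$covariance) - ldet(reduced_prior$covariance)) +
    0.5 * (sum(mt * (Pt %*% mt)) - c_term)
  list(posterior = gaussian_belief(as.numeric(mt), (St + t(St)) / 2),
       delta_evidence = as.numeric(dF))
}

# map a connection mask to a reduced prior over the PEB beta belief:
# switched-off between-region connections get mean 0, variance 1e-6
reduced_prior_for_mask <- function(mask, prior_mean, prior_cov, field_indices,
                                   n_regions, off_variance = 1e-6) {
  lay <- dcm_par_layout(n_regions)
  # positions of the A off-diagonals within the selected field block
  a_pos <- match(lay$A, field_indices)
  # row-major traversal matching the layout
  ij <- do.call(rbind, lapply(seq_len(n_regions), function(i) {
    cbind(i, setdiff(seq_len(n_regions), i))
  }))
  off <- which(mask[ij] == 0)
  m <- prior_mean
  V <- prior_cov
  sel <- a_pos[off]
  sel <- sel[!is.na(sel)]
  if (length(sel)) {
    m[sel] <- 0
    V[sel, ] <- 0
    V[, sel] <- 0
    diag(V)[sel] <- off_variance
  }
  gaussian_belief(m, V)
}

softmax <- function(logw) {
  w <- exp(logw - max(logw))
  w / sum(w)
}

discrete_kl_uniform <- function(prob) {
  prob <- prob[prob > 0]
  sum(prob * log(prob * length(prob)))
}

#' Information gain over models, nats
#'
#' Scores how well a dataset discriminates among the architectures of a
#' [build_model_space()]: each reduced model's log evidence is obtained by
#' [bayesian_model_reduction()] of the group-level `beta` belief, model
#' posterior probabilities follow by normalised exponentiation
#' (log-sum-exp guarded), and the result is the discrete KL divergence of
#' that posterior from the uniform prior — in `[0, ln M]`.
#'
#' @param peb A [fit_peb()] result.
#' @param space A [build_model_space()].
#' @return List with `info_gain` (nats), `log_evidence`,
#'   `posterior_probabilities`.
#' @export
information_gain_models <- function(peb, space) {
  stopifnot(inherits(peb, "peb_model"), inherits(space, "model_space"))
  if (space$n_regions != peb$n_regions) {
    stop("model space and PEB model have different region counts", call. = FALSE)
  }
  k <- ncol(peb$beta_mean)
  d <- nrow(peb$beta_mean)
  # reductions act on the group-mean column; other covariates untouched
  post <- gaussian_belief(as.numeric(peb$beta_mean), peb$beta_covariance)
  prior <- gaussian_belief(peb$prior_mean, peb$prior_covariance)
  logev <- vapply(space$masks, function(mask) {
    red_mean <- peb$prior_mean
    red_cov <- peb$prior_covariance
    mean_col <- reduced_prior_for_mask(mask, peb$prior_mean[seq_len(d)],
                                       peb$prior_covariance[seq_len(d), seq_len(d), drop = FALSE],
                                       peb$field_indices, peb$n_regions)
    red_mean[seq_len(d)] <- mean_col$mean
    red_cov[seq_len(d), seq_len(d)] <- mean_col$covariance
    bayesian_model_reduction(post, prior,
                             gaussian_belief(red_mean, red_cov))$delta_evidence
  }, numeric(1))
  prob <- softmax(logev + log(space$prior_model_probabilities))
  list(info_gain = discrete_kl_uniform(prob),
       log_evidence = logev,
       posterior_probabilities = prob)
}

#' Evidence category for a difference in nats
#'
#' Conventional thresholds: below 1.1 nats the difference is insufficient
#' to count as evidence; 1.1-3 nats is positive evidence; 3-5 nats strong;
#' beyond 5 nats very strong.
#'
#' @param delta Non-negative difference in nats.
#' @return One of `"insufficient"`, `"positive"`, `"strong"`,
#'   `"very strong"`.
#' @export
label_evidence <- function(delta) {
  if (any(delta < 0)) stop("evidence difference must be >= 0", call. = FALSE)
  cut_labels <- c("insufficient", "positive", "strong", "very strong")
  cut_labels[findInterval(delta, c(0, 1.1, 3, 5))]
}

#' Compare two fitted datasets
#'
#' Computes the three quality indices for each dataset from its PEB
#' belief — parameter certainty, information gain over parameters, and
#' information gain over models (all from the same group-level `beta`
#' belief) — and reports each index difference relative to the worst
#' dataset with an evidence label.
#'
#' @param peb_a,peb_b [fit_peb()] results for the two datasets (same
#'   regions, same parameter block, same priors).
#' @param space A [build_model_space()]; defaults to leave-one-out.
#' @param labels Dataset labels (length 2).
#' @return An object of class `quality_report`: `indices` (data frame,
#'   one row per dataset), `differences` (data frame with index, best
#'   dataset, difference in nats, evidence label).
#' @export
compare_datasets <- function(peb_a, peb_b, space = NULL,
                             labels = c("dataset_a", "dataset_b")) {
  stopifnot(inherits(peb_a, "peb_model"), inherits(peb_b, "peb_model"))
  if (!identical(peb_a$field_indices, peb_b$field_indices) ||
      peb_a$n_regions != peb_b$n_regions) {
    stop("datasets were fitted with mismatched parameterizations", call. = FALSE)
  }
  if (is.null(space)) space <- build_model_space(peb_a$n_regions)
  one <- function(peb, label) {
    post <- gaussian_belief(as.numeric(peb$beta_mean), peb$beta_covariance)
    prior <- gaussian_belief(peb$prior_mean, peb$prior_covariance)
    data.frame(
      dataset = label,
      parameter_certainty = parameter_certainty(peb$beta_covariance),
      info_gain_parameters = information_gain_parameters(prior, post),
      info_gain_models = information_gain_models(peb, space)$info_gain,
      stringsAsFactors = FALSE
    )
  }
  idx <- rbind(one(peb_a, labels[1]), one(peb_b, labels[2]))
  diffs <- do.call(rbind, lapply(
    c("parameter_certainty", "info_gain_parameters", "info_gain_models"),
    function(nm) {
      v <- idx[[nm]]
      best <- which.max(v)
      data.frame(index = nm, best_dataset = idx$dataset[best],
                 difference_nats = v[best] - v[-best][1],
                 stringsAsFactors = FALSE)
    }))
  diffs$evidence <- label_evidence(diffs$difference_nats)
  structure(list(indices = idx, differences = diffs, labels = labels),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\nPer-dataset indices (nats):\n")
  print(x$indices, row.names = FALSE)
  cat("Differences relative to the worst dataset:\n")
  print(x$differences, row.names = FALSE)
  invisible(x)
}
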