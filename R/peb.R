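## Group stages: empirical-Bayes reestimation of subject fits under
## group-average priors, and the hierarchical parametric-empirical-Bayes
## (PEB) summary of one dataset.

#' Reestimate subject DCMs under group-average priors
#'
#' Computes the grand average of the posterior means over all supplied
#' subjects (typically the concatenation of both datasets' subjects), sets
#' it as the new prior mean with the default shrinkage prior covariance,
#' and re-inverts every subject from its stored spectral data. This can
#' rescue subjects whose first fit fell into a different local optimum.
#'
#' @param posteriors List of `dcm_posterior` (all subjects, both
#'   datasets).
#' @param prior_covariance Optional prior covariance for the refit;
#'   defaults to the shrinkage prior of [dcm_priors()].
#' @param settings Inversion settings passed to [variational_laplace()].
#' @return List of reestimated `dcm_posterior`, same length and order.
#' @export
reestimate_with_group_priors <- function(posteriors, prior_covariance = NULL,
                                         settings = list()) {
  if (length(posteriors) == 0) stop("no posteriors supplied", call. = FALSE)
  stopifnot(all(vapply(posteriors, inherits, logical(1), "dcm_posterior")))
  dims <- vapply(posteriors, function(x) length(x$mean), integer(1))
  if (length(unique(dims)) != 1) {
    stop("mismatched parameter orders across subjects", call. = FALSE)
  }
  grand_mean <- rowMeans(vapply(posteriors, function(x) x$mean,
                                numeric(dims[1])))
  p <- posteriors[[1]]$n_regions
  priors <- dcm_priors(p, mean = grand_mean)
  if (!is.null(prior_covariance)) priors$covariance <- prior_covariance
  lapply(posteriors, function(post) {
    variational_laplace(post$data$observed, priors,
                        settings = utils::modifyList(post$data$settings, settings),
                        input_power = post$data$input_power,
                        feature_weights = post$data$feature_weights)
  })
}

#' Hierarchical PEB model of one dataset
#'
#' Summarises one dataset's subject posteriors with the two-level model
#' `theta_s = X_s beta + E_s` over the selected parameter block
#' (default: the invariant-connectivity block, i.e. the A off-diagonals
#' and self log-scaling values). Subject posteriors enter through
#' Bayesian-model-reduction evidence (no refit of timeseries): for a given
#' between-subject covariance, the model is linear-Gaussian in `beta`, so
#' the `beta` belief is exact; the single between-subject log-precision
#' hyperparameter is optimised by free-energy ascent.
#'
#' The between-subject covariance is parameterised as
#' `exp(-gamma) * Q` with `Q` the within-subject prior variances divided
#' by 16 and `gamma ~ N(0, 1/16)`. Group priors on `beta` default to the
#' within-subject shrinkage priors for the group-mean column and zero-mean
#' shrinkage for other covariates.
#'
#' @param posteriors List of `dcm_posterior` for one dataset (>= 2).
#' @param X Design matrix, subjects x covariates; first column must be the
#'   constant group mean. Default: intercept only.
#' @param group_priors Optional list with `mean`, `covariance` for `beta`.
#' @param field `"a_block"` (default) or `"all"`: which parameter block to
#'   take to the group level.
#' @param gamma_prior_var Prior variance of the log-precision
#'   hyperparameter.
#' @param fix_gamma Optional fixed value of gamma (skips optimisation);
#'   useful for sensitivity analyses.
#' @return An object of class `peb_model`: `design_matrix`, `beta_mean`
#'   (block-parameters x covariates matrix), `beta_covariance`,
#'   `between_subject_covariance`, `free_energy`, `complexity`,
#'   `prior_mean`, `prior_covariance`, `gamma`, `field_indices`.
#' @export
fit_peb <- function(posteriors, X = NULL, group_priors = NULL,
                    field = c("a_block", "all"), gamma_prior_var = 1 / 16,
                    fix_gamma = NULL) {
  field <- match.arg(field)
  n <- length(posteriors)
  if (n < 2) stop("PEB requires >= 2 subjects", call. = FALSE)
  stopifnot(all(vapply(posteriors, inherits, logical(1), "dcm_posterior")))
  dims <- vapply(posteriors, function(x) length(x$mean), integer(1))
  if (length(unique(dims)) != 1) {
    stop("mismatched parameter orders across subjects", call. = FALSE)
  }
  p <- posteriors[[1]]$n_regions
  lay <- dcm_par_layout(p)
  idx <- if (field == "a_block") lay$a_block else seq_len(lay$n)
  d <- length(idx)

  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("design matrix row count must equal subject count", call. = FALSE)
  k <- ncol(X)
  if (n < k) stop("fewer subjects than covariates", call. = FALSE)
  if (qr(X)$rank < k) stop("singular design matrix", call. = FALSE)
  if (any(X[, 1] != 1)) stop("first design column must be the constant group mean", call. = FALSE)

  mu_s <- lapply(posteriors, function(x) x$mean[idx])
  Sg_s <- lapply(posteriors, function(x) x$covariance[idx, idx, drop = FALSE])
  mu0_s <- lapply(posteriors, function(x) x$priors$mean[idx])
  S0_s <- lapply(posteriors, function(x) x$priors$covariance[idx, idx, drop = FALSE])
  Pi_s <- lapply(Sg_s, function(S) chol2inv(chol(S)))
  Pi0_s <- lapply(S0_s, function(S) chol2inv(chol(S)))
  ld_Sg <- vapply(Sg_s, ldet, numeric(1))
  ld_S0 <- vapply(S0_s, ldet, numeric(1))
  Fs <- vapply(posteriors, function(x) x$free_energy, numeric(1))

  # within-subject reference priors define Q and the default group priors
  ref <- dcm_priors(p)
  q_var <- diag(ref$covariance)[idx] / 16
  if (is.null(group_priors)) {
    b0 <- c(ref$mean[idx], rep(0, d * (k - 1)))
    B0 <- diag(rep(diag(ref$covariance)[idx], k))
  } else {
    b0 <- group_priors$mean
    B0 <- group_priors$covariance
    stopifnot(length(b0) == d * k, all(dim(B0) == d * k))
  }
  B0_inv <- solve(B0)
  ld_B0 <- ldet(B0)

  evaluate <- function(gamma) {
    g_var <- exp(-gamma) * q_var
    W <- diag(1 / g_var, d)
    ldG <- sum(log(g_var))
    H <- matrix(0, d * k, d * k)
    gvec <- numeric(d * k)
    lconst <- sum(Fs)
    for (s in seq_len(n)) {
      Pt <- Pi_s[[s]] + W - Pi0_s[[s]]
      ch <- tryCatch(chol(Pt), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      V <- chol2inv(ch)
      ldV <- -2 * sum(log(diag(ch)))
      q <- Pi_s[[s]] %*% mu_s[[s]] - Pi0_s[[s]] %*% mu0_s[[s]]
      WV <- W %*% V
      H <- H + kronecker(tcrossprod(X[s, ]), WV %*% W - W)
      gvec <- gvec + as.numeric(kronecker(X[s, ], as.numeric(WV %*% q)))
      lconst <- lconst + 0.5 * (ldV - ld_Sg[s] + ld_S0[s] - ldG) +
        0.5 * (sum(q * (V %*% q)) - sum(mu_s[[s]] * (Pi_s[[s]] %*% mu_s[[s]])) +
                 sum(mu0_s[[s]] * (Pi0_s[[s]] %*% mu0_s[[s]])))
    }
    Pb <- B0_inv - H
    chb <- tryCatch(chol(Pb), error = function(e) NULL)
    if (is.null(chb)) return(NULL)
    Sb <- chol2inv(chb)
    mb <- Sb %*% (B0_inv %*% b0 + gvec)
    Fv <- lconst + 0.5 * (-2 * sum(log(diag(chb))) - ld_B0) +
      0.5 * (sum(mb * (Pb %*% mb)) - sum(b0 * (B0_inv %*% b0))) -
      0.5 * gamma^2 / gamma_prior_var
    if (!is.finite(Fv)) return(NULL)
    list(F = Fv, beta_mean = as.numeric(mb), beta_cov = Sb, gamma = gamma,
         between_cov = diag(g_var, d))
  }

  if (is.null(fix_gamma)) {
    fobj <- function(g) {
      e <- evaluate(g)
      if (is.null(e)) -1e12 else e$F
    }
    opt <- stats::optimize(fobj, interval = c(-6, 6), maximum = TRUE, tol = 1e-4)
    gamma_hat <- opt$maximum
  } else {
    gamma_hat <- fix_gamma
  }
  best <- evaluate(gamma_hat)
  if (is.null(best)) stop("PEB free energy not computable at the optimum", call. = FALSE)

  # Laplace correction for the hyperparameter uncertainty
  eps <- 1e-3
  fp <- evaluate(gamma_hat + eps); fm <- evaluate(gamma_hat - eps)
  hess <- if (!is.null(fp) && !is.null(fm)) {
    (fp$F - 2 * best$F + fm$F) / eps^2
  } else NA_real_
  gamma_var <- if (is.finite(hess) && hess < 0) -1 / hess else gamma_prior_var
  F_total <- best$F + 0.5 * log(gamma_var / gamma_prior_var) + 0.5

  structure(
    list(design_matrix = X,
         beta_mean = matrix(best$beta_mean, d, k),
         beta_covariance = (best$beta_cov + t(best$beta_cov)) / 2,
         between_subject_covariance = best$between_cov,
         free_energy = F_total,
         complexity = gaussian_kl_core(best$beta_mean, best$beta_cov, b0, B0),
         prior_mean = b0, prior_covariance = B0,
         gamma = gamma_hat, gamma_variance = gamma_var,
         field_indices = idx, n_subjects = n, n_regions = p),
    class = "peb_model"
  )
}

#' @export
print.peb_model <- function(x, ...) {
  cat(sprintf("<peb_model> %d subjects, %d group parameters x %d covariates | F = %.2f nats, gamma = %.2f\n",
              x$n_subjects, nrow(x$beta_mean), ncol(x$beta_mean),
              x$free_energy, x$gamma))
  invisible(x)
}
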