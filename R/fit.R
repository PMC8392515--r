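#' Fit the structural equation model
#'
#' Front-end for the three estimators.  `method = "bayes"` runs a
#' conjugate Gibbs sampler (normal priors on loadings and path
#' coefficients, inverse-gamma priors on residual variances, latent
#' scores sampled from their exact Gaussian full conditional);
#' `method = "ml"` minimizes the maximum-likelihood discrepancy between
#' the sample and model-implied covariance matrices by multi-start
#' quasi-Newton with an analytic gradient; `method = "pls"` runs partial
#' least squares path modelling (Mode-A outer estimation, centroid inner
#' scheme) followed by ordinary least squares on the factor scores.
#'
#' All observed variables are z-standardized internally and the reported
#' solution is fully standardized: latent constructs have unit variance
#' and each construct's sign is fixed by its first loading being
#' positive.  Coefficient estimates are therefore comparable across
#' estimators and across groups.
#'
#' @param data a data frame containing every observed variable of `spec`
#'   with no missing values.  Extra columns (such as the group label) are
#'   ignored.
#' @param spec a [sem_spec]; defaults to [obesity_model()].
#' @param method `"bayes"`, `"ml"` or `"pls"`.
#' @param prior a [prior_config] (Bayes only), default [diffuse_prior()].
#' @param mcmc an [mcmc_config] (Bayes only).
#' @param ... further arguments passed to the estimator backends:
#'   `n_starts`, `start` for ML; `tol`, `max_iter` for PLS.
#'
#' @return An object of class `c("bsem_fit"|"mlsem_fit"|"plssem_fit",
#'   "sem_fit")` with components `estimates` (named standardized
#'   estimates), `se` (uncertainty: posterior SD or delta-method
#'   asymptotic SE; `NA` for PLS), `structural` (a data frame of path
#'   estimates), plus estimator-specific pieces (posterior `draws`,
#'   `chisq`/`df`/`discrepancy`, outer weights, ...).  Methods:
#'   [print()], [summary()], [coef()], [predict()], [residuals()],
#'   [simulate()], [plot()].
#'
#' @examples
#' d <- simulate_study(300, 0.5, seed = 42)
#' fit <- sem_fit(d[d$gender == "girl", ], method = "pls")
#' coef(fit)[1:3]
#' @export
sem_fit <- function(data, spec = obesity_model(),
                    method = c("bayes", "ml", "pls"),
                    prior = diffuse_prior(), mcmc = mcmc_config(), ...) {
  method <- match.arg(method)
  sd <- standardize_data(data, spec)
  fit <- switch(method,
                bayes = gibbs_backend(sd, spec, prior, mcmc, ...),
                ml = ml_backend(sd, spec, ...),
                pls = pls_backend(sd, spec, ...))
  fit$spec <- spec
  fit$method <- method
  fit$n <- sd$n
  fit$scaling <- sd[c("center", "scale")]
  fit$data_std <- sd$X
  lbl <- path_labels(spec)
  fit$structural <- data.frame(
    path = lbl,
    estimate = unname(fit$estimates[lbl]),
    se = unname(fit$se[lbl]),
    stringsAsFactors = FALSE)
  class(fit) <- c(switch(method, bayes = "bsem_fit", ml = "mlsem_fit",
                         pls = "plssem_fit"),
                  "sem_fit")
  fit
}

# z-standardize the observed block; errors on missing columns, missing
# values or zero-variance variables
standardize_data <- function(data, spec) {
  obs <- spec_observed(spec)
  miss <- setdiff(obs, names(data))
  if (length(miss))
    stop("data lack model variable(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(data[, obs, drop = FALSE])
  if (!is.numeric(X)) stop("model variables must be numeric")
  if (anyNA(X))
    stop("missing values in: ",
         paste(obs[colSums(is.na(X)) > 0], collapse = ", "))
  if (nrow(X) < 3) stop("need at least 3 observations")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl <= 0))
    stop("zero-variance variable(s): ", paste(obs[scl <= 0], collapse = ", "))
  list(X = scale(X, center = ctr, scale = scl), center = ctr, scale = scl,
       n = nrow(X))
}

# index bookkeeping shared by the estimators
model_index <- function(spec) {
  ind <- spec_indicators(spec)
  lat <- names(spec$latents)
  eqs <- lapply(intersect(topological_order(spec), endogenous_vars(spec)),
                function(v) {
                  rows <- which(spec$paths$target == v)
                  list(target = v,
                       is_latent = v %in% lat,
                       sources = spec$paths$source[rows],
                       labels = path_labels(spec)[rows])
                })
  list(ind = ind, lat = lat, nl = length(lat), q = length(ind),
       lat_of = match(indicator_latent(spec), lat),
       first_ind = vapply(spec$latents, `[`, "", 1L),
       eqs = eqs, labels = path_labels(spec))
}

# covariance of the structural block on an arbitrary (raw) scale
raw_structural_cov <- function(spec, structural, lat_var, ctl_var, out_var) {
  vars <- structural_vars(spec)
  m <- length(vars)
  B <- matrix(0, m, m, dimnames = list(vars, vars))
  B[cbind(match(spec$paths$target, vars),
          match(spec$paths$source, vars))] <- structural[path_labels(spec)]
  psi <- c(lat_var, ctl_var, out_var)[vars]
  E <- solve(diag(m) - B)
  S <- E %*% (psi * t(E))
  dimnames(S) <- list(vars, vars)
  S
}

# Fully standardized solution from raw-scale parameters.
# lat_var: latent disturbance variances (total variance for exogenous),
# on whatever sampling scale the estimator used.  Returns the named
# vector of standardized loadings, paths, and outcome R-squared values.
std_solution <- function(spec, loadings, structural, psi_ind, psi_out,
                         lat_var, ctl_var) {
  Su <- raw_structural_cov(spec, structural, lat_var, ctl_var, psi_out)
  s_u <- sqrt(diag(Su))
  ind <- spec_indicators(spec)
  s_lat_of <- s_u[indicator_latent(spec)]
  tot_ind <- loadings^2 * s_lat_of^2 + psi_ind
  lo <- loadings * s_lat_of / sqrt(tot_ind)
  b_std <- structural * s_u[spec$paths$source] / s_u[spec$paths$target]
  r2 <- 1 - psi_out[spec$outcomes] / diag(Su)[spec$outcomes]
  c(setNames(lo, ind),
    setNames(b_std, path_labels(spec)),
    setNames(r2, paste0("r2_", spec$outcomes)))
}

#' Model-based predictions of the outcomes
#'
#' Computes per-row predictions of the outcome variables from a parameter
#' set: factor scores for the latent constructs are obtained by the
#' regression method from the indicator block (the conditional mean of
#' the latents given the indicators), and the structural equations for
#' the outcomes are then applied to the scores plus the control columns.
#' Mediator equations are not substituted -- the scores already condition
#' on all indicators.
#'
#' `data` must be on the same scale as `params` (for the standardized
#' parameter sets produced by [true_params()] this is the generator's
#' own scale).  Fitted-model predictions with automatic rescaling are
#' available through [predict.sem_fit()].
#'
#' @param spec a [sem_spec].
#' @param params a [parameter_set].
#' @param data data frame with the indicator and control columns.
#' @return A numeric matrix with one row per observation and one column
#'   per outcome.
#' @export
predict_outcomes <- function(spec, params, data) {
  stopifnot(inherits(spec, "sem_spec"), inherits(params, "parameter_set"))
  need <- c(spec_indicators(spec), spec$controls)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lack model variable(s): ", paste(miss, collapse = ", "))
  eta <- factor_scores_reg(spec, params, data)
  O <- matrix(0, nrow(data), length(spec$outcomes),
              dimnames = list(NULL, spec$outcomes))
  for (o in spec$outcomes) {
    rows <- spec$paths$target == o
    for (k in which(rows)) {
      src <- spec$paths$source[k]
      b <- params$structural[path_labels(spec)[k]]
      O[, o] <- O[, o] + b * (if (src %in% names(spec$latents)) eta[, src]
                              else data[[src]])
    }
  }
  O
}

# regression-method factor scores E[eta | indicators]
factor_scores_reg <- function(spec, params, data) {
  ind <- spec_indicators(spec)
  X <- as.matrix(data[, ind, drop = FALSE])
  Seta <- latent_cov(spec, params)
  lam <- params$loadings[ind]
  lat <- indicator_latent(spec)
  Lam <- matrix(0, length(ind), ncol(Seta),
                dimnames = list(ind, colnames(Seta)))
  Lam[cbind(seq_along(ind), match(lat, colnames(Seta)))] <- lam
  Sxx <- Lam %*% Seta %*% t(Lam)
  diag(Sxx) <- diag(Sxx) + params$residual_variances[ind]
  A <- tryCatch(t(solve(Sxx, Lam %*% Seta)),
                error = function(e) Seta %*% t(Lam) %*% MASS::ginv(Sxx))
  sc <- X %*% t(A)
  colnames(sc) <- colnames(Seta)
  sc
}
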