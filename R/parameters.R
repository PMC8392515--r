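#' Bundle numeric parameter values for an SEM specification
#'
#' A `parameter_set` holds every quantity needed to turn a [sem_spec] into
#' a concrete linear-Gaussian population: standardized factor loadings,
#' structural/control path coefficients, residual variances for indicators
#' and outcomes, disturbance variances for the latent constructs (total
#' variance for exogenous constructs) and variances of the observed
#' controls.
#'
#' @param spec a [sem_spec].
#' @param loadings named numeric vector, one value per indicator.
#' @param structural named numeric vector, one value per path; names must
#'   match `paste(spec$paths$source, "->", spec$paths$target)`.
#' @param residual_variances named numeric vector over indicators and
#'   outcomes.  Zero is allowed (a noise-free variable) but negative
#'   values are rejected.
#' @param latent_disturbances named numeric vector over latent constructs:
#'   the disturbance variance for endogenous constructs and the total
#'   variance for exogenous ones.  Defaults to 1 for each.
#' @param control_variances named numeric vector over controls, default 1.
#'
#' @return An object of class `parameter_set`.
#' @seealso [true_params()] for the default generating values.
#' @export
parameter_set <- function(spec, loadings, structural, residual_variances,
                          latent_disturbances = NULL,
                          control_variances = NULL) {
  stopifnot(inherits(spec, "sem_spec"))
  ind <- spec_indicators(spec)
  lbl <- path_labels(spec)
  if (is.null(latent_disturbances))
    latent_disturbances <- setNames(rep(1, length(spec$latents)),
                                    names(spec$latents))
  if (is.null(control_variances))
    control_variances <- setNames(rep(1, length(spec$controls)),
                                  spec$controls)
  need <- function(x, names, what) {
    miss <- setdiff(names, names(x))
    if (length(miss))
      stop("missing ", what, ": ", paste(miss, collapse = ", "))
    x[names]
  }
  loadings <- need(loadings, ind, "loadings")
  structural <- need(structural, lbl, "structural coefficients")
  residual_variances <- need(residual_variances, c(ind, spec$outcomes),
                             "residual variances")
  latent_disturbances <- need(latent_disturbances, names(spec$latents),
                              "latent disturbance variances")
  control_variances <- need(control_variances, spec$controls,
                            "control variances")
  if (any(residual_variances < 0))
    stop("negative residual variance for: ",
         paste(names(residual_variances)[residual_variances < 0],
               collapse = ", "))
  if (any(latent_disturbances < 0) || any(control_variances < 0))
    stop("latent disturbance and control variances must be non-negative")
  structure(list(loadings = loadings, structural = structural,
                 residual_variances = residual_variances,
                 latent_disturbances = latent_disturbances,
                 control_variances = control_variances),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("parameter_set:", length(x$loadings), "loadings,",
      length(x$structural), "paths\n")
  cat("structural coefficients:\n")
  print(round(x$structural, 3))
  invisible(x)
}

# printed standardized loadings of the survey's measurement model
.obesity_loadings <- c(
  age_father = 0.48, age_mother = 0.32, edu_father = 0.79, edu_mother = 0.71,
  income_mother = 0.46, income_father = 0.79,
  sleep = 0.81, physical_activity = 0.83, screen_time = 0.79,
  pocket_money = 0.87,
  fruits = 0.73, vegetables = 0.71, whole_grains = 0.76,
  snacks = 0.88, fast_food = 0.87, soft_drink = 0.95, sweets = 0.93)

# group-specific standardized path coefficients, in default path order
.obesity_paths <- list(
  boy  = c(0.41, 0.08, 0.31, -0.19, 0.22, 0.06, 0.37, -0.09, -0.29,
           0.09, 0.34, 0.53, 0.65, 0.19, 0.23),
  girl = c(0.61, 0.31, 0.05, 0.10, 0.09, 0.25, 0.33, -0.20, -0.21,
           -0.21, 0.22, 0.71, 0.76, 0.22, 0.18))

#' Generating ("true") parameter values for the obesity model
#'
#' Returns the per-group population used by the synthetic-data generator:
#' the reported standardized factor loadings of the four constructs and the
#' group-specific standardized path coefficients (boys' and girls' models
#' differ), with residual and disturbance variances solved so that every
#' variable -- indicator, latent construct and outcome -- has unit total
#' variance.  If a requested coefficient pattern cannot be standardized
#' (an explained variance at or above 1), the function stops and names the
#' offending variable.
#'
#' @param group `"boy"` or `"girl"`.
#' @param spec the model topology; defaults to [obesity_model()].
#' @return A [parameter_set].
#' @examples
#' p <- true_params("girl")
#' p$structural["ses -> healthy"]   # 0.61
#' @export
true_params <- function(group = c("girl", "boy"), spec = obesity_model()) {
  group <- match.arg(group)
  stopifnot(identical(spec$latents, obesity_model()$latents))
  canon <- setNames(.obesity_paths[[group]], path_labels(obesity_model()))
  structural <- canon[path_labels(spec)]
  if (anyNA(structural))
    stop("spec contains paths outside the default obesity model")
  names(structural) <- path_labels(spec)
  standardized_params(spec, loadings = .obesity_loadings,
                      structural = structural)
}

#' Build a unit-variance parameter set from loadings and paths
#'
#' Given standardized loadings and standardized path coefficients, solves
#' for the residual/disturbance variances under which every observed and
#' latent variable has total variance 1, and returns the complete
#' [parameter_set].  Errors if any implied residual variance would be
#' negative.
#'
#' @inheritParams parameter_set
#' @return A [parameter_set].
#' @export
standardized_params <- function(spec, loadings, structural) {
  ind <- spec_indicators(spec)
  loadings <- loadings[ind]
  lbl <- path_labels(spec)
  structural <- structural[lbl]
  if (anyNA(loadings) || anyNA(structural))
    stop("loadings/structural coefficients incomplete for this spec")
  vars <- structural_vars(spec)
  m <- length(vars)
  B <- matrix(0, m, m, dimnames = list(vars, vars))
  B[cbind(match(spec$paths$target, vars),
          match(spec$paths$source, vars))] <- structural
  # walk the DAG: each endogenous variable's disturbance tops its
  # explained variance up to 1
  Sigma <- diag(1, m); dimnames(Sigma) <- list(vars, vars)
  psi <- setNames(rep(1, m), vars)
  endo <- intersect(topological_order(spec), endogenous_vars(spec))
  for (v in endo) {
    b <- B[v, ]
    pred <- names(b)[b != 0]
    expl <- drop(b[pred] %*% Sigma[pred, pred, drop = FALSE] %*% b[pred])
    if (expl >= 1)
      stop("cannot standardize '", v, "': explained variance ",
           round(expl, 3), " >= 1")
    psi[v] <- 1 - expl
    Sigma[v, ] <- Sigma[, v] <- drop(Sigma %*% b)
    Sigma[v, v] <- 1
  }
  if (any(abs(loadings) >= 1))
    stop("standardized loadings must lie strictly inside (-1, 1)")
  parameter_set(
    spec,
    loadings = loadings,
    structural = setNames(as.numeric(structural), lbl),
    residual_variances = c(setNames(1 - loadings^2, ind),
                           psi[spec$outcomes]),
    latent_disturbances = psi[names(spec$latents)],
    control_variances = setNames(rep(1, length(spec$controls)),
                                 spec$controls))
}

# ---- implied moments ------------------------------------------------------

# covariance of the structural block (latents, controls, outcomes)
structural_cov <- function(spec, params) {
  vars <- structural_vars(spec)
  m <- length(vars)
  B <- matrix(0, m, m, dimnames = list(vars, vars))
  B[cbind(match(spec$paths$target, vars),
          match(spec$paths$source, vars))] <- params$structural
  psi <- c(params$latent_disturbances, params$control_variances,
           params$residual_variances[spec$outcomes])[vars]
  E <- solve(diag(m) - B)
  S <- E %*% (psi * t(E))   # E diag(psi) E'
  dimnames(S) <- list(vars, vars)
  S
}

#' Model-implied covariance matrix
#'
#' Computes the population covariance matrix of all observed variables
#' (indicators, controls, outcomes -- in the specification's fixed order)
#' implied by a parameter set under the linear-Gaussian SEM.
#'
#' @param spec a [sem_spec].
#' @param params a [parameter_set].
#' @return A symmetric positive-definite covariance matrix with one
#'   row/column per observed variable.
#' @export
implied_cov <- function(spec, params) {
  stopifnot(inherits(spec, "sem_spec"), inherits(params, "parameter_set"))
  Su <- structural_cov(spec, params)
  ind <- spec_indicators(spec)
  lat <- indicator_latent(spec)
  obs <- spec_observed(spec)
  co <- c(spec$controls, spec$outcomes)
  lam <- params$loadings[ind]
  Sxx <- lam * Su[lat, lat] * rep(lam, each = length(ind)) # Lam S Lam'
  diag(Sxx) <- diag(Sxx) + params$residual_variances[ind]
  Sxc <- lam * Su[lat, co, drop = FALSE]
  S <- rbind(cbind(Sxx, Sxc), cbind(t(Sxc), Su[co, co]))
  dimnames(S) <- list(obs, obs)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= -1e-8 * max(ev))
    stop("implied covariance is not positive semi-definite ",
         "(smallest eigenvalue ", signif(min(ev), 3),
         "); check residual variances")
  S
}

# latent covariance block, used by factor scoring
latent_cov <- function(spec, params)
  structural_cov(spec, params)[names(spec$latents), names(spec$latents),
                               drop = FALSE]
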