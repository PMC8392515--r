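# Maximum-likelihood backend.
#
# The model is written in RAM form over v = (latents, indicators,
# controls, outcomes): v = A v + u, u ~ N(0, diag(s)), implied covariance
# F (I-A)^-1 diag(s) (I-A)^-T F'.  Free parameters: all loadings, all
# structural/control paths, log residual variances of indicators and
# outcomes, log control variances.  Latent scales are pinned exactly as
# in the Gibbs sampler -- every latent disturbance variance is fixed at 1
# (the total variance for the exogenous construct) -- which leaves no
# unidentified scale direction while keeping all loadings free; signs
# are fixed after convergence by flipping constructs whose first
# loading is negative.  The discrepancy
#   F_ML = log det Sigma + tr(S Sigma^-1) - log det S - p
# is minimized by nlminb with the analytic gradient; standard errors come
# from the expected information at the optimum, and standardized-solution
# SEs by the delta method with a numerical Jacobian.

ml_layout <- function(spec) {
  mi <- model_index(spec)
  vars <- c(mi$lat, spec_observed(spec))
  m <- length(vars)
  obs <- match(spec_observed(spec), vars)
  # A-matrix free entries: loadings then paths
  a_rows <- c(match(mi$ind, vars), match(spec$paths$target, vars))
  a_cols <- c(match(mi$lat[mi$lat_of], vars), match(spec$paths$source, vars))
  a_names <- c(mi$ind, mi$labels)
  # diagonal free entries (log scale); all latent disturbances fixed at 1
  endo_lat <- intersect(mi$lat, spec$paths$target)
  s_vars <- c(mi$ind, spec$outcomes, spec$controls)
  s_idx <- match(s_vars, vars)
  s_names <- paste0("v_", s_vars)
  fixed_one <- match(mi$lat, vars)
  list(mi = mi, vars = vars, m = m, obs = obs,
       a_rows = a_rows, a_cols = a_cols, a_names = a_names,
       n_a = length(a_rows), s_idx = s_idx, s_names = s_names,
       endo_lat = endo_lat, fixed_one = fixed_one,
       n_out = length(spec$outcomes), n_endo = length(endo_lat),
       n_ctl = length(spec$controls),
       n_par = length(a_rows) + length(s_idx),
       par_names = c(a_names, s_names))
}

ml_matrices <- function(theta, ly) {
  A <- matrix(0, ly$m, ly$m)
  A[cbind(ly$a_rows, ly$a_cols)] <- theta[seq_len(ly$n_a)]
  s <- numeric(ly$m)
  s[ly$s_idx] <- exp(theta[-seq_len(ly$n_a)])
  s[ly$fixed_one] <- 1
  E <- solve(diag(ly$m) - A)
  Sig_all <- E %*% (s * t(E))
  list(A = A, s = s, E = E, Sig_all = Sig_all,
       Sigma = Sig_all[ly$obs, ly$obs])
}

ml_objective <- function(theta, ly, S, ldS) {
  mm <- ml_matrices(theta, ly)
  ch <- tryCatch(chol(mm$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ld <- 2 * sum(log(diag(ch)))
  ld + sum(S * chol2inv(ch)) - ldS - nrow(S)
}

ml_gradient <- function(theta, ly, S, ldS) {
  mm <- ml_matrices(theta, ly)
  ch <- tryCatch(chol(mm$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(numeric(ly$n_par))
  Si <- chol2inv(ch)
  W <- Si - Si %*% S %*% Si
  Eo <- mm$E[ly$obs, , drop = FALSE]
  So <- mm$Sig_all[ly$obs, , drop = FALSE]
  P <- crossprod(Eo, W %*% So)
  Q <- crossprod(Eo, W %*% Eo)
  c(2 * P[cbind(ly$a_rows, ly$a_cols)],
    mm$s[ly$s_idx] * diag(Q)[ly$s_idx])
}

# expected information of theta at the optimum (per F_ML scaled by
# (n-1)/2, i.e. the information of the chi-square statistic / (n-1))
ml_information <- function(theta, ly, S, n) {
  mm <- ml_matrices(theta, ly)
  Si <- chol2inv(chol(mm$Sigma))
  Eo <- mm$E[ly$obs, , drop = FALSE]
  So <- mm$Sig_all[ly$obs, , drop = FALSE]
  # dSigma_k = u_k v_k' + v_k u_k'
  U <- cbind(Eo[, ly$a_rows, drop = FALSE],
             Eo[, ly$s_idx, drop = FALSE])
  Vv <- cbind(So[, ly$a_cols, drop = FALSE],
              Eo[, ly$s_idx, drop = FALSE] *
                rep(mm$s[ly$s_idx] / 2, each = nrow(Eo)))
  Gu <- crossprod(U, Si %*% U)
  Gv <- crossprod(Vv, Si %*% Vv)
  Guv <- crossprod(U, Si %*% Vv)
  (n - 1) * (Gu * Gv + Guv * t(Guv))
}

# neutral start: moderate loadings, small positive paths, residual
# variances half the (standardized) total, unit latent/control variances
ml_start_default <- function(ly) {
  c(rep(0.7, ly$mi$q), rep(0.1, ly$n_a - ly$mi$q),
    log(c(rep(0.5, ly$mi$q + ly$n_out), rep(1, ly$n_ctl))))
}

# Map a standardized parameter_set (e.g. the generating truth) onto the
# unit-disturbance ML coordinates for a warm start: each latent is
# rescaled by the square root of its disturbance variance.
ml_start_from_params <- function(ly, spec, params) {
  mi <- ly$mi
  cfac <- sqrt(params$latent_disturbances[mi$lat])  # eta' = eta / cfac
  scale_of <- c(cfac, setNames(rep(1, length(spec$controls) +
                                     length(spec$outcomes)),
                               c(spec$controls, spec$outcomes)))
  lam <- params$loadings[mi$ind] * cfac[obsem_indicator_latent(spec)]
  src <- sub(" ->.*", "", mi$labels)
  tgt <- sub(".*-> ", "", mi$labels)
  b <- params$structural[mi$labels] * scale_of[src] / scale_of[tgt]
  v <- c(params$residual_variances[mi$ind],
         params$residual_variances[spec$outcomes],
         params$control_variances[spec$controls])
  c(unname(lam), unname(b), log(unname(v)))
}

obsem_indicator_latent <- function(spec)
  rep(names(spec$latents), lengths(spec$latents))

ml_backend <- function(sd, spec, n_starts = 3, start = NULL,
                       start_seed = 1, moments = NULL, ...) {
  ly <- ml_layout(spec)
  if (is.null(moments)) {
    S <- cov(sd$X)
    n <- sd$n
  } else {
    S <- moments$cov
    n <- moments$n
  }
  p <- nrow(S)
  chS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance matrix is not positive definite"))
  ldS <- 2 * sum(log(diag(chS)))

  base <- if (inherits(start, "parameter_set"))
    ml_start_from_params(ly, spec, start)
  else if (is.numeric(start)) start
  else ml_start_default(ly)
  starts <- list(base)
  if (n_starts > 1) {
    # jittered starts from a private RNG stream so a fit is a
    # deterministic function of (data, spec, start_seed)
    rs <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(start_seed)
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- base + c(rnorm(ly$n_a, 0, 0.2),
                                  rnorm(ly$n_par - ly$n_a, 0, 0.2))
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  }

  best <- NULL
  for (s0 in starts) {
    opt <- nlminb(s0, ml_objective, gradient = ml_gradient,
                  ly = ly, S = S, ldS = ldS,
                  control = list(iter.max = 500, eval.max = 1000))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  converged <- best$convergence == 0
  theta <- best$par

  # sign identification
  theta <- ml_fix_signs(theta, ly)

  disc <- max(0, ml_objective(theta, ly, S, ldS))
  chisq <- (n - 1) * disc
  df <- p * (p + 1) / 2 - ly$n_par

  info <- ml_information(theta, ly, S, n)
  vcov_raw <- tryCatch(solve(info), error = function(e) MASS::ginv(info))

  std <- ml_std(theta, ly, spec)
  # delta method for standardized-solution SEs
  J <- matrix(0, length(std), ly$n_par)
  h <- 1e-5
  for (k in seq_len(ly$n_par)) {
    tp <- tm <- theta
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    J[, k] <- (ml_std(tp, ly, spec) - ml_std(tm, ly, spec)) / (2 * h)
  }
  vstd <- J %*% vcov_raw %*% t(J)
  se <- setNames(sqrt(pmax(diag(vstd), 0)), names(std))

  raw <- setNames(c(theta[seq_len(ly$n_a)],
                    exp(theta[-seq_len(ly$n_a)])), ly$par_names)
  list(estimates = std, se = se, raw_estimates = raw,
       discrepancy = disc, chisq = chisq, df = df, df_model = df,
       sample_cov = S, converged = converged,
       implied = ml_matrices(theta, ly)$Sigma,
       vcov_std = vstd, vcov_raw = vcov_raw, n_free = ly$n_par)
}

ml_fix_signs <- function(theta, ly) {
  mi <- ly$mi
  lam <- theta[seq_len(mi$q)]
  first <- match(mi$first_ind, mi$ind)
  for (l in seq_len(mi$nl)) {
    if (lam[first[l]] < 0) {
      lname <- mi$lat[l]
      lam_idx <- which(mi$lat_of == l)
      theta[lam_idx] <- -theta[lam_idx]
      pth <- mi$q + seq_along(mi$labels)
      src <- sub(" ->.*", "", mi$labels)
      tgt <- sub(".*-> ", "", mi$labels)
      flip <- xor(src == lname, tgt == lname)
      theta[pth][flip] <- -theta[pth][flip]
      lam <- theta[seq_len(mi$q)]
    }
  }
  theta
}

# standardized solution from an ML parameter vector
ml_std <- function(theta, ly, spec) {
  mi <- ly$mi
  lam <- setNames(theta[seq_len(mi$q)], mi$ind)
  b <- setNames(theta[mi$q + seq_along(mi$labels)], mi$labels)
  v <- exp(theta[-seq_len(ly$n_a)])
  names(v) <- sub("^v_", "", ly$s_names)
  lat_var <- setNames(rep(1, mi$nl), mi$lat)  # unit disturbances
  std_solution(spec, lam, b,
               psi_ind = v[mi$ind],
               psi_out = v[spec$outcomes],
               lat_var = lat_var,
               ctl_var = v[spec$controls])
}

#' Fit the SEM by maximum likelihood from moment input
#'
#' Runs the ML estimator directly on a covariance matrix instead of raw
#' data -- useful for population-level checks (fitting the model to its
#' own implied covariance must give zero discrepancy) and for re-analyses
#' where only moments are available.  No predictions are possible from
#' moment input.
#'
#' @param S covariance matrix over the observed variables of `spec`, in
#'   the specification's variable order (dimnames are checked when
#'   present).
#' @param n nominal sample size used for the chi-square scaling.
#' @param spec a [sem_spec].
#' @param ... passed to the ML backend (`n_starts`, `start`).
#' @return An `mlsem_fit` (see [sem_fit()]) without data-dependent
#'   components.
#' @export
sem_fit_moments <- function(S, n, spec = obesity_model(), ...) {
  obs <- spec_observed(spec)
  if (!is.null(dimnames(S))) {
    stopifnot(all(obs %in% colnames(S)))
    S <- S[obs, obs]
  } else stopifnot(nrow(S) == length(obs))
  fit <- ml_backend(sd = NULL, spec = spec, moments = list(cov = S, n = n),
                    ...)
  fit$spec <- spec
  fit$method <- "ml"
  fit$n <- n
  lbl <- path_labels(spec)
  fit$structural <- data.frame(path = lbl,
                               estimate = unname(fit$estimates[lbl]),
                               se = unname(fit$se[lbl]),
                               stringsAsFactors = FALSE)
  class(fit) <- c("mlsem_fit", "sem_fit")
  fit
}
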