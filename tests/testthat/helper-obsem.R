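# shared fixtures built in code

# short MCMC settings for unit tests; long chains are exercised by the
# calibration suites
quick_mcmc <- function(seed = 1, n_iterations = 800, burn_in = 300,
                       n_chains = 1)
  mcmc_config(n_iterations, burn_in, thin = 1, n_chains = n_chains,
              seed = seed)

# k centered columns with exact pairwise sample correlations:
# orthonormal basis from orthogonal polynomials, mixed by chol(R)
items_with_cor <- function(R, n = 60) {
  k <- nrow(R)
  U <- stats::poly(seq_len(n), k)        # orthonormal, centered
  X <- U %*% chol(R)
  colnames(X) <- paste0("item", seq_len(k))
  X * sqrt(n - 1)                        # unit sample variance
}

# a parameter set with all structural coefficients zero
zero_path_params <- function(spec = obesity_model()) {
  lbl <- paste(spec$paths$source, "->", spec$paths$target)
  standardized_params(spec,
                      loadings = true_params("girl", spec)$loadings,
                      structural = setNames(rep(0, length(lbl)), lbl))
}

# near-noise-free variant of the girl model: indicators almost perfectly
# reliable, outcomes almost deterministic given latents and controls
noisefree_params <- function(spec = obesity_model(), ind_res = 0.02,
                             out_res = 1e-4) {
  p <- true_params("girl", spec)
  ind <- unlist(spec$latents, use.names = FALSE)
  rv <- p$residual_variances
  rv[ind] <- ind_res
  lo <- p$loadings
  lo[] <- sqrt(1 - ind_res)
  parameter_set(spec, loadings = lo, structural = p$structural,
                residual_variances = c(rv[ind],
                                       setNames(rep(out_res,
                                                    length(spec$outcomes)),
                                                spec$outcomes)),
                latent_disturbances = p$latent_disturbances,
                control_variances = p$control_variances)
}

# small two-construct spec with single-indicator latents (degenerate PLS)
single_indicator_spec <- function() {
  sem_spec(latents = list(f1 = "x1", f2 = "x2"),
           outcomes = "y",
           controls = character(0),
           paths = data.frame(source = c("f1", "f2", "f1"),
                              target = c("y", "y", "f2"),
                              role = "structural",
                              stringsAsFactors = FALSE))
}
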