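#' MCMC settings for the Gibbs sampler
#'
#' @param n_iterations sweeps per chain (default 10000).
#' @param burn_in sweeps discarded from the start of each chain
#'   (default 5000; must be smaller than `n_iterations`).
#' @param thin keep every `thin`-th retained sweep (default 1).
#' @param n_chains number of independent chains (default 2).
#' @param seed integer seed; chain `k` is seeded deterministically from
#'   it, so identical configurations give identical chains.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 10000, burn_in = 5000, thin = 1,
                        n_chains = 2, seed = 1) {
  stopifnot(n_iterations >= 2, burn_in >= 0, burn_in < n_iterations,
            thin >= 1, n_chains >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "mcmc_config")
}

# Gibbs sampler backend.  Sampling parameterization: latent disturbances
# fixed at 1 (which sets each construct's scale), loadings and structural
# coefficients free with conjugate normal priors, indicator/outcome
# residual variances with conjugate inverse-gamma priors.  Each retained
# sweep is mapped to the fully standardized solution, so the reported
# draws are on the same scale for every prior regime.
gibbs_backend <- function(sd, spec, prior, mcmc) {
  stopifnot(inherits(prior, "prior_config"), inherits(mcmc, "mcmc_config"))
  mi <- model_index(spec)
  X <- sd$X
  n <- sd$n
  Xi <- X[, mi$ind, drop = FALSE]
  Xc <- X[, spec$controls, drop = FALSE]
  Xo <- X[, spec$outcomes, drop = FALSE]
  q <- mi$q; nl <- mi$nl
  no <- length(spec$outcomes)
  v0 <- prior$prior_variance
  a0 <- prior$variance_shape; b0 <- prior$variance_rate
  # per-equation prior means/variances in equation order
  eq_prior <- lapply(mi$eqs, function(eq) {
    m0 <- ifelse(eq$labels %in% names(prior$path_means),
                 prior$path_means[eq$labels], 0)
    vv <- ifelse(eq$labels %in% names(prior$path_variances),
                 prior$path_variances[eq$labels], v0)
    list(m0 = unname(m0), v0 = unname(vv))
  })
  ctl_var <- setNames(rep(1, length(spec$controls)), spec$controls)
  lat_var1 <- setNames(rep(1, nl), mi$lat)   # unit disturbances

  n_keep <- (mcmc$n_iterations - mcmc$burn_in) %/% mcmc$thin
  par_names <- c(mi$ind, mi$labels,
                 paste0("r2_", spec$outcomes))
  raw_names <- c(mi$ind, mi$labels,
                 paste0("psi_", c(mi$ind, spec$outcomes)))
  chains_std <- chains_raw <- vector("list", mcmc$n_chains)

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 7919L * (ch - 1L))
    lambda <- setNames(rep(0.7, q), mi$ind)
    psi_i <- setNames(rep(0.5, q), mi$ind)
    psi_o <- setNames(rep(0.5, no), spec$outcomes)
    coefs <- lapply(mi$eqs, function(eq)
      setNames(rep(0, length(eq$sources)), eq$sources))
    names(coefs) <- vapply(mi$eqs, `[[`, "", "target")
    draws_std <- matrix(NA_real_, n_keep, length(par_names),
                        dimnames = list(NULL, par_names))
    draws_raw <- matrix(NA_real_, n_keep, length(raw_names),
                        dimnames = list(NULL, raw_names))
    kept <- 0L

    for (it in seq_len(mcmc$n_iterations)) {
      ## (a) latent scores | parameters: exact Gaussian conditional
      sc <- structural_pieces(spec, mi, coefs)
      Lam <- matrix(0, q, nl, dimnames = list(mi$ind, mi$lat))
      Lam[cbind(seq_len(q), mi$lat_of)] <- lambda
      Lmat <- rbind(Lam, sc$Gamma_lat)
      dres <- c(psi_i, psi_o)
      Ystar <- cbind(Xi, Xo - Xc %*% t(sc$Gamma_ctl))
      LS <- Lmat %*% sc$Seta
      M <- LS %*% t(Lmat)
      diag(M) <- diag(M) + dres
      A <- t(solve(M, LS))                     # nl x (q+no)
      V <- sc$Seta - A %*% LS
      V <- (V + t(V)) / 2
      eta <- Ystar %*% t(A) +
        matrix(rnorm(n * nl), n) %*% chol(V)
      colnames(eta) <- mi$lat

      ## (b1) loadings | scores (conjugate normal)
      css <- colSums(eta^2)
      etaX <- crossprod(eta, Xi)               # nl x q
      prec <- css[mi$lat_of] / psi_i + 1 / v0
      mu <- (etaX[cbind(mi$lat_of, seq_len(q))] / psi_i +
               prior$loading_mean / v0) / prec
      lambda <- setNames(rnorm(q, mu, sqrt(1 / prec)), mi$ind)

      ## (c1) indicator residual variances (conjugate inverse-gamma)
      res <- Xi - eta[, mi$lat_of, drop = FALSE] * rep(lambda, each = n)
      ssr <- colSums(res^2)
      psi_i <- setNames(1 / rgamma(q, a0 + n / 2, rate = b0 + ssr / 2),
                        mi$ind)

      ## (b2) structural coefficients equation by equation
      for (k in seq_along(mi$eqs)) {
        eq <- mi$eqs[[k]]
        W <- cbind(eta, Xc)[, eq$sources, drop = FALSE]
        y <- if (eq$is_latent) eta[, eq$target] else Xo[, eq$target]
        s2 <- if (eq$is_latent) 1 else psi_o[eq$target]
        P0 <- diag(1 / eq_prior[[k]]$v0, length(eq$sources))
        Prec <- crossprod(W) / s2 + P0
        Vp <- chol2inv(chol(Prec))
        mpost <- Vp %*% (crossprod(W, y) / s2 +
                           eq_prior[[k]]$m0 / eq_prior[[k]]$v0)
        coefs[[eq$target]][] <- drop(mpost) +
          drop(rnorm(length(eq$sources)) %*% chol(Vp))
        if (!eq$is_latent) {
          ## (c2) outcome residual variance
          r <- y - W %*% coefs[[eq$target]]
          psi_o[eq$target] <-
            1 / rgamma(1, a0 + n / 2, rate = b0 + sum(r^2) / 2)
        }
      }

      ## sign identification: first loading of each construct positive
      for (l in seq_len(nl)) {
        if (lambda[mi$first_ind[l]] < 0) {
          lname <- mi$lat[l]
          idx <- mi$lat_of == l
          lambda[idx] <- -lambda[idx]
          eta[, l] <- -eta[, l]
          for (tg in names(coefs)) {
            if (tg == lname) coefs[[tg]][] <- -coefs[[tg]]
            hit <- names(coefs[[tg]]) == lname
            coefs[[tg]][hit] <- -coefs[[tg]][hit]
          }
        }
      }

      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
        kept <- kept + 1L
        structural <- flatten_coefs(mi, coefs)
        draws_std[kept, ] <- std_solution(
          spec, lambda, structural, psi_i, psi_o, lat_var1, ctl_var)
        draws_raw[kept, ] <- c(lambda, structural, psi_i, psi_o)
      }
    }
    if (anyNA(draws_std) || any(!is.finite(draws_std))) {
      bad <- par_names[which(colSums(!is.finite(draws_std)) > 0)[1]]
      stop("non-finite posterior draw for '", bad,
           "'; the data may be degenerate")
    }
    chains_std[[ch]] <- draws_std
    chains_raw[[ch]] <- draws_raw
  }

  all_std <- do.call(rbind, chains_std)
  all_raw <- do.call(rbind, chains_raw)
  est <- colMeans(all_std)
  se <- apply(all_std, 2, pop_sd)
  raw_est <- colMeans(all_raw)
  list(estimates = est, se = se,
       draws = chains_std, draws_raw = chains_raw,
       raw_estimates = raw_est,
       prior = prior, mcmc = mcmc,
       diagnostics = data.frame(parameter = par_names,
                                rhat = split_rhat(chains_std),
                                row.names = NULL))
}

# posterior SD with the population (divide-by-N) convention
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# latent-block covariance and outcome coefficient matrices for the
# current structural state (unit latent disturbances)
structural_pieces <- function(spec, mi, coefs) {
  nl <- mi$nl
  B <- matrix(0, nl, nl, dimnames = list(mi$lat, mi$lat))
  no <- length(spec$outcomes)
  Gamma_lat <- matrix(0, no, nl, dimnames = list(spec$outcomes, mi$lat))
  Gamma_ctl <- matrix(0, no, length(spec$controls),
                      dimnames = list(spec$outcomes, spec$controls))
  for (tg in names(coefs)) {
    b <- coefs[[tg]]
    if (tg %in% mi$lat) {
      B[tg, names(b)] <- b
    } else {
      latb <- names(b) %in% mi$lat
      Gamma_lat[tg, names(b)[latb]] <- b[latb]
      Gamma_ctl[tg, names(b)[!latb]] <- b[!latb]
    }
  }
  E <- solve(diag(nl) - B)
  list(B = B, Seta = tcrossprod(E), Gamma_lat = Gamma_lat,
       Gamma_ctl = Gamma_ctl)
}

flatten_coefs <- function(mi, coefs) {
  out <- setNames(numeric(length(mi$labels)), mi$labels)
  for (tg in names(coefs))
    out[paste(names(coefs[[tg]]), "->", tg)] <- coefs[[tg]]
  out
}

#' Split-half R-hat convergence diagnostic
#'
#' Splits every chain in half and computes the potential scale reduction
#' factor over the resulting half-chains; values near 1 indicate that the
#' chains have mixed.
#'
#' @param chains a list of draw matrices (one per chain, common columns),
#'   or a `bsem_fit`.
#' @return Named vector of R-hat values, one per parameter (`NA` for a
#'   parameter with zero variance).
#' @export
split_rhat <- function(chains) {
  if (inherits(chains, "bsem_fit")) chains <- chains$draws
  halves <- unlist(lapply(chains, function(m) {
    h <- nrow(m) %/% 2
    list(m[seq_len(h), , drop = FALSE],
         m[(h + 1):(2 * h), , drop = FALSE])
  }), recursive = FALSE)
  nh <- length(halves)
  nd <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)             # P x nh
  vars <- sapply(halves, function(m) apply(m, 2, var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  B <- nd * apply(means, 1, var)
  Wv <- rowMeans(vars)
  out <- sqrt(((nd - 1) / nd * Wv + B / nd) / Wv)
  out[Wv == 0] <- NA_real_
  setNames(out, colnames(halves[[1]]))
}

#' Posterior summary table
#'
#' One row per monitored parameter: posterior mean, posterior standard
#' deviation (population convention, divide by the number of draws),
#' 95% equal-tailed credible interval and split-half R-hat.
#'
#' @param fit a `bsem_fit` from [sem_fit()].
#' @param prob credible-interval mass (default 0.95).
#' @return A data frame with columns `parameter`, `estimate`, `se`,
#'   `lower`, `upper`, `rhat`.
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "bsem_fit"))
  draws <- do.call(rbind, fit$draws)
  if (nrow(draws) < 2) stop("need at least 2 retained draws")
  a <- (1 - prob) / 2
  data.frame(parameter = colnames(draws),
             estimate = colMeans(draws),
             se = apply(draws, 2, pop_sd),
             lower = apply(draws, 2, quantile, probs = a),
             upper = apply(draws, 2, quantile, probs = 1 - a),
             rhat = split_rhat(fit$draws),
             row.names = NULL)
}
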