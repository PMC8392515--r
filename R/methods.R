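#' @export
print.sem_fit <- function(x, ...) {
  cat("Structural equation model fit (", toupper(x$method), "), n = ",
      x$n, "\n", sep = "")
  tab <- x$structural
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  print(tab, row.names = FALSE)
  r2 <- x$estimates[grep("^r2_", names(x$estimates))]
  if (length(r2))
    cat("R-squared:", paste(sprintf("%s = %.2f", sub("^r2_", "", names(r2)),
                                    r2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sem_fit <- function(object, ...) {
  out <- list(method = object$method, n = object$n,
              structural = object$structural,
              loadings = coef(object, "loadings"))
  if (inherits(object, "bsem_fit")) {
    out$posterior <- posterior_summary(object)
    out$max_rhat <- max(object$diagnostics$rhat, na.rm = TRUE)
  }
  if (inherits(object, "mlsem_fit")) {
    out$chisq <- object$chisq; out$df <- object$df
    out$discrepancy <- object$discrepancy
    out$converged <- object$converged
  }
  if (inherits(object, "plssem_fit")) {
    out$converged <- object$converged
    out$iterations <- object$iterations
  }
  class(out) <- "summary.sem_fit"
  out
}

#' @export
print.summary.sem_fit <- function(x, ...) {
  cat("SEM fit summary --", toupper(x$method), "estimator, n =", x$n, "\n\n")
  cat("Structural paths (standardized):\n")
  tab <- x$structural
  tab$z <- tab$estimate / tab$se
  print(cbind(tab[1], round(tab[-1], 3)), row.names = FALSE)
  cat("\nLoadings (standardized):\n")
  print(round(x$loadings, 3))
  if (!is.null(x$chisq))
    cat(sprintf("\nchisq = %.3f on %d df (discrepancy %.5f)\n",
                x$chisq, x$df, x$discrepancy))
  if (!is.null(x$max_rhat))
    cat(sprintf("\nmax split R-hat = %.3f\n", x$max_rhat))
  invisible(x)
}

#' Extract standardized coefficients from an SEM fit
#'
#' @param object a fit from [sem_fit()].
#' @param type `"structural"` (path coefficients, the default),
#'   `"loadings"`, `"r2"` or `"all"`.
#' @param ... unused.
#' @return Named numeric vector of standardized estimates.
#' @export
coef.sem_fit <- function(object, type = c("structural", "loadings",
                                          "r2", "all"), ...) {
  type <- match.arg(type)
  est <- object$estimates
  spec <- object$spec
  switch(type,
         structural = est[path_labels(spec)],
         loadings = est[spec_indicators(spec)],
         r2 = est[paste0("r2_", spec$outcomes)],
         all = est)
}

# rebuild a raw-scale parameter_set from a fitted object (for scoring,
# prediction and simulation)
fitted_params <- function(fit) {
  spec <- fit$spec
  mi <- model_index(spec)
  if (inherits(fit, "plssem_fit"))
    stop("internal: PLS has no model-based parameter set")
  raw <- fit$raw_estimates
  if (inherits(fit, "bsem_fit")) {
    parameter_set(spec,
                  loadings = raw[mi$ind],
                  structural = raw[mi$labels],
                  residual_variances = setNames(
                    raw[paste0("psi_", c(mi$ind, spec$outcomes))],
                    c(mi$ind, spec$outcomes)),
                  latent_disturbances = setNames(rep(1, mi$nl), mi$lat))
  } else {
    v <- raw[grep("^v_", names(raw))]
    names(v) <- sub("^v_", "", names(v))
    parameter_set(spec,
                  loadings = raw[mi$ind],
                  structural = raw[mi$labels],
                  residual_variances = setNames(
                    pmax(v[c(mi$ind, spec$outcomes)], 0),
                    c(mi$ind, spec$outcomes)),
                  latent_disturbances = setNames(rep(1, mi$nl), mi$lat),
                  control_variances = setNames(v[spec$controls],
                                               spec$controls))
  }
}

#' Predict outcomes from a fitted SEM
#'
#' For the Bayesian and ML fits, latent factor scores are computed by the
#' regression method from the (standardized) indicator block and the
#' estimated structural equations for the outcomes are applied to scores
#' and controls; for PLS the native outer-weight scores are used.
#' Predictions are returned in the original units of the training data.
#'
#' @param object a fit from [sem_fit()].
#' @param newdata data frame with the indicator and control columns; the
#'   training data when omitted.
#' @param ... unused.
#' @return Numeric matrix, one row per observation, one column per
#'   outcome.
#' @export
predict.sem_fit <- function(object, newdata = NULL, ...) {
  spec <- object$spec
  need <- c(spec_indicators(spec), spec$controls)
  if (is.null(newdata)) {
    Xs <- object$data_std[, need, drop = FALSE]
  } else {
    miss <- setdiff(need, names(newdata))
    if (length(miss))
      stop("newdata lack model variable(s): ", paste(miss, collapse = ", "))
    Xs <- scale(as.matrix(newdata[, need, drop = FALSE]),
                center = object$scaling$center[need],
                scale = object$scaling$scale[need])
  }
  ctr <- object$scaling$center[spec$outcomes]
  scl <- object$scaling$scale[spec$outcomes]
  if (inherits(object, "plssem_fit")) {
    P <- pls_predict_std(object, Xs)
  } else {
    P <- predict_outcomes(spec, fitted_params(object),
                          as.data.frame(Xs))
  }
  sweep(sweep(P, 2, scl, `*`), 2, ctr, `+`)
}

pls_predict_std <- function(object, Xs) {
  spec <- object$spec
  mi <- model_index(object$spec)
  sc_names <- setdiff(names(object$score_center), spec$outcomes)
  scores <- matrix(0, nrow(Xs), length(sc_names),
                   dimnames = list(NULL, sc_names))
  for (b in sc_names) {
    v <- if (b %in% names(spec$latents)) spec$latents[[b]] else b
    w <- if (b %in% names(spec$latents)) object$outer_weights[[b]] else 1
    scores[, b] <- (Xs[, v, drop = FALSE] %*% w -
                      object$score_center[b]) / object$score_scale[b]
  }
  P <- matrix(0, nrow(Xs), length(spec$outcomes),
              dimnames = list(NULL, spec$outcomes))
  for (o in spec$outcomes) {
    rows <- spec$paths$target == o
    b <- object$estimates[path_labels(spec)[rows]]
    P[, o] <- scores[, spec$paths$source[rows], drop = FALSE] %*% b
    # path coefficients act on the outcome's score scale
    P[, o] <- P[, o] * object$score_scale[o] + object$score_center[o]
  }
  P
}

#' @export
residuals.sem_fit <- function(object, ...) {
  obs <- sweep(sweep(object$data_std[, object$spec$outcomes, drop = FALSE],
                     2, object$scaling$scale[object$spec$outcomes], `*`),
               2, object$scaling$center[object$spec$outcomes], `+`)
  obs - predict(object)
}

#' Simulate new datasets from a fitted model
#'
#' Draws datasets from the fully standardized fitted solution (a
#' parametric-bootstrap generator).  Not available for PLS, which has no
#' generative model.
#'
#' @param object a `bsem_fit` or `mlsem_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n rows per dataset (training sample size by default).
#' @param ... unused.
#' @return A list of `nsim` data frames (a single data frame if
#'   `nsim = 1`).
#' @export
simulate.sem_fit <- function(object, nsim = 1, seed = 1, n = object$n,
                             ...) {
  if (inherits(object, "plssem_fit"))
    stop("simulate() is not available for a PLS fit")
  spec <- object$spec
  params <- standardized_params(
    spec,
    loadings = coef(object, "loadings"),
    structural = coef(object, "structural"))
  out <- lapply(seq_len(nsim), function(k)
    simulate_group(spec, params, n,
                   seed = (as.integer(seed) + k - 1L) %% 2147483647L))
  if (nsim == 1) out[[1]] else out
}

#' Plot an SEM fit
#'
#' The default plot is a dot chart of the standardized structural
#' coefficients with approximate 95% intervals; for a Bayesian fit,
#' `type = "trace"` instead draws trace plots of the structural
#' coefficients' posterior chains.
#'
#' @param x a fit from [sem_fit()].
#' @param type `"coef"` or `"trace"`.
#' @param pars parameter names for trace plots (default: all structural
#'   paths).
#' @param ... passed to the underlying graphics calls.
#' @export
plot.sem_fit <- function(x, type = c("coef", "trace"), pars = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    if (!inherits(x, "bsem_fit"))
      stop("trace plots require a Bayesian fit")
    pars <- pars %||% path_labels(x$spec)
    old <- graphics::par(mfrow = c(min(4, length(pars)), 1),
                         mar = c(2, 4, 1, 1))
    on.exit(graphics::par(old))
    for (p in pars[seq_len(min(4, length(pars)))]) {
      graphics::matplot(sapply(x$draws, function(m) m[, p]), type = "l",
                        lty = 1, ylab = p, xlab = "", ...)
    }
  } else {
    tab <- x$structural
    ord <- rev(seq_len(nrow(tab)))
    graphics::dotchart(tab$estimate[ord], labels = tab$path[ord],
                       xlab = "standardized coefficient", ...)
    if (!all(is.na(tab$se))) {
      graphics::segments(tab$estimate[ord] - 1.96 * tab$se[ord], ord,
                         tab$estimate[ord] + 1.96 * tab$se[ord], ord)
    }
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes a common schema for all three estimators: the estimator tag,
#' sample size, standardized estimates, uncertainties and convergence
#' information.
#'
#' @param fit a fit from [sem_fit()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sem_fit_json <- function(fit, path) {
  out <- list(estimator = fit$method, n = fit$n,
              estimates = as.list(fit$estimates),
              se = as.list(fit$se),
              structural = fit$structural)
  if (!is.null(fit$chisq)) {
    out$chisq <- fit$chisq; out$df <- fit$df
    out$discrepancy <- fit$discrepancy
  }
  if (!is.null(fit$converged)) out$converged <- fit$converged
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
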