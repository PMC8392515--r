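#' SEM fit indices
#'
#' Computes the six conventional indices from the model and baseline
#' (independence) chi-squares:
#' NFI = (chisq_b - chisq_m)/chisq_b;
#' IFI = (chisq_b - chisq_m)/(chisq_b - df_m);
#' RFI = (chisq_b/df_b - chisq_m/df_m)/(chisq_b/df_b);
#' TLI = (chisq_b/df_b - chisq_m/df_m)/(chisq_b/df_b - 1);
#' CFI = 1 - max(chisq_m - df_m, 0)/max(chisq_b - df_b, chisq_m - df_m, 0);
#' and GFI from the ML trace form
#' `1 - tr((solve(implied) %*% sample - I)^2) / tr((solve(implied) %*% sample)^2)`
#' when the two covariance matrices are supplied.
#'
#' @param chisq_model,df_model model chi-square and degrees of freedom.
#' @param chisq_baseline,df_baseline independence-model chi-square and
#'   degrees of freedom.
#' @param sample_cov,implied_cov optional covariance matrices for GFI.
#' @param n optional sample size (recorded in the report).
#' @return A `fit_index_report`: list of gfi, nfi, ifi, rfi, tli, cfi and
#'   the inputs.  With a zero baseline chi-square the incremental indices
#'   are undefined and returned as `NA` with a message.
#' @examples
#' fit_indices(20, 8, 100, 10)$nfi   # 0.8
#' @export
fit_indices <- function(chisq_model, df_model, chisq_baseline, df_baseline,
                        sample_cov = NULL, implied_cov = NULL, n = NULL) {
  stopifnot(chisq_model >= 0, chisq_baseline >= 0, df_baseline > 0,
            df_model > 0)
  if (chisq_baseline == 0) {
    message("baseline chi-square is zero: incremental indices undefined")
    nfi <- ifi <- rfi <- tli <- cfi <- NA_real_
  } else {
    nfi <- (chisq_baseline - chisq_model) / chisq_baseline
    ifi <- (chisq_baseline - chisq_model) / (chisq_baseline - df_model)
    rb <- chisq_baseline / df_baseline
    rm_ <- chisq_model / df_model
    rfi <- (rb - rm_) / rb
    tli <- (rb - rm_) / (rb - 1)
    num <- max(chisq_model - df_model, 0)
    den <- max(chisq_baseline - df_baseline, chisq_model - df_model, 0)
    cfi <- if (den == 0) 1 else 1 - num / den
  }
  gfi <- NA_real_
  if (!is.null(sample_cov) && !is.null(implied_cov)) {
    M <- solve(implied_cov, sample_cov)
    gfi <- 1 - sum(diag((M - diag(nrow(M))) %*% (M - diag(nrow(M))))) /
      sum(diag(M %*% M))
  }
  structure(list(gfi = gfi, nfi = nfi, ifi = ifi, rfi = rfi, tli = tli,
                 cfi = cfi, chisq_model = chisq_model, df_model = df_model,
                 chisq_baseline = chisq_baseline,
                 df_baseline = df_baseline, n = n),
            class = "fit_index_report")
}

#' @export
print.fit_index_report <- function(x, ...) {
  v <- unlist(x[c("gfi", "nfi", "ifi", "rfi", "tli", "cfi")])
  cat("Fit indices:\n")
  print(round(v, 3))
  cat(sprintf("model chisq %.2f (df %d) | baseline chisq %.2f (df %d)\n",
              x$chisq_model, x$df_model, x$chisq_baseline, x$df_baseline))
  invisible(x)
}

#' Fit indices for a fitted ML model
#'
#' Derives the baseline (independence) chi-square from the stored sample
#' covariance -- the independence model fits only the variances, so its
#' ML discrepancy is `-log det` of the sample correlation matrix -- and
#' calls [fit_indices()].
#'
#' @param fit an `mlsem_fit` from [sem_fit()].
#' @return A `fit_index_report`.
#' @export
model_fit_indices <- function(fit) {
  stopifnot(inherits(fit, "mlsem_fit"))
  S <- fit$sample_cov
  p <- nrow(S)
  f_base <- -determinant(stats::cov2cor(S), logarithm = TRUE)$modulus
  chisq_b <- (fit$n - 1) * as.numeric(f_base)
  df_b <- p * (p - 1) / 2
  fit_indices(fit$chisq, fit$df, chisq_b, df_b,
              sample_cov = S, implied_cov = fit$implied, n = fit$n)
}

#' Predictive accuracy metrics
#'
#' Compares observed and predicted outcome values: `r2` is the squared
#' Pearson correlation; `rmse` the root-mean-squared error; `mape` the
#' mean absolute percentage error (requires all observed values to be
#' non-zero); `mae` the mean absolute error (`mse_printed` is an alias
#' kept for comparison tables that label the mean absolute error "MSE");
#' `mse` the conventional mean squared error.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2).
#' @return A one-row data frame with columns `r2`, `rmse`, `mape`,
#'   `mse_printed`, `mae`, `mse`, `n`.  `r2` is `NA` (with a warning)
#'   for a constant series.
#' @examples
#' predictive_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
predictive_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (anyNA(observed) || anyNA(predicted)) stop("missing values")
  err <- predicted - observed
  if (any(observed == 0))
    stop("MAPE undefined: observed values contain zero")
  r2 <- if (sd(observed) == 0 || sd(predicted) == 0) {
    warning("constant series: r2 undefined")
    NA_real_
  } else cor(observed, predicted)^2
  mae <- mean(abs(err))
  data.frame(r2 = r2,
             rmse = sqrt(mean(err^2)),
             mape = mean(abs(err / observed)),
             mse_printed = mae, mae = mae,
             mse = mean(err^2),
             n = length(observed))
}

#' Compare the three estimators on one dataset
#'
#' Fits the Bayesian, ML and PLS estimators to the same data and reports
#' the predictive metrics of each on the stacked outcome predictions
#' (both outcomes appended into one observed/predicted pair of vectors).
#' A failing estimator gets a row of `NA`s flagged `failed` while the
#' others are still reported.
#'
#' @param data data frame of observed variables.
#' @param spec a [sem_spec].
#' @param prior,mcmc Bayesian settings (see [sem_fit()]).
#' @param methods estimators to include.
#' @return A data frame with one row per estimator: `estimator`, `r2`,
#'   `rmse`, `mape`, `mse_printed`, `mse`, `failed`.  Attribute `fits`
#'   holds the fitted objects.
#' @export
compare_estimators <- function(data, spec = obesity_model(),
                               prior = diffuse_prior(),
                               mcmc = mcmc_config(),
                               methods = c("ml", "pls", "bayes")) {
  rows <- list()
  fits <- list()
  for (m in methods) {
    res <- tryCatch({
      fit <- sem_fit(data, spec, method = m, prior = prior, mcmc = mcmc)
      P <- predict(fit)
      obs <- as.matrix(data[, spec$outcomes, drop = FALSE])
      met <- predictive_metrics(as.vector(obs), as.vector(P))
      fits[[m]] <- fit
      cbind(data.frame(estimator = m, stringsAsFactors = FALSE),
            met[, c("r2", "rmse", "mape", "mse_printed", "mse")],
            failed = FALSE)
    }, error = function(e) {
      warning("estimator '", m, "' failed: ", conditionMessage(e))
      data.frame(estimator = m, r2 = NA, rmse = NA, mape = NA,
                 mse_printed = NA, mse = NA, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    rows[[m]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
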