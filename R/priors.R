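#' Prior configuration for Bayesian SEM fitting
#'
#' Normal priors are placed on loadings and path coefficients and
#' inverse-gamma priors on residual variances; the Gibbs sampler exploits
#' their conjugacy.  `path_means` carries prior means for any subset of
#' structural/control paths (named as `"source -> target"`); paths not
#' listed get prior mean 0.  The latent-to-outcome hyperparameters of the
#' obesity model are conventionally called beta-1 ... beta-8 (in the order
#' SES, lifestyle, healthy, unhealthy, each to BMI then body fat).
#'
#' @param path_means named numeric vector of prior means for path
#'   coefficients (possibly empty).
#' @param loading_mean scalar prior mean for every factor loading
#'   (default 0.5).
#' @param prior_variance scalar prior variance for every loading and path
#'   coefficient (default 1, a mildly informative "small variance").
#' @param path_variances optional named numeric vector overriding
#'   `prior_variance` for individual paths (e.g. to pin a coefficient
#'   with a near-zero prior variance).
#' @param variance_shape,variance_rate shape and rate of the
#'   inverse-gamma prior on residual variances (default 0.01, 0.01 -- a
#'   conventional noninformative choice).
#' @return An object of class `prior_config`.
#' @seealso [type_i_prior()], [prior_regime()], [diffuse_prior()].
#' @export
prior_config <- function(path_means = numeric(0), loading_mean = 0.5,
                         prior_variance = 1, path_variances = numeric(0),
                         variance_shape = 0.01, variance_rate = 0.01) {
  stopifnot(prior_variance > 0, variance_shape > 0, variance_rate > 0)
  if (length(path_means) && is.null(names(path_means)))
    stop("path_means must be named by path label ('source -> target')")
  if (length(path_variances) &&
      (is.null(names(path_variances)) || any(path_variances <= 0)))
    stop("path_variances must be a named vector of positive variances")
  structure(list(path_means = path_means, loading_mean = loading_mean,
                 prior_variance = prior_variance,
                 path_variances = path_variances,
                 variance_shape = variance_shape,
                 variance_rate = variance_rate),
            class = "prior_config")
}

#' @export
print.prior_config <- function(x, ...) {
  cat("prior_config: loading mean", x$loading_mean,
      "| coefficient variance", x$prior_variance,
      "| IG(", x$variance_shape, ",", x$variance_rate, ") on variances\n")
  if (length(x$path_means)) {
    cat("path prior means:\n"); print(round(x$path_means, 3))
  }
  invisible(x)
}

# base (Type I) hyperparameter values for the 8 latent-to-outcome paths,
# per group; order: ses->bmi, ses->body_fat, lifestyle->bmi,
# lifestyle->body_fat, healthy->bmi, healthy->body_fat, unhealthy->bmi,
# unhealthy->body_fat
.type_i_means <- list(
  girl = c(0.4, 0.7, 0.3, 0.5, 0.7, 0.7, 0.6, 0.7),
  boy  = c(0.5, 0.4, 0.6, 0.6, 0.7, 0.7, 0.5, 0.6))

beta_path_labels <- function(spec = obesity_model()) {
  out <- spec$outcomes
  src <- names(spec$latents)
  as.vector(t(outer(src, out, function(s, o) paste(s, "->", o))))
}

#' Base (Type I) prior for the obesity model
#'
#' The Type I regime assigns the study's base hyperparameter values to the
#' eight latent-to-outcome path coefficients and 0.5 to every loading.
#' [prior_regime()] derives the Type II (halved) and Type III (doubled)
#' regimes from it for sensitivity analysis.
#'
#' @param group `"girl"` or `"boy"`: the two groups use different base
#'   hyperparameter values.
#' @param prior_variance see [prior_config()].
#' @return A [prior_config] with all eight path means populated.
#' @export
type_i_prior <- function(group = c("girl", "boy"), prior_variance = 1) {
  group <- match.arg(group)
  prior_config(path_means = setNames(.type_i_means[[group]],
                                     beta_path_labels()),
               loading_mean = 0.5, prior_variance = prior_variance)
}

#' Derive a prior-sensitivity regime from a base prior
#'
#' Regime `"I"` returns the base prior unchanged; `"II"` halves every path
#' prior mean; `"III"` doubles them.  Loading means are 0.5 in all
#' regimes.
#'
#' @param base a [prior_config] with its path means populated.
#' @param regime `"I"`, `"II"` or `"III"`.
#' @return A [prior_config].
#' @examples
#' b <- type_i_prior("girl")
#' prior_regime(b, "II")$path_means[1]  # half the base value
#' @export
prior_regime <- function(base, regime = c("I", "II", "III")) {
  stopifnot(inherits(base, "prior_config"))
  if (!is.character(regime) || !all(regime %in% c("I", "II", "III")))
    stop("unknown prior regime: ", paste(regime, collapse = ", "),
         " (expected 'I', 'II' or 'III')")
  regime <- match.arg(regime)
  mult <- c(I = 1, II = 0.5, III = 2)[[regime]]
  out <- base
  out$path_means <- base$path_means * mult
  out$loading_mean <- 0.5
  out
}

#' Diffuse prior
#'
#' Zero-mean normal priors with large variance on all coefficients --
#' posterior summaries are then dominated by the data and agree with
#' maximum likelihood in large samples.
#'
#' @param prior_variance prior variance on coefficients, default 100.
#' @return A [prior_config].
#' @export
diffuse_prior <- function(prior_variance = 100)
  prior_config(loading_mean = 0, prior_variance = prior_variance)
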