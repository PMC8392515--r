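#' Simulate survey data for one group
#'
#' Draws independent observations from the linear-Gaussian model implied
#' by a specification and parameter set: exogenous constructs and controls
#' first, then each endogenous construct and outcome from its structural
#' equation, then indicators from the measurement model.  Identical
#' `(spec, params, n, seed)` give bit-identical output.
#'
#' @param spec a [sem_spec].
#' @param params a [parameter_set] (see [true_params()]).
#' @param n number of rows.
#' @param seed integer RNG seed.
#' @param group optional group label stored in the `spec$group_variable`
#'   column.
#' @return A data frame with one column per observed variable (in the
#'   specification's fixed order) plus the group column if `group` is
#'   given.  Attributes `truth`, `seed` and `spec` record the generator.
#' @export
simulate_group <- function(spec, params, n, seed, group = NULL) {
  stopifnot(inherits(spec, "sem_spec"), inherits(params, "parameter_set"),
            n >= 1)
  # fails early on an inadmissible parameter set
  implied_cov(spec, params)
  set.seed(as.integer(seed))
  vars <- structural_vars(spec)
  U <- matrix(0, n, length(vars), dimnames = list(NULL, vars))
  psi <- c(params$latent_disturbances, params$control_variances,
           params$residual_variances[spec$outcomes])[vars]
  endo <- endogenous_vars(spec)
  for (v in intersect(topological_order(spec), vars)) {
    e <- rnorm(n, 0, sqrt(psi[v]))
    if (v %in% endo) {
      rows <- spec$paths$target == v
      src <- spec$paths$source[rows]
      b <- params$structural[path_labels(spec)[rows]]
      U[, v] <- U[, src, drop = FALSE] %*% b + e
    } else U[, v] <- e
  }
  ind <- spec_indicators(spec)
  lat <- indicator_latent(spec)
  X <- U[, lat, drop = FALSE] *
    rep(params$loadings[ind], each = n) +
    matrix(rnorm(n * length(ind)), n) *
    rep(sqrt(params$residual_variances[ind]), each = n)
  colnames(X) <- ind
  out <- as.data.frame(cbind(X, U[, c(spec$controls, spec$outcomes),
                                  drop = FALSE]))
  if (!is.null(group)) out[[spec$group_variable]] <- group
  attr(out, "truth") <- params
  attr(out, "seed") <- as.integer(seed)
  attr(out, "spec") <- spec
  out
}

#' Simulate a full two-group synthetic study
#'
#' Generates a boy group and a girl group from their respective
#' group-specific generating parameters ([true_params()]) and stacks them.
#' Defaults emulate the survey scale the model was designed for: 881
#' completed questionnaires with an even gender split (the source study
#' does not report its group sizes).
#'
#' @param n_total total sample size (default 881).
#' @param boy_fraction fraction of boys, strictly between 0 and 1; the boy
#'   group gets `round(n_total * boy_fraction)` rows and the girl group
#'   the remainder.
#' @param seed integer RNG seed.
#' @param spec model topology, default [obesity_model()].
#' @return A data frame of all observed variables plus the group column;
#'   attribute `truth` is a named list of the per-group [parameter_set]s,
#'   `seed` the seed used.
#' @examples
#' d <- simulate_study(20, 0.5, seed = 1)
#' table(d$gender)
#' @export
simulate_study <- function(n_total = 881, boy_fraction = 0.5, seed = 1,
                           spec = obesity_model()) {
  stopifnot(n_total >= 2, boy_fraction > 0, boy_fraction < 1)
  n_boy <- round(n_total * boy_fraction)
  n_girl <- n_total - n_boy
  if (n_boy < 1 || n_girl < 1)
    stop("both groups must be non-empty")
  base <- as.integer(seed) %% 1073741824L  # keep derived seeds < 2^31
  boys <- simulate_group(spec, true_params("boy", spec), n_boy,
                         seed = 2L * base + 1L, group = "boy")
  girls <- simulate_group(spec, true_params("girl", spec), n_girl,
                          seed = 2L * base + 2L, group = "girl")
  out <- rbind(boys, girls)
  rownames(out) <- NULL
  attr(out, "truth") <- list(boy = attr(boys, "truth"),
                             girl = attr(girls, "truth"))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "spec") <- spec
  out
}

#' Optional Likert discretization of simulated indicators
#'
#' Survey items are ordinal in real data; this helper cuts continuous
#' simulated indicator columns into `n_levels` ordered categories at
#' equally spaced normal quantiles.  Off by default throughout the
#' package because every estimator treats indicators as continuous.
#'
#' @param data a data frame from [simulate_group()]/[simulate_study()].
#' @param spec the generating [sem_spec].
#' @param n_levels number of categories (default 5).
#' @return The data frame with indicator columns replaced by integer
#'   scores `1..n_levels`.
#' @export
discretize_likert <- function(data, spec = attr(data, "spec"),
                              n_levels = 5) {
  stopifnot(inherits(spec, "sem_spec"), n_levels >= 2)
  cuts <- stats::qnorm(seq_len(n_levels - 1) / n_levels)
  for (v in spec_indicators(spec)) {
    z <- (data[[v]] - mean(data[[v]])) / sd(data[[v]])
    data[[v]] <- findInterval(z, cuts) + 1L
  }
  data
}

#' Write / read a synthetic study as CSV plus JSON sidecar
#'
#' The data go to `<stem>.csv`; the generating truth (loadings, paths,
#' variances per group) and seed go to `<stem>_truth.json` so a dataset on
#' disk stays reproducible and auditable.
#'
#' @param data a data frame from [simulate_study()].
#' @param stem file path stem (without extension).
#' @return `write_study()` the stem invisibly; `read_study()` the data
#'   frame with `truth` and `seed` attributes restored.
#' @export
write_study <- function(data, stem) {
  write.csv(data, paste0(stem, ".csv"), row.names = FALSE)
  truth <- attr(data, "truth")
  side <- list(seed = attr(data, "seed"),
               truth = lapply(truth, function(p) lapply(unclass(p),
                                                        as.list)))
  jsonlite::write_json(side, paste0(stem, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_study
#' @param spec model topology used to rebuild the truth parameter sets.
#' @export
read_study <- function(stem, spec = obesity_model()) {
  data <- read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  side_path <- paste0(stem, "_truth.json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(data, "seed") <- side$seed
    attr(data, "truth") <- lapply(side$truth, function(p)
      parameter_set(spec,
                    loadings = unlist(p$loadings),
                    structural = unlist(p$structural),
                    residual_variances = unlist(p$residual_variances),
                    latent_disturbances = unlist(p$latent_disturbances),
                    control_variances = unlist(p$control_variances)))
  }
  attr(data, "spec") <- spec
  data
}
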