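#' Construct an SEM specification
#'
#' A `sem_spec` describes the topology of a linear structural equation
#' model: latent constructs with their reflective indicators, observed
#' outcome variables, observed exogenous controls, and the directed
#' structural/control paths among them.  Identification follows the fully
#' standardized convention: every latent variable has unit variance and the
#' sign of each construct is pinned by requiring its first loading to be
#' positive, so all loadings are free parameters.
#'
#' @param latents named list; one entry per latent construct giving the
#'   character vector of its indicator column names (order matters -- the
#'   first indicator fixes the construct's sign).
#' @param outcomes character vector of observed endogenous outcome columns.
#' @param controls character vector of observed exogenous control columns.
#' @param paths data frame with columns `source`, `target` and `role`
#'   (`"structural"` or `"control"`); row order is preserved in all output
#'   tables.
#' @param group_variable name of the grouping column (moderator) in
#'   datasets, default `"gender"`.
#'
#' @return An object of class `sem_spec`.
#' @seealso [obesity_model()] for the default adolescent-obesity topology.
#' @export
sem_spec <- function(latents, outcomes, controls, paths,
                     group_variable = "gender") {
  stopifnot(is.list(latents), length(latents) >= 1,
            !is.null(names(latents)), all(nzchar(names(latents))))
  if (any(lengths(latents) < 1L))
    stop("every latent construct needs at least one indicator")
  indicators <- unlist(latents, use.names = FALSE)
  all_vars <- c(indicators, outcomes, controls, names(latents))
  if (anyDuplicated(all_vars))
    stop("variable labels must be unique across the whole model: ",
         paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "))
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "role") %in% names(paths)))
  declared <- c(names(latents), outcomes, controls)
  bad <- setdiff(unique(c(paths$source, paths$target)), declared)
  if (length(bad))
    stop("path endpoints not declared in the model: ",
         paste(bad, collapse = ", "))
  if (any(paths$source == paths$target))
    stop("self-loops are not allowed")
  if (!all(paths$role %in% c("structural", "control")))
    stop("path role must be 'structural' or 'control'")
  spec <- structure(
    list(latents = latents, outcomes = outcomes, controls = controls,
         paths = paths, group_variable = group_variable),
    class = "sem_spec")
  # acyclicity check doubles as computation of an evaluation order
  topological_order(spec)
  spec
}

#' Default adolescent-obesity model topology
#'
#' Builds the survey model relating household socioeconomic status to
#' adolescent BMI and body fat.  One exogenous construct (household
#' socioeconomic status, six indicators) acts on two observed outcomes
#' (BMI, body fat) directly and through three mediating constructs:
#' lifestyle (four indicators), healthy food intake (three) and unhealthy
#' food intake (four).  Parents' BMI and parents' body fat are observed
#' controls for the matching outcome.  The model has 15 directed paths:
#' 13 structural and 2 control.
#'
#' @return A [sem_spec] with 4 latent constructs, 17 indicators, 2
#'   outcomes, 2 controls and 15 paths.
#' @examples
#' spec <- obesity_model()
#' nrow(spec$paths)      # 15
#' length(unlist(spec$latents))  # 17 indicators
#' @export
obesity_model <- function() {
  sem_spec(
    latents = list(
      ses       = c("age_father", "age_mother", "edu_father", "edu_mother",
                    "income_mother", "income_father"),
      lifestyle = c("sleep", "physical_activity", "screen_time",
                    "pocket_money"),
      healthy   = c("fruits", "vegetables", "whole_grains"),
      unhealthy = c("snacks", "fast_food", "soft_drink", "sweets")),
    outcomes = c("bmi", "body_fat"),
    controls = c("parent_bmi", "parent_body_fat"),
    paths = data.frame(
      source = c("ses", "ses", "ses", "ses", "ses",
                 "lifestyle", "lifestyle", "lifestyle", "lifestyle",
                 "healthy", "healthy", "unhealthy", "unhealthy",
                 "parent_bmi", "parent_body_fat"),
      target = c("healthy", "unhealthy", "lifestyle", "bmi", "body_fat",
                 "healthy", "unhealthy", "bmi", "body_fat",
                 "bmi", "body_fat", "bmi", "body_fat",
                 "bmi", "body_fat"),
      role = c(rep("structural", 13), "control", "control"),
      stringsAsFactors = FALSE),
    group_variable = "gender")
}

# ---- accessors ------------------------------------------------------------

#' @export
print.sem_spec <- function(x, ...) {
  cat("SEM specification\n")
  cat("  latents  :", paste(sprintf("%s (%d)", names(x$latents),
                                    lengths(x$latents)), collapse = ", "), "\n")
  cat("  outcomes :", paste(x$outcomes, collapse = ", "), "\n")
  cat("  controls :", paste(x$controls, collapse = ", "), "\n")
  cat("  paths    :", nrow(x$paths), "(",
      sum(x$paths$role == "structural"), "structural,",
      sum(x$paths$role == "control"), "control )\n")
  invisible(x)
}

spec_indicators <- function(spec) unlist(spec$latents, use.names = FALSE)

# fixed observed-variable order: indicators, controls, outcomes
spec_observed <- function(spec)
  c(spec_indicators(spec), spec$controls, spec$outcomes)

# which latent each indicator loads on
indicator_latent <- function(spec) {
  rep(names(spec$latents), lengths(spec$latents))
}

path_labels <- function(spec) paste(spec$paths$source, "->", spec$paths$target)

# structural-block variables: latents then controls then outcomes
structural_vars <- function(spec)
  c(names(spec$latents), spec$controls, spec$outcomes)

# Kahn topological sort of latents+outcomes over structural paths.
# Errors if the directed graph has a cycle.
topological_order <- function(spec) {
  nodes <- structural_vars(spec)
  edges <- spec$paths[, c("source", "target")]
  order <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    has_in <- remaining %in% edges$target[edges$source %in% remaining]
    free <- remaining[!has_in]
    if (!length(free))
      stop("the structural graph contains a cycle involving: ",
           paste(remaining, collapse = ", "))
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  order
}

endogenous_vars <- function(spec) {
  nodes <- structural_vars(spec)
  nodes[nodes %in% spec$paths$target]
}

exogenous_latents <- function(spec)
  setdiff(names(spec$latents), spec$paths$target)

#' Drop indicators from a model specification
#'
#' Removes measurement indicators (for example those screened out by
#' [reliability_filter()]) and returns the reduced specification.  The
#' structural part of the model is unchanged.
#'
#' @param spec a [sem_spec].
#' @param drop character vector of indicator names to remove.
#' @return The reduced `sem_spec`.
#' @export
drop_indicators <- function(spec, drop) {
  stopifnot(inherits(spec, "sem_spec"))
  unknown <- setdiff(drop, spec_indicators(spec))
  if (length(unknown))
    stop("not indicators of this model: ", paste(unknown, collapse = ", "))
  latents <- lapply(spec$latents, function(ind) setdiff(ind, drop))
  empty <- names(latents)[lengths(latents) == 0L]
  if (length(empty))
    stop("dropping these indicators empties construct(s): ",
         paste(empty, collapse = ", "))
  sem_spec(latents, spec$outcomes, spec$controls, spec$paths,
           spec$group_variable)
}

# ---- serialization --------------------------------------------------------

#' Read / write a model specification as YAML
#'
#' The YAML layout mirrors the `sem_spec` fields; the package ships a
#' default at `system.file("extdata", "obesity_model.yaml", package =
#' "obsem")` equal to [obesity_model()].
#'
#' @param path file path.
#' @return `read_sem_spec()` returns a [sem_spec]; `write_sem_spec()`
#'   returns `path` invisibly.
#' @export
read_sem_spec <- function(path) {
  y <- yaml::read_yaml(path)
  sem_spec(latents = lapply(y$latents, unlist),
           outcomes = unlist(y$outcomes),
           controls = unlist(y$controls),
           paths = data.frame(source = vapply(y$paths, `[[`, "", "source"),
                              target = vapply(y$paths, `[[`, "", "target"),
                              role   = vapply(y$paths, `[[`, "", "role"),
                              stringsAsFactors = FALSE),
           group_variable = y$group_variable %||% "gender")
}

#' @rdname read_sem_spec
#' @param spec a [sem_spec].
#' @export
write_sem_spec <- function(spec, path) {
  stopifnot(inherits(spec, "sem_spec"))
  y <- list(latents = spec$latents,
            outcomes = spec$outcomes,
            controls = spec$controls,
            paths = lapply(seq_len(nrow(spec$paths)), function(i)
              as.list(spec$paths[i, c("source", "target", "role")])),
            group_variable = spec$group_variable)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
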