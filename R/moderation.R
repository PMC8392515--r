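#' Critical-ratio test for a coefficient difference between groups
#'
#' The multi-group moderation Z-score:
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)`, with a two-sided standard
#' normal p-value.  A path is called significantly moderated when
#' `|z| > 1.96`.
#'
#' @param b1,b2 coefficient estimates in the two groups.
#' @param se1,se2 their standard errors (posterior SDs for Bayesian
#'   fits); non-negative, not both zero.
#' @return A list with elements `z` and `p`.
#' @examples
#' z_difference(1, sqrt(0.5), 0, sqrt(0.5))  # z = 1, p = 0.317
#' @export
z_difference <- function(b1, se1, b2, se2) {
  stopifnot(is.finite(b1), is.finite(b2), se1 >= 0, se2 >= 0)
  if (se1 == 0 && se2 == 0)
    stop("z undefined: both standard errors are zero")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Multi-group moderation table
#'
#' Compares every structural/control path between two group-specific fits
#' of the same specification with the critical-ratio test; this is the
#' standard multi-group analysis for a categorical moderator such as
#' gender.  Standard errors are taken from each group's own fit
#' (unpooled).
#'
#' @param fit_boy,fit_girl fits from [sem_fit()] on the two groups'
#'   data, sharing the model specification.  Any pair of groups works;
#'   the argument names follow the boy-vs-girl convention, and `z` is
#'   signed as first group minus second.
#' @param alpha significance level; the significance flag uses the
#'   matching normal critical value (1.96 at the default 0.05).
#' @return A `moderation_table` data frame, one row per path in
#'   specification order: `path`, `coef_boy`, `se_boy`, `coef_girl`,
#'   `se_girl`, `z`, `p`, `significant`.  Attribute `n_significant`
#'   counts the flagged rows.
#' @export
multigroup_table <- function(fit_boy, fit_girl, alpha = 0.05) {
  stopifnot(inherits(fit_boy, "sem_fit"), inherits(fit_girl, "sem_fit"))
  p1 <- fit_boy$structural
  p2 <- fit_girl$structural
  if (!identical(p1$path, p2$path)) {
    odd <- c(setdiff(p1$path, p2$path), setdiff(p2$path, p1$path))
    stop("fits do not estimate the same paths; mismatched: ",
         paste(unique(odd), collapse = ", "))
  }
  if (any(is.na(p1$se)) || any(is.na(p2$se)))
    stop("both fits need standard errors (PLS fits carry none)")
  crit <- stats::qnorm(1 - alpha / 2)
  z <- (p1$estimate - p2$estimate) / sqrt(p1$se^2 + p2$se^2)
  out <- data.frame(path = p1$path,
                    coef_boy = p1$estimate, se_boy = p1$se,
                    coef_girl = p2$estimate, se_girl = p2$se,
                    z = z, p = 2 * pnorm(-abs(z)),
                    significant = abs(z) > crit,
                    stringsAsFactors = FALSE)
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "critical") <- crit
  class(out) <- c("moderation_table", "data.frame")
  out
}

#' @export
print.moderation_table <- function(x, ...) {
  cat("Multi-group moderation analysis (|z| >",
      round(attr(x, "critical"), 2), ")\n")
  y <- as.data.frame(x)
  y[, sapply(y, is.numeric)] <- round(y[, sapply(y, is.numeric)], 3)
  print(y, row.names = FALSE)
  cat(attr(x, "n_significant"), "of", nrow(x),
      "paths significantly moderated\n")
  invisible(x)
}
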