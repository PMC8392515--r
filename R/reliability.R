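#' Cronbach's alpha
#'
#' Internal-consistency reliability of an item set:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(item sum))`.
#' For two items with equal variances and correlation `r` this reduces to
#' `2r/(1+r)`.
#'
#' @param items numeric matrix or data frame, one column per item
#'   (at least two items, each with positive variance).
#' @return Alpha, a number in (-Inf, 1].
#' @export
cronbach_alpha <- function(items) {
  X <- as.matrix(items)
  if (ncol(X) < 2) stop("Cronbach's alpha needs at least 2 items")
  if (anyNA(X)) stop("missing values in the item table")
  V <- cov(X)
  if (any(diag(V) <= 0))
    stop("zero-variance item(s): ",
         paste(colnames(X)[diag(V) <= 0], collapse = ", "))
  k <- ncol(X)
  k / (k - 1) * (1 - sum(diag(V)) / sum(V))
}

#' Average variance extracted
#'
#' Mean squared standardized loading of a construct; the conventional
#' convergent-validity summary with threshold 0.5.
#'
#' @param loadings numeric vector of standardized loadings.
#' @return AVE, in \eqn{[0, 1]} for loadings in \eqn{[-1, 1]}.
#' @export
average_variance_extracted <- function(loadings) {
  if (!length(loadings)) stop("no loadings supplied")
  mean(loadings^2)
}

# standardized single-factor loadings for one construct.  ML factor
# analysis where it is feasible (>= 3 items); the two-item construct is
# exactly identified by lambda = sqrt(|r|); a single item loads 1.
single_factor_loadings <- function(X) {
  k <- ncol(X)
  if (k == 1) return(setNames(1, colnames(X)))
  R <- cor(X)
  if (k == 2) {
    r <- R[1, 2]
    return(setNames(rep(sqrt(abs(r)), 2) * c(1, sign(r)), colnames(X)))
  }
  fa <- tryCatch(factanal(covmat = R, factors = 1, n.obs = nrow(X)),
                 error = function(e) NULL)
  lo <- if (!is.null(fa)) drop(fa$loadings[, 1]) else {
    # fall back to the first principal axis when ML factoring fails
    e <- eigen(R, symmetric = TRUE)
    drop(e$vectors[, 1] * sqrt(e$values[1]))
  }
  if (sum(lo) < 0) lo <- -lo
  setNames(lo, colnames(X))
}

#' Reliability and validity screening with indicator elimination
#'
#' Applies the conventional three-threshold screen to each construct:
#' standardized loadings above 0.7, Cronbach's alpha above 0.7 and
#' average variance extracted (AVE) above 0.5.  Indicators whose loading
#' falls *below* the loading threshold are flagged as dropped (a loading
#' exactly at the threshold is retained), and alpha/AVE are re-computed
#' on the retained indicators.  Filtering an already filtered report is a
#' no-op.
#'
#' @param x either a data frame of raw survey data (loadings are then
#'   estimated by a per-construct single-factor fit), a named list of
#'   per-construct loading vectors (each named by indicator), or a
#'   `reliability_report` to re-filter.
#' @param spec a [sem_spec] (needed for data input; inferred otherwise).
#' @param loading_threshold drop indicators below this loading
#'   (default 0.7).
#' @param alpha_threshold,ave_threshold pass/fail thresholds reported per
#'   construct (defaults 0.7 and 0.5).
#' @return A `reliability_report`: list with `table` (indicator-level:
#'   construct, indicator, loading, dropped), `constructs`
#'   (construct-level: retained count, alpha, AVE, pass flags, validity),
#'   `dropped` (character vector) and `thresholds`.
#' @examples
#' ses <- c(age_father = 0.48, age_mother = 0.32, edu_father = 0.79,
#'          edu_mother = 0.71, income_mother = 0.46, income_father = 0.79)
#' rep <- reliability_filter(list(ses = ses))
#' rep$dropped
#' @export
reliability_filter <- function(x, spec = NULL, loading_threshold = 0.7,
                               alpha_threshold = 0.7, ave_threshold = 0.5) {
  if (inherits(x, "reliability_report")) {
    kept <- x$table[!x$table$dropped, ]
    loads <- split(setNames(kept$loading, kept$indicator), kept$construct)
    alphas <- setNames(x$constructs$alpha, x$constructs$construct)
    return(reliability_core(loads[unique(kept$construct)], alphas = alphas,
                            loading_threshold = loading_threshold,
                            alpha_threshold = alpha_threshold,
                            ave_threshold = ave_threshold))
  }
  if (is.data.frame(x)) {
    if (is.null(spec)) spec <- obesity_model()
    loads <- lapply(spec$latents, function(ind)
      single_factor_loadings(as.matrix(x[, ind, drop = FALSE])))
    alpha_fun <- function(ind) if (length(ind) >= 2)
      cronbach_alpha(x[, ind, drop = FALSE]) else NA_real_
    return(reliability_core(loads, data = x, alpha_fun = alpha_fun,
                            loading_threshold = loading_threshold,
                            alpha_threshold = alpha_threshold,
                            ave_threshold = ave_threshold))
  }
  if (is.list(x) && !is.null(names(x)))
    return(reliability_core(x, loading_threshold = loading_threshold,
                            alpha_threshold = alpha_threshold,
                            ave_threshold = ave_threshold))
  stop("x must be a data frame, a named list of loadings, ",
       "or a reliability_report")
}

reliability_core <- function(loads, data = NULL, alpha_fun = NULL,
                             alphas = NULL, loading_threshold,
                             alpha_threshold, ave_threshold) {
  tab <- do.call(rbind, lapply(names(loads), function(cn) {
    lo <- loads[[cn]]
    data.frame(construct = cn, indicator = names(lo),
               loading = unname(lo),
               dropped = unname(lo) < loading_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  cons <- do.call(rbind, lapply(names(loads), function(cn) {
    sub <- tab[tab$construct == cn, ]
    kept <- sub$indicator[!sub$dropped]
    valid <- length(kept) > 0
    ave <- if (valid)
      average_variance_extracted(sub$loading[!sub$dropped]) else NA_real_
    alpha <- if (!is.null(alpha_fun)) {
      if (length(kept) >= 2) alpha_fun(kept) else NA_real_
    } else if (!is.null(alphas)) alphas[[cn]] else NA_real_
    data.frame(construct = cn, n_indicators = nrow(sub),
               n_retained = length(kept),
               alpha = alpha, alpha_pass = !is.na(alpha) &&
                 alpha > alpha_threshold,
               ave = ave, ave_pass = !is.na(ave) && ave > ave_threshold,
               valid = valid, stringsAsFactors = FALSE)
  }))
  rownames(cons) <- NULL
  if (any(!cons$valid))
    warning("construct(s) left without retained indicators: ",
            paste(cons$construct[!cons$valid], collapse = ", "))
  structure(list(table = tab, constructs = cons,
                 dropped = tab$indicator[tab$dropped],
                 thresholds = c(loading = loading_threshold,
                                alpha = alpha_threshold,
                                ave = ave_threshold)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Reliability / validity report (loading threshold",
      x$thresholds["loading"], ")\n")
  tab <- x$table
  tab$loading <- round(tab$loading, 2)
  print(tab, row.names = FALSE)
  cat("\nConstruct summaries (retained indicators):\n")
  cons <- x$constructs
  cons$alpha <- round(cons$alpha, 2); cons$ave <- round(cons$ave, 2)
  print(cons, row.names = FALSE)
  if (length(x$dropped))
    cat("\ndropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.reliability_report <- function(x, ...) {
  merge(x$table, x$constructs[, c("construct", "alpha", "ave")],
        by = "construct", sort = FALSE)
}
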