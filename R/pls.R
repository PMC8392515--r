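# Partial least squares path modelling backend: Mode-A outer estimation
# with the centroid inner scheme, iterated to weight convergence, then
# path coefficients by OLS on the factor scores following the structural
# DAG.  Outcomes and controls enter the inner model as single-indicator
# blocks whose score is the standardized variable itself.
pls_backend <- function(sd, spec, tol = 1e-6, max_iter = 300) {
  mi <- model_index(spec)
  X <- sd$X
  n <- sd$n
  blocks <- c(spec$latents,
              setNames(as.list(c(spec$controls, spec$outcomes)),
                       c(spec$controls, spec$outcomes)))
  bn <- names(blocks)
  nb <- length(blocks)
  # inner adjacency from the path diagram (undirected)
  adj <- matrix(FALSE, nb, nb, dimnames = list(bn, bn))
  adj[cbind(match(spec$paths$source, bn), match(spec$paths$target, bn))] <-
    TRUE
  adj <- adj | t(adj)

  std1 <- function(y) (y - mean(y)) / sd(y)
  w <- lapply(blocks, function(v) rep(1, length(v)))
  scores <- sapply(seq_len(nb), function(b)
    std1(X[, blocks[[b]], drop = FALSE] %*% w[[b]]))
  colnames(scores) <- bn

  iter <- 0L
  change <- Inf
  repeat {
    iter <- iter + 1L
    w_old <- w
    R <- cor(scores)
    inner <- sign(R) * adj     # centroid scheme
    Z <- scores %*% inner
    for (b in seq_len(nb)) {
      if (length(blocks[[b]]) == 1L) next      # single-indicator block
      if (all(Z[, b] == 0)) next               # isolated block
      wb <- drop(cov(X[, blocks[[b]], drop = FALSE], Z[, b]))  # Mode A
      w[[b]] <- wb
      scores[, b] <- std1(X[, blocks[[b]], drop = FALSE] %*% wb)
    }
    # align signs with the first indicator before measuring change
    for (b in seq_len(nb)) {
      s <- sign(sum(w[[b]] * sign(w_old[[b]] + (w_old[[b]] == 0))))
      if (s < 0) { w[[b]] <- -w[[b]]; scores[, b] <- -scores[, b] }
    }
    nw <- lapply(w, function(x) x / sqrt(sum(x^2)))
    nwo <- lapply(w_old, function(x) x / sqrt(sum(x^2)))
    change <- max(unlist(Map(function(a, b) max(abs(a - b)), nw, nwo)))
    if (change < tol || iter >= max_iter) break
  }
  converged <- change < tol
  if (!converged)
    warning("PLS weights did not converge in ", max_iter,
            " iterations (last change ", signif(change, 3), ")")

  # fix construct signs: positive correlation with first indicator
  for (l in mi$lat) {
    if (cor(scores[, l], X[, spec$latents[[l]][1]]) < 0) {
      scores[, l] <- -scores[, l]
      w[[l]] <- -w[[l]]
    }
  }

  loadings <- setNames(numeric(mi$q), mi$ind)
  for (l in mi$lat)
    loadings[spec$latents[[l]]] <-
      drop(cor(X[, spec$latents[[l]], drop = FALSE], scores[, l]))

  # structural coefficients: OLS per equation on the scores
  est_path <- setNames(numeric(length(mi$labels)), mi$labels)
  r2 <- setNames(numeric(length(spec$outcomes)),
                 paste0("r2_", spec$outcomes))
  for (eq in mi$eqs) {
    W <- scores[, eq$sources, drop = FALSE]
    y <- scores[, eq$target]
    b <- solve(crossprod(W), crossprod(W, y))
    est_path[eq$labels] <- drop(b)
    if (!eq$is_latent)
      r2[paste0("r2_", eq$target)] <- 1 - sum((y - W %*% b)^2) / sum(y^2)
  }

  raw_z <- sapply(seq_len(nb), function(b)
    X[, blocks[[b]], drop = FALSE] %*% w[[b]])
  est <- c(loadings, est_path, r2)
  list(estimates = est,
       score_center = setNames(colMeans(raw_z), bn),
       score_scale = setNames(apply(raw_z, 2, sd), bn),
       se = setNames(rep(NA_real_, length(est)), names(est)),
       outer_weights = w[mi$lat], loadings = loadings,
       factor_scores = scores, converged = converged,
       iterations = iter, last_change = change)
}
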