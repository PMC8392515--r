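test_that("the default obesity topology has the documented shape", {
  spec <- obesity_model()
  expect_s3_class(spec, "sem_spec")
  expect_equal(nrow(spec$paths), 15)
  expect_equal(sum(spec$paths$role == "control"), 2)
  expect_length(unlist(spec$latents), 17)
  expect_equal(lengths(spec$latents),
               c(ses = 6L, lifestyle = 4L, healthy = 3L, unhealthy = 4L))
  # acyclic: a topological order exists and starts from the exogenous block
  ord <- obsem:::topological_order(spec)
  expect_true("ses" %in% ord[1:3])
  expect_setequal(ord, obsem:::structural_vars(spec))
})

test_that("specification validation rejects malformed models", {
  expect_error(sem_spec(list(f = c("a", "a")), "y", character(0),
                        data.frame(source = "f", target = "y",
                                   role = "structural")),
               "unique")
  expect_error(sem_spec(list(f = "a"), "y", character(0),
                        data.frame(source = "f", target = "f",
                                   role = "structural")),
               "self-loop")
  expect_error(sem_spec(list(f = "a", g = "b"), "y", character(0),
                        data.frame(source = c("f", "g", "y"),
                                   target = c("g", "f", "y2"),
                                   role = "structural")),
               "not declared")
  # a two-latent cycle
  expect_error(sem_spec(list(f = "a", g = "b"), "y", character(0),
                        data.frame(source = c("f", "g"),
                                   target = c("g", "f"),
                                   role = "structural")),
               "cycle")
})

test_that("prior regimes scale the base hyperparameters as documented", {
  base <- type_i_prior("girl")
  expect_length(base$path_means, 8)
  expect_equal(unname(base$path_means["ses -> bmi"]), 0.4)
  expect_identical(prior_regime(base, "I"), base)
  expect_equal(prior_regime(base, "II")$path_means, base$path_means / 2)
  expect_equal(prior_regime(base, "III")$path_means, base$path_means * 2)
  expect_equal(prior_regime(base, "III")$loading_mean, 0.5)
  expect_error(prior_regime(base, "IV"), "unknown prior regime")
  # boy and girl base values differ
  expect_false(isTRUE(all.equal(type_i_prior("boy")$path_means,
                                base$path_means)))
})

test_that("implied covariance is symmetric, PD and order-invariant", {
  spec <- obesity_model()
  p <- true_params("girl", spec)
  S <- implied_cov(spec, p)
  expect_identical(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_equal(unname(diag(S)), rep(1, ncol(S)))
  # declaring the paths in reverse order changes nothing
  spec2 <- sem_spec(spec$latents, spec$outcomes, spec$controls,
                    spec$paths[rev(seq_len(nrow(spec$paths))), ])
  p2 <- true_params("girl", spec2)
  S2 <- implied_cov(spec2, p2)
  expect_equal(S2, S)
})

test_that("a free path fixed at zero matches the model without the path", {
  spec <- obesity_model()
  lbl <- obsem:::path_labels(spec)
  girl <- true_params("girl", spec)
  st <- girl$structural
  st["ses -> bmi"] <- 0
  p_zero <- standardized_params(spec, girl$loadings, st)
  keep <- spec$paths$source != "ses" | spec$paths$target != "bmi"
  spec_no <- sem_spec(spec$latents, spec$outcomes, spec$controls,
                      spec$paths[keep, ])
  p_no <- standardized_params(spec_no, girl$loadings, st[lbl[keep]])
  expect_equal(implied_cov(spec_no, p_no), implied_cov(spec, p_zero))
})

test_that("with no paths and unit loadings the covariance is block-diagonal", {
  spec <- obesity_model()
  ind <- unlist(spec$latents, use.names = FALSE)
  lbl <- paste(spec$paths$source, "->", spec$paths$target)
  p <- parameter_set(
    spec,
    loadings = setNames(rep(1, length(ind)), ind),
    structural = setNames(rep(0, length(lbl)), lbl),
    residual_variances = setNames(rep(1, length(ind) + 2),
                                  c(ind, spec$outcomes)))
  S <- implied_cov(spec, p)
  blocks <- obsem:::indicator_latent(spec)
  for (a in seq_along(ind)) for (b in seq_along(ind)) {
    expected <- if (a == b) 2 else if (blocks[a] == blocks[b]) 1 else 0
    expect_equal(unname(S[a, b]), expected)
  }
  # outcomes and controls uncorrelated with everything
  expect_equal(max(abs(S[ind, c(spec$controls, spec$outcomes)])), 0)
})

test_that("inadmissible parameter sets are rejected with a diagnostic", {
  spec <- obesity_model()
  girl <- true_params("girl", spec)
  st <- girl$structural
  st["unhealthy -> bmi"] <- 1.4   # explained variance above 1
  expect_error(standardized_params(spec, girl$loadings, st),
               "cannot standardize 'bmi'")
  rv <- girl$residual_variances
  rv["bmi"] <- -0.1
  expect_error(parameter_set(spec, girl$loadings, girl$structural, rv),
               "negative residual variance.*bmi")
})

test_that("the YAML round trip preserves the specification", {
  spec <- obesity_model()
  tmp <- tempfile(fileext = ".yaml")
  write_sem_spec(spec, tmp)
  spec2 <- read_sem_spec(tmp)
  expect_identical(spec2$latents, spec$latents)
  expect_identical(spec2$paths, spec$paths)
  expect_identical(spec2$outcomes, spec$outcomes)
  shipped <- system.file("extdata", "obesity_model.yaml", package = "obsem")
  expect_identical(read_sem_spec(shipped)$paths, spec$paths)
})

test_that("drop_indicators reduces the measurement model safely", {
  spec <- obesity_model()
  red <- drop_indicators(spec, c("age_father", "age_mother",
                                 "income_mother"))
  expect_length(unlist(red$latents), 14)
  expect_equal(red$paths, spec$paths)
  expect_error(drop_indicators(spec, "nonesuch"), "not indicators")
  expect_error(drop_indicators(spec, spec$latents$healthy), "empties")
})
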