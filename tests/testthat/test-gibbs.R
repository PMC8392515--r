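test_that("identical configurations give identical chains", {
  d <- simulate_study(200, 0.5, seed = 2)
  g <- d[d$gender == "girl", ]
  f1 <- sem_fit(g, method = "bayes", mcmc = quick_mcmc(seed = 5))
  f2 <- sem_fit(g, method = "bayes", mcmc = quick_mcmc(seed = 5))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$estimates, f2$estimates)
  f3 <- sem_fit(g, method = "bayes", mcmc = quick_mcmc(seed = 6))
  expect_false(identical(f1$estimates, f3$estimates))
})

test_that("the retained draw count honours the MCMC configuration", {
  d <- simulate_study(150, 0.5, seed = 3)
  g <- d[d$gender == "boy", ]
  mc <- mcmc_config(420, 120, thin = 3, n_chains = 2, seed = 1)
  f <- sem_fit(g, method = "bayes", mcmc = mc)
  expect_length(f$draws, 2)
  expect_equal(nrow(f$draws[[1]]), (420 - 120) / 3)
  expect_equal(nrow(do.call(rbind, f$draws)), 200)
})

test_that("a near-degenerate prior pins its path at the prior mean", {
  d <- simulate_study(300, 0.5, seed = 11)
  g <- d[d$gender == "girl", ]
  pr <- prior_config(path_means = c("ses -> bmi" = 0.5),
                     path_variances = c("ses -> bmi" = 1e-10),
                     prior_variance = 100, loading_mean = 0)
  f <- sem_fit(g, method = "bayes", prior = pr, mcmc = quick_mcmc(seed = 4))
  raw <- do.call(rbind, f$draws_raw)
  expect_equal(mean(raw[, "ses -> bmi"]), 0.5, tolerance = 1e-3)
  expect_lt(obsem:::pop_sd(raw[, "ses -> bmi"]), 1e-4)
})

test_that("posterior summaries follow the documented conventions", {
  fake <- structure(list(draws = list(matrix(c(0, 1, 0, 1), 4, 1,
                                             dimnames = list(NULL, "b")))),
                    class = c("bsem_fit", "sem_fit"))
  ps <- posterior_summary(fake)
  expect_equal(ps$estimate, 0.5)
  expect_equal(ps$se, 0.5)        # population-SD convention
  const <- structure(list(draws = list(matrix(1, 4, 1,
                                              dimnames = list(NULL, "b")))),
                     class = c("bsem_fit", "sem_fit"))
  expect_equal(posterior_summary(const)$se, 0)
  # interval brackets the estimate on a real fit
  d <- simulate_study(150, 0.5, seed = 8)
  f <- sem_fit(d[d$gender == "girl", ], method = "bayes",
               mcmc = quick_mcmc(seed = 2))
  ps2 <- posterior_summary(f)
  expect_true(all(ps2$lower <= ps2$estimate + 1e-12))
  expect_true(all(ps2$estimate <= ps2$upper + 1e-12))
})

test_that("structural coefficients are recovered at survey scale", {
  spec <- obesity_model()
  p <- true_params("girl", spec)
  g <- simulate_group(spec, p, 2000, seed = 23, group = "girl")
  f <- sem_fit(g, spec, method = "bayes", prior = diffuse_prior(),
               mcmc = mcmc_config(1200, 400, n_chains = 1, seed = 3))
  expect_lt(max(abs(coef(f) - p$structural)), 0.10)
  expect_lt(max(abs(coef(f, "loadings") - p$loadings)), 0.10)
})

test_that("chains mix at default-style settings on synthetic data", {
  d <- simulate_study(881, 0.5, seed = 14)
  g <- d[d$gender == "girl", ]
  f <- sem_fit(g, method = "bayes", prior = type_i_prior("girl"),
               mcmc = mcmc_config(1500, 500, n_chains = 2, seed = 9))
  expect_lt(max(f$diagnostics$rhat, na.rm = TRUE), 1.05)
})

test_that("degenerate data are rejected with the variable named", {
  d <- simulate_study(100, 0.5, seed = 4)
  d$fruits <- 1
  expect_error(sem_fit(d, method = "bayes", mcmc = quick_mcmc()),
               "zero-variance.*fruits")
})

test_that("prior sensitivity: identical regimes agree, small samples diverge", {
  spec <- obesity_model()
  g2000 <- simulate_group(spec, true_params("girl"), 2000, seed = 31)
  g10 <- simulate_group(spec, true_params("girl"), 10, seed = 31)
  base <- type_i_prior("girl")
  same <- prior_sensitivity(g2000, spec,
                            priors = list(a = base, b = base),
                            mcmc = quick_mcmc(seed = 2))
  expect_lt(max(attr(same, "discrepancy")), 1e-12)
  two <- list(I = prior_regime(base, "I"), III = prior_regime(base, "III"))
  big <- prior_sensitivity(g2000, spec, priors = two,
                           mcmc = quick_mcmc(seed = 2))
  small <- prior_sensitivity(g10, spec, priors = two,
                             mcmc = quick_mcmc(seed = 2))
  # the prior dominates small samples: discrepancies shrink with n
  expect_gt(max(attr(small, "discrepancy")),
            max(attr(big, "discrepancy")))
  expect_equal(nrow(big), 30)   # 15 paths x 2 regimes
})
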