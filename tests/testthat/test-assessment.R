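test_that("incremental fit indices match their closed forms", {
  fi <- fit_indices(20, 8, 100, 10)
  expect_equal(fi$nfi, 0.8)
  expect_equal(fi$ifi, 80 / 92)
  expect_equal(fi$rfi, 0.75)
  expect_equal(fi$tli, 7.5 / 9)
  expect_equal(fi$cfi, 1 - 12 / 90)
})

test_that("saturated and baseline-equal models hit the index bounds", {
  sat <- fit_indices(0, 8, 100, 10)
  expect_equal(sat$nfi, 1)
  expect_equal(sat$cfi, 1)
  same <- fit_indices(100, 10, 100, 10)
  expect_equal(same$nfi, 0)
  expect_equal(same$tli, 0)
  # zero baseline chi-square: incremental indices undefined
  expect_message(z0 <- fit_indices(0, 8, 0, 10), "undefined")
  expect_true(is.na(z0$nfi) && is.na(z0$cfi))
})

test_that("CFI dominates NFI when the model beats the baseline per df", {
  # brute-force evaluator, independent of the package implementation;
  # the algebraic condition for CFI >= NFI (baseline above its df) is
  # chisq_m/df_m <= chisq_b/df_b, which any acceptable model satisfies
  brute <- function(cm, dm, cb, db) {
    nfi <- (cb - cm) / cb
    cfi <- 1 - max(cm - dm, 0) / max(cb - db, cm - dm, 0)
    c(nfi = nfi, cfi = cfi)
  }
  set.seed(42)
  checked <- 0
  for (k in 1:400) {
    db <- sample(5:40, 1)
    dm <- sample(2:(db - 1), 1)
    cb <- db + rexp(1, 1 / 50)   # baseline chi-square above its df
    cm <- runif(1, 0, cb)
    fi <- fit_indices(cm, dm, cb, db)
    b <- brute(cm, dm, cb, db)
    expect_equal(fi$nfi, unname(b["nfi"]))
    expect_equal(fi$cfi, unname(b["cfi"]))
    if (cm / dm <= cb / db) {
      expect_gte(fi$cfi + 1e-12, fi$nfi)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)   # the ordering branch was actually exercised
})

test_that("GFI is 1 at a perfect fit and below 1 otherwise", {
  S <- implied_cov(obesity_model(), true_params("girl"))
  expect_equal(fit_indices(1, 1, 10, 5, S, S)$gfi, 1)
  S2 <- S; diag(S2) <- diag(S2) + 0.2
  expect_lt(fit_indices(1, 1, 10, 5, S2, S)$gfi, 1)
})

test_that("predictive metrics match hand computations", {
  # constant predictions: r2 undefined (warned), error metrics defined
  expect_warning(m <- predictive_metrics(c(1, 2, 3), c(2, 2, 2)),
                 "constant")
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$mape, 4 / 9)
  expect_equal(m$mse_printed, 2 / 3)
  expect_equal(m$mse, 2 / 3)
  perfect <- predictive_metrics(c(1, 2, 4), c(1, 2, 4))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mape, 0)
  expect_equal(perfect$mse_printed, 0)
  # affine predictions still give r2 = 1
  obs <- c(1, 3, 2, 5)
  expect_equal(predictive_metrics(obs, 2 + 3 * obs)$r2, 1)
})

test_that("predictive metrics reject or flag degenerate input", {
  expect_error(predictive_metrics(c(0, 1, 2), c(1, 1, 1)), "zero")
  expect_warning(m <- predictive_metrics(c(1, 1, 1), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(m$r2))
  expect_error(predictive_metrics(1:3, 1:4))
})

test_that("fit indices from a fitted model are deterministic and sane", {
  d <- simulate_study(600, 0.5, seed = 31)
  g <- d[d$gender == "girl", ]
  fm <- sem_fit(g, method = "ml")
  fi <- model_fit_indices(fm)
  fi2 <- model_fit_indices(sem_fit(g, method = "ml"))
  for (nm in c("gfi", "nfi", "ifi", "rfi", "tli", "cfi")) {
    expect_true(is.finite(fi[[nm]]))
    expect_gte(fi[[nm]], 0)
    expect_lte(fi[[nm]], 1.05)
  }
  expect_equal(fi$cfi, fi2$cfi, tolerance = 1e-8)
  expect_gte(fi$cfi, fi$nfi)
})

test_that("the estimator comparison is complete and reproducible", {
  d <- simulate_study(400, 0.5, seed = 17)
  cmp1 <- compare_estimators(d, mcmc = quick_mcmc(seed = 2))
  cmp2 <- compare_estimators(d, mcmc = quick_mcmc(seed = 2))
  expect_equal(nrow(cmp1), 3)
  cells <- as.matrix(cmp1[, c("r2", "rmse", "mape", "mse_printed")])
  expect_equal(sum(is.finite(cells)), 12)
  expect_false(any(cmp1$failed))
  expect_equal(cmp1, cmp2, ignore_attr = TRUE)
})

test_that("estimators approach perfect prediction as noise vanishes", {
  spec <- obesity_model()
  d <- simulate_group(spec, noisefree_params(spec), 500, seed = 9,
                      group = "girl")
  cmp <- compare_estimators(d, spec, mcmc = quick_mcmc(seed = 3))
  expect_true(all(cmp$r2 > 0.97))
})
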