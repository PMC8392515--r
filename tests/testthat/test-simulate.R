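test_that("generation is deterministic in the seed and sensitive to it", {
  spec <- obesity_model()
  p <- true_params("girl", spec)
  d1 <- simulate_group(spec, p, 5, seed = 7)
  d2 <- simulate_group(spec, p, 5, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_group(spec, p, 5, seed = 8)
  expect_false(isTRUE(all.equal(d1, d3)))
  s1 <- simulate_study(40, 0.5, seed = 1)
  s2 <- simulate_study(40, 0.5, seed = 2)
  expect_false(isTRUE(all.equal(s1$bmi, s2$bmi)))
})

test_that("group sizes follow the rounding contract", {
  d <- simulate_study(881, 0.5, seed = 1)
  tab <- table(d$gender)
  expect_equal(sum(tab), 881)
  expect_equal(unname(tab[["boy"]]), 440)
  expect_equal(unname(tab[["girl"]]), 441)
  d2 <- simulate_study(10, 0.3, seed = 1)
  expect_equal(unname(table(d2$gender)[["boy"]]), 3)
  expect_equal(unname(table(d2$gender)[["girl"]]), 7)
  expect_error(simulate_study(100, 0), "boy_fraction")
})

test_that("sample moments converge to the implied moments", {
  spec <- obesity_model()
  p <- true_params("girl", spec)
  d <- simulate_group(spec, p, 1e6, seed = 99)
  S <- cov(as.matrix(d[, obsem:::spec_observed(spec)]))
  expect_lt(max(abs(S - implied_cov(spec, p))), 0.02)
  # unit marginal variances under the standardized convention
  expect_lt(max(abs(diag(S) - 1)), 0.02)
})

test_that("indicators are independent of outcomes under the null", {
  spec <- obesity_model()
  d <- simulate_group(spec, zero_path_params(spec), 1e5, seed = 12)
  ses_ind <- spec$latents$ses
  cors <- cor(as.matrix(d[, ses_ind]), d$bmi)
  expect_lt(max(abs(cors)), 0.02)
})

test_that("the study carries its generating truth", {
  d <- simulate_study(30, 0.5, seed = 5)
  truth <- attr(d, "truth")
  expect_named(truth, c("boy", "girl"))
  expect_equal(truth$girl$structural[["ses -> healthy"]], 0.61)
  expect_equal(truth$boy$structural[["ses -> healthy"]], 0.41)
  # regenerating from the recorded seed reproduces the data
  d2 <- simulate_study(30, 0.5, seed = attr(d, "seed"))
  expect_identical(d[, names(d)], d2[, names(d2)])
})

test_that("group-specific truths match the reported group models", {
  girl <- true_params("girl")$structural
  boy <- true_params("boy")$structural
  expect_equal(girl[["unhealthy -> body_fat"]], 0.76)
  expect_equal(girl[["lifestyle -> bmi"]], -0.20)
  expect_equal(boy[["ses -> bmi"]], -0.19)
  expect_equal(boy[["lifestyle -> body_fat"]], -0.29)
  # all residual and disturbance variances strictly positive
  for (g in c("girl", "boy")) {
    p <- true_params(g)
    expect_true(all(p$residual_variances > 0))
    expect_true(all(p$latent_disturbances > 0))
  }
})

test_that("CSV round trip with truth sidecar is faithful", {
  d <- simulate_study(25, 0.4, seed = 3)
  stem <- tempfile("study")
  write_study(d, stem)
  d2 <- read_study(stem)
  expect_equal(as.data.frame(d), as.data.frame(d2)[, names(d)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(d2, "seed"), 3L)
  expect_equal(attr(d2, "truth")$girl$structural,
               attr(d, "truth")$girl$structural)
})

test_that("Likert discretization yields ordered categories", {
  spec <- obesity_model()
  d <- simulate_study(500, 0.5, seed = 4)
  dl <- discretize_likert(d, spec, n_levels = 5)
  ind <- unlist(spec$latents, use.names = FALSE)
  for (v in ind[c(1, 9, 17)]) {
    expect_true(all(dl[[v]] %in% 1:5))
  }
  # outcomes are untouched
  expect_identical(dl$bmi, d$bmi)
})
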