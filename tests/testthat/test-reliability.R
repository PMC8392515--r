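test_that("alpha matches the two-item closed form 2r/(1+r)", {
  for (r in c(0.2, 0.5, 0.8)) {
    X <- items_with_cor(matrix(c(1, r, r, 1), 2))
    expect_equal(cronbach_alpha(X), 2 * r / (1 + r), tolerance = 1e-10)
  }
})

test_that("alpha is 0 for uncorrelated items and 1 for perfect consistency", {
  X <- items_with_cor(diag(4))
  expect_equal(cronbach_alpha(X), 0, tolerance = 1e-10)
  x <- rnorm(40)
  expect_equal(cronbach_alpha(cbind(x, x + 1, x + 2)), 1, tolerance = 1e-12)
})

test_that("alpha is invariant to a common rescaling and rejects bad input", {
  X <- items_with_cor(matrix(c(1, .4, .3, .4, 1, .5, .3, .5, 1), 3))
  expect_equal(cronbach_alpha(X * 7), cronbach_alpha(X), tolerance = 1e-12)
  expect_error(cronbach_alpha(X[, 1, drop = FALSE]), "at least 2")
  expect_error(cronbach_alpha(cbind(X, zero = 0)), "zero-variance")
})

test_that("AVE is the mean squared loading", {
  expect_equal(average_variance_extracted(c(1, 1, 1)), 1)
  expect_equal(average_variance_extracted(c(0.8, 0.6)), 0.5)
  expect_equal(average_variance_extracted(0.3), 0.09)
  expect_error(average_variance_extracted(numeric(0)), "no loadings")
})

test_that("the 0.7 rule drops exactly the three weak socioeconomic items", {
  ses <- c(age_father = 0.48, age_mother = 0.32, edu_father = 0.79,
           edu_mother = 0.71, income_mother = 0.46, income_father = 0.79)
  rep <- reliability_filter(list(ses = ses))
  expect_setequal(rep$dropped,
                  c("age_father", "age_mother", "income_mother"))
  kept <- rep$table$indicator[!rep$table$dropped]
  expect_setequal(kept, c("edu_father", "edu_mother", "income_father"))
  # AVE is recomputed on the retained loadings
  expect_equal(rep$constructs$ave,
               mean(c(0.79, 0.71, 0.79)^2))
})

test_that("threshold boundaries behave as documented", {
  lo <- list(f = c(a = 0.9, b = 0.7, c = 0.69))
  rep <- reliability_filter(lo)
  expect_equal(rep$dropped, "c")          # exactly 0.7 is retained
  expect_length(reliability_filter(list(f = c(a = .9, b = .8)))$dropped, 0)
  rep0 <- reliability_filter(lo, loading_threshold = 0)
  expect_length(rep0$dropped, 0)
  expect_warning(reliability_filter(list(f = c(a = .2, b = .1))),
                 "without retained")
})

test_that("filtering is idempotent", {
  lo <- list(f = c(a = 0.9, b = 0.5, c = 0.8),
             g = c(d = 0.75, e = 0.72))
  r1 <- reliability_filter(lo)
  r2 <- reliability_filter(r1)
  expect_length(r2$dropped, 0)
  kept1 <- r1$table[!r1$table$dropped, c("indicator", "loading")]
  expect_equal(r2$table[, c("indicator", "loading")], kept1,
               ignore_attr = TRUE)
  expect_equal(r2$constructs$ave, r1$constructs$ave)
})

test_that("data-driven screening recovers the weak indicators", {
  d <- simulate_study(2000, 0.5, seed = 21)
  rep <- reliability_filter(d, obesity_model())
  expect_setequal(rep$dropped,
                  c("age_father", "age_mother", "income_mother"))
  # strong constructs pass both thresholds
  cons <- rep$constructs
  expect_true(all(cons$alpha_pass[cons$construct != "ses"]))
  expect_true(all(cons$ave_pass))
  # loadings estimated close to the generating values
  tab <- rep$table
  truth <- true_params("girl")$loadings   # equal loadings in both groups
  expect_lt(max(abs(tab$loading - truth[tab$indicator])), 0.1)
})
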