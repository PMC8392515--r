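test_that("the critical-ratio test matches hand computation", {
  z <- z_difference(1, sqrt(0.5), 0, sqrt(0.5))
  expect_equal(z$z, 1)
  expect_equal(z$p, 2 * pnorm(-1), tolerance = 1e-12)
  expect_equal(round(z$p, 4), 0.3173)
  eq <- z_difference(0.4, 0.1, 0.4, 0.2)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_error(z_difference(1, 0, 0, 0), "both standard errors")
  # a critical ratio of 2.54 clears the 1.96 threshold
  p254 <- 2 * pnorm(-2.54)
  expect_lt(p254, 0.05)
  expect_equal(round(p254, 3), 0.011)
})

test_that("swapping the groups negates z and preserves p", {
  d <- simulate_study(500, 0.5, seed = 25)
  fb <- sem_fit(d[d$gender == "boy", ], method = "ml", n_starts = 1)
  fg <- sem_fit(d[d$gender == "girl", ], method = "ml", n_starts = 1)
  m1 <- multigroup_table(fb, fg)
  m2 <- multigroup_table(fg, fb)
  expect_equal(m2$z, -m1$z)
  expect_equal(m2$p, m1$p)
  expect_equal(m1$path, obsem:::path_labels(obesity_model()))
  expect_equal(nrow(m1), 15)
  expect_true(all(m1$significant == (abs(m1$z) > 1.96)))
})

test_that("identical fits give a null moderation table", {
  d <- simulate_study(400, 0.5, seed = 26)
  f <- sem_fit(d[d$gender == "girl", ], method = "ml", n_starts = 1)
  m <- multigroup_table(f, f)
  expect_true(all(m$z == 0))
  expect_true(all(m$p == 1))
  expect_equal(attr(m, "n_significant"), 0)
})

test_that("mismatched path sets are rejected with the path named", {
  spec <- obesity_model()
  keep <- !(spec$paths$source == "ses" & spec$paths$target == "bmi")
  spec2 <- sem_spec(spec$latents, spec$outcomes, spec$controls,
                    spec$paths[keep, ])
  d <- simulate_study(400, 0.5, seed = 27)
  f1 <- sem_fit(d[d$gender == "boy", ], spec, method = "ml", n_starts = 1)
  f2 <- sem_fit(d[d$gender == "girl", ], spec2, method = "ml",
                n_starts = 1)
  expect_error(multigroup_table(f1, f2), "ses -> bmi")
  fp <- sem_fit(d[d$gender == "girl", ], spec, method = "pls")
  expect_error(multigroup_table(f1, fp), "standard errors")
})

test_that("clearly different paths are detected in most replicates", {
  # power check: paths whose generating coefficients differ by >= 0.2
  # between the groups should be flagged in the majority of replicates
  # at the survey's sample size
  spec <- obesity_model()
  p_boy <- true_params("boy", spec)
  p_girl <- true_params("girl", spec)
  gap <- abs(p_boy$structural - p_girl$structural)
  big <- names(gap)[gap >= 0.2]
  expect_gte(length(big), 3)
  n_rep <- 40
  hits <- setNames(numeric(length(big)), big)
  for (r in seq_len(n_rep)) {
    db <- simulate_group(spec, p_boy, 440, seed = 5000 + r)
    dg <- simulate_group(spec, p_girl, 441, seed = 6000 + r)
    fb <- sem_fit(db, spec, method = "ml", n_starts = 1, start = p_boy)
    fg <- sem_fit(dg, spec, method = "ml", n_starts = 1, start = p_girl)
    m <- multigroup_table(fb, fg)
    hits <- hits + m$significant[match(big, m$path)]
  }
  expect_true(all(hits / n_rep > 0.5))
})
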