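# Unit conversions, error statistics, regression, comparison reports.

test_that("g/L to mM follows the molar-mass formula", {
  expect_equal(gl_to_mM(0, 60.05), 0)
  expect_equal(gl_to_mM(1, 60.05), 1000 / 60.05)  # acetate, 16.653 mM
  expect_equal(gl_to_mM(gl_to_mM(7.3, 90.08) * 90.08 / 1000, 90.08),
               gl_to_mM(7.3, 90.08))  # round trip
  expect_error(gl_to_mM(1, 0), "molar_mass")
})

test_that("pseudo-log10 floors at one bacterium per litre", {
  expect_equal(gl_to_pseudolog10(0), 0)
  expect_equal(gl_to_pseudolog10(4.6e-12), 0)       # exactly 1 bacterium/L
  expect_equal(gl_to_pseudolog10(4.6e-12 * 1e9), 9)
  expect_equal(gl_to_pseudolog10(2e-12), 0)         # below 1/L
  expect_error(gl_to_pseudolog10(-1), ">= 0")
  expect_error(gl_to_pseudolog10(1, cell_mass = 0), "cell_mass")
})

test_that("rmse matches closed forms and a brute-force loop", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5 + 2, 1:5), 2)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(3:50, 1)
      a <- rnorm(n); b <- rnorm(n)
      acc <- 0
      for (j in seq_len(n)) acc <- acc + (a[j] - b[j])^2
      expect_equal(rmse(a, b), sqrt(acc / n), tolerance = 1e-12)
    }
  })
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("rmse percent is relative to the observation mean", {
  expect_equal(rmse_percent(0, c(1, 2, 3)), 0)
  expect_equal(rmse_percent(2, c(2, 2, 2)), 100)
  # the reported 0.31 log10 error on a mean of 11.13 is about 2.78-2.79%
  expect_equal(rmse_percent(0.31, rep(11.13, 5)), 2.785, tolerance = 0.002)
  expect_true(is.na(rmse_percent(1, c(0, 0))))
})

test_that("lm_fit is ordinary least squares with a slope t-test", {
  obs <- 1:10
  fit <- suppressWarnings(lm_fit(obs, obs))
  expect_equal(fit$slope, 1)
  expect_lt(fit$p_value, 1e-6)
  fit2 <- suppressWarnings(lm_fit(2 * obs + 1, obs))
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)
  # cross-check against stats::lm on noisy data
  withr::with_seed(2, {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    ref <- summary(stats::lm(y ~ x))$coefficients
    got <- lm_fit(y, x)
    expect_equal(got$p_value, ref["x", "Pr(>|t|)"], tolerance = 1e-12)
  })
  expect_error(lm_fit(1:5, rep(1, 5)), "constant")
  expect_error(lm_fit(1:2, 1:2), "3 pairs")
})

test_that("under the null the regression p-value is uniform", {
  withr::with_seed(77, {
    p <- replicate(1000, lm_fit(rnorm(20), rnorm(20))$p_value)
  })
  # Kolmogorov distance from U(0,1), 1% critical value for n = 1000
  d <- max(abs(sort(p) - (seq_along(p) - 0.5) / length(p)))
  expect_lt(d, 1.63 / sqrt(1000))
})

test_that("comparing a simulation to its own converted output gives 0", {
  bt <- benchmark_world()
  obs <- generate_observations(bt$result, noise = noise_model(0, 0))
  rep <- compare(bt$result, obs)
  expect_true(all(rep$matched))
  expect_equal(max(rep$rmse), 0)
  # a constant offset on one genus appears as exactly that RMSE
  obs2 <- obs
  sel <- obs2$variable == "FibreFermenter"
  obs2$value[sel] <- obs2$value[sel] + 1
  rep2 <- compare(bt$result, obs2)
  expect_equal(rep2$rmse[rep2$variable == "FibreFermenter"], 1,
               tolerance = 1e-9)
})

test_that("comparison is invariant to row order and to grid density", {
  bt <- benchmark_world()
  obs <- generate_observations(bt$result, noise = noise_model(), seed = 3)
  rep1 <- compare(bt$result, obs)
  shuffled <- obs[withr::with_seed(1, sample(nrow(obs))), ]
  rep2 <- compare(bt$result, shuffled)
  expect_equal(dplyr::arrange(tidy(rep1), variable),
               dplyr::arrange(tidy(rep2), variable))
  sc <- bt$scenario
  sc$grid_dt <- 0.5
  fine <- simulate(sc, bt$community)
  rep3 <- compare(fine, obs)
  expect_equal(rep1$rmse, rep3$rmse, tolerance = 1e-3)
})

test_that("observed variables missing from the simulation are flagged", {
  bt <- benchmark_world()
  obs <- generate_observations(bt$result, noise = noise_model(0, 0))
  obs <- dplyr::bind_rows(obs, tibble::tibble(
    time_h = c(0, 24), variable = "Mystery", kind = "genus",
    value = c(5, 5)))
  rep <- compare(bt$result, obs)
  row <- rep[rep$variable == "Mystery", ]
  expect_false(row$matched)
  expect_true(is.na(row$rmse))
})

test_that("core fractions reproduce the composition table summaries", {
  t1 <- table1_fixture()
  core <- t1$genus[t1$genus != "Others"]
  inoc <- core_summary(t1[, c("genus", "fecal_inoculum")], core)
  expect_equal(inoc$mean, 48.18, tolerance = 1e-9)
  reac <- core_summary(t1[, c("genus", "reactor1", "reactor2", "reactor3")],
                       core)
  expect_equal(reac$mean, 49.78, tolerance = 0.01)
  expect_equal(reac$sd, 4.51, tolerance = 0.01)
  # complement of the Others row
  expect_equal(inoc$mean, 100 - 51.81 - 0.01, tolerance = 0.011)

  zero <- core_summary(tibble::tibble(genus = c("A", "B"),
                                      s1 = c(0, 100)), "A")
  expect_equal(zero$mean, 0)
  expect_warning(
    missing <- core_summary(t1[, c("genus", "fecal_inoculum")],
                            c(core, "Ghost")), "Ghost")
  expect_equal(missing$missing_genera, "Ghost")
})

test_that("observation TSVs round-trip and are validated", {
  bt <- benchmark_world()
  obs <- generate_observations(bt$result, noise = noise_model(), seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back, obs)
  bad <- obs
  bad$value[1] <- -2
  expect_error(write_observations(bad, path), ">= 0")
})
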