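test_that("zero-noise data are a fixed point of the estimator", {
  truth <- default_truth_fluxes()
  fit <- base_fit_bonded()
  expect_true(fit$convergence$converged)
  expect_lt(max(abs(fit$estimates$free - truth$free) / truth$free), 0.01)
  # positional variant fits its 6 curves
  fitp <- base_fit_positional()
  expect_equal(fitp$n_curves, 6L)
  expect_equal(base_fit_bonded()$n_curves, 17L)
  expect_lt(max(abs(fitp$estimates$free - truth$free) / truth$free), 0.01)
})

test_that("the optimum is insensitive to a perturbed start on clean data", {
  truth <- default_truth_fluxes()
  init <- as_flux_set(truth$free * c(1.5, 0.5, 1.5, 0.5, 1.5, 0.5, 1.5))
  fit <- fit_fluxes(zero_noise_bonded(), init = init)
  expect_lt(max(abs(fit$estimates$free - truth$free) / truth$free), 0.01)
})

test_that("residual weighting scales as 1/sd", {
  # uniformly doubling every SD halves each weighted residual, so the
  # optimum is unchanged and the weighted SSE is quartered
  ds <- generate_dataset(seed = 31, net = default_net())
  fit1 <- fit_fluxes(ds)
  ds2 <- ds
  ds2$curves$sd <- 2 * ds2$curves$sd
  fit2 <- fit_fluxes(ds2)
  expect_equal(fit2$estimates$free, fit1$estimates$free,
               tolerance = 1e-4)
  expect_equal(fit2$residual, fit1$residual / 4, tolerance = 1e-4)
})

test_that("gamma summaries recover known generators", {
  set.seed(123)
  x <- rgamma(500, shape = 100, rate = 100 / 0.3)
  s <- summarize_distribution(x)
  expect_lt(abs(s$shape - 100) / 100, 0.10)
  # near-Gaussian limit: FWHM ~ 2.355 sigma
  expect_equal(s$fwhm, 2.3548 * sd(x), tolerance = 0.05)
  expect_error(summarize_distribution(rep(1, 60)), "degenerate")
  expect_error(summarize_distribution(c(-1, rep(1, 60))), "positive")
  expect_error(summarize_distribution(rgamma(10, 2)), "at least 50")
})

test_that("correlation matrices are well-formed and detect independence", {
  set.seed(99)
  n <- 400
  x <- matrix(rnorm(n * 7), ncol = 7,
              dimnames = list(NULL, free_flux_names))
  r <- correlation_matrix(x)
  expect_equal(diag(r), setNames(rep(1, 7), free_flux_names))
  expect_equal(r, t(r))
  expect_true(all(abs(r[upper.tri(r)]) < 3 / sqrt(n)))
  x[, 2] <- 1
  expect_error(correlation_matrix(x), "zero-variance")
})

test_that("constraining a flux at its true value costs nothing on clean data", {
  ds <- zero_noise_positional()
  sc <- cached("scan_vnt",
               sensitivity_scan(ds, "Vnt", grid = c(0.07, 0.10, 0.20)))
  expect_equal(sc$grid, default_scan_grid("Vnt"))
  expect_equal(default_scan_grid("Vdil"), c(0.20, 0.30, 0.60))
  fit0 <- base_fit_positional()
  expect_lt(abs(sc$residuals[2] - fit0$residual), 1e-6)
  expect_gt(sc$residuals[1], sc$residuals[2] + 1)
  expect_gt(sc$residuals[3], sc$residuals[2] + 1)
  expect_true(all(sc$converged))
})

test_that("GlnC4 singlet and doublet move oppositely under constrained Vnt", {
  sc <- cached("scan_vnt",
               sensitivity_scan(zero_noise_positional(), "Vnt",
                                grid = c(0.07, 0.10, 0.20)))
  ss <- function(v, pat) {
    cc <- sc$curves
    s <- cc[cc$metabolite == "gln" & cc$pattern == pat &
              cc$constrained_value == v, ]
    s$fe[which.max(s$time_min)]
  }
  s_vals <- vapply(sc$grid, ss, numeric(1), pat = "S")
  d_vals <- vapply(sc$grid, ss, numeric(1), pat = "D43")
  expect_true(all(diff(s_vals) < 0))   # singlet falls with Vnt
  expect_true(all(diff(d_vals) > 0))   # doublet rises with Vnt
  # while the total barely moves (relative range under 5%)
  t_vals <- vapply(sc$grid, ss, numeric(1), pat = "total")
  expect_lt(diff(range(t_vals)) / mean(t_vals), 0.05)
})

test_that("monte_carlo is reproducible and guards its preconditions", {
  ds <- generate_dataset(seed = 21, net = default_net())
  fit <- fit_fluxes(ds)
  mc1 <- monte_carlo(fit, n_mc = 3, seed = 7, max_fail_frac = 1)
  mc2 <- monte_carlo(fit, n_mc = 3, seed = 7, max_fail_frac = 1)
  expect_identical(mc1$samples, mc2$samples)
  fit0 <- base_fit_bonded()
  fit0$dataset$curves$sd <- 0 * fit0$dataset$curves$sd
  expect_error(monte_carlo(fit0), "zero noise")
})
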