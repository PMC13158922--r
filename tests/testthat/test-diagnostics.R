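# One noiseless and one noisy fit reused across the diagnostics tests.
.diag_cache <- local({
  ds0 <- generate_dataset(default_truth(), default_design(),
                          noise_model(cv = 0, seed = 1))
  f0 <- suppressWarnings(fit_kinetics(ds0, fit_options(n_starts = 4, seed = 2)))
  ds1 <- generate_dataset(default_truth(), default_design(),
                          noise_model(cv = 0.05, seed = 31))
  f1 <- suppressWarnings(fit_kinetics(ds1, fit_options(n_starts = 4, seed = 31)))
  list(f0 = f0, f1 = f1, ds1 = ds1)
})

test_that("standardized residuals vanish on noiseless data and normalize on noisy data", {
  r0 <- standardized_residuals(.diag_cache$f0)
  expect_equal(nrow(r0), 36)
  expect_lt(max(abs(r0$residual)), 1e-8 * 5e-4)

  r1 <- standardized_residuals(.diag_cache$f1)
  # sum of squared standardized residuals equals n - p exactly, because
  # sigma-hat is ssr/(n-p)
  expect_equal(sum(r1$standardized^2),
               .diag_cache$f1$n_obs - .diag_cache$f1$n_params,
               tolerance = 1e-10)
})

test_that("multiplicative noise leaves a positive |residual|-vs-fitted slope", {
  expect_gt(heteroscedasticity_slope(.diag_cache$f1), 0)
})

test_that("parameter correlations are normalized, flagged, and restricted to the core", {
  fit <- .diag_cache$f1
  pc <- parameter_correlation(fit)
  expect_equal(diag(pc$correlation), c(k1 = 1, k2 = 1, k3 = 1))
  expect_true(all(abs(pc$correlation) <= 1))

  # hand-built covariance reproduces the textbook example
  mock <- fit
  mock$covariance <- matrix(c(1, 0.95, 0.95, 1), 2, 2,
                            dimnames = list(c("k1", "k2"), c("k1", "k2")))
  mock$log_par <- c(k1 = 0, k2 = 0)
  pc2 <- parameter_correlation(mock, threshold = 0.9)
  expect_equal(nrow(pc2$high_corr_pairs), 1)
  expect_equal(pc2$high_corr_pairs$r, 0.95)

  mock$covariance <- diag(2)
  dimnames(mock$covariance) <- list(c("k1", "k2"), c("k1", "k2"))
  expect_equal(nrow(parameter_correlation(mock)$high_corr_pairs), 0)
})

test_that("dropping the early sampling window degrades identifiability", {
  # compare |r| > 0.9 flag frequency with and without the pre-10-min
  # samples, at constants slow enough that the full design resolves the
  # activation transient
  truth <- rate_constants(2, 10, 0.5)
  flags <- sapply(1:10, function(s) {
    full <- generate_dataset(truth, default_design(),
                             noise_model(cv = 0.05, seed = 300 + s))
    late_design <- experiment_descriptor(
      5e-4, 10, "continuous", 3600,
      sample_times = c(10, 15, 20, 25, 30, 40, 50, 60), n_replicates = 3)
    late <- generate_dataset(truth, late_design,
                             noise_model(cv = 0.05, seed = 300 + s))
    n_flag <- function(ds) {
      f <- suppressWarnings(fit_kinetics(ds, fit_options(n_starts = 2,
                                                         seed = s)))
      nrow(parameter_correlation(f)$high_corr_pairs)
    }
    c(full = n_flag(full), late = n_flag(late))
  })
  expect_gte(mean(flags["late", ]), mean(flags["full", ]))
})

test_that("AIC and adjusted R2 follow their definitions", {
  fit <- .diag_cache$f1
  expect_equal(aic_fit(fit),
               fit$n_obs * log(fit$ssr / fit$n_obs) + 2 * fit$n_params)

  # adding a parameter with no SSR change costs exactly 2 AIC units
  mock <- fit
  mock$n_params <- fit$n_params + 1L
  expect_equal(aic_fit(mock), aic_fit(fit) + 2)

  r2a <- adjusted_r2(fit)
  y <- fit$observations$peak_area
  r2 <- 1 - fit$ssr / sum((y - mean(y))^2)
  expect_lte(r2a, r2)
  expect_gt(r2a, 0.9)  # the default synthetic fit explains the data

  # near-perfect fit drives adjusted R2 to 1 and AIC to -Inf at ssr = 0
  expect_gt(adjusted_r2(.diag_cache$f0), 1 - 1e-8)
  mock0 <- .diag_cache$f0
  mock0$ssr <- 0
  expect_message(a <- aic_fit(mock0), "-Inf")
  expect_identical(a, -Inf)
})

test_that("model selection retains the standard model on ties and negligible k4", {
  ds <- .diag_cache$ds1
  f_std <- .diag_cache$f1
  f_ext <- suppressWarnings(
    fit_kinetics(ds, fit_options("extended", n_starts = 4, seed = 31)))
  sel <- select_model(f_std, f_ext)
  expect_true(sel$variant %in% c("standard", "extended"))

  # exact AIC tie: parsimony keeps the standard model
  tie <- f_ext
  tie$ssr <- f_std$ssr
  tie$n_params <- f_std$n_params
  sel_tie <- select_model(f_std, tie)
  expect_identical(sel_tie$variant, "standard")

  # k4 = 0 can never select the extended model, whatever the AIC says
  zero4 <- f_ext
  zero4$estimates <- rate_constants(f_ext$estimates$k1, f_ext$estimates$k2,
                                    f_ext$estimates$k3, k4 = 0)
  zero4$ssr <- f_std$ssr * 1e-6  # force an AIC advantage
  sel0 <- select_model(f_std, zero4)
  expect_identical(sel0$variant, "standard")
  expect_match(sel0$rationale, "negligible")
})

test_that("model selection refuses mismatched data or unconverged fits", {
  f_std <- .diag_cache$f1
  f_ext <- suppressWarnings(
    fit_kinetics(.diag_cache$ds1, fit_options("extended", n_starts = 2,
                                              seed = 31)))
  other <- generate_dataset(default_truth(), default_design(),
                            noise_model(cv = 0.05, seed = 99))
  f_other <- suppressWarnings(
    fit_kinetics(other, fit_options("extended", n_starts = 2, seed = 99)))
  expect_error(select_model(f_std, f_other), "same data")
  expect_error(select_model(f_ext, f_std), "standard fit first")
  un <- f_ext
  un$converged <- FALSE
  expect_error(select_model(f_std, un), "unconverged")
})
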