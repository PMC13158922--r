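test_that("objective is zero at the generating truth on noiseless data", {
  ds <- generate_dataset(default_truth(), default_design(),
                         noise_model(cv = 0, seed = 1))
  r <- kinetic_objective(log(c(k1 = 2, k2 = 200, k3 = 0.2)), ds)
  expect_length(r, 3 * 12)
  expect_lt(max(abs(r)), 1e-6 * 5e-4)
})

test_that("residuals are invariant (after normalization) to response rescaling", {
  scale <- 2000
  ds1 <- generate_dataset(default_truth(), default_design(),
                          noise_model(cv = 0.05, seed = 3))
  ds2 <- generate_dataset(default_truth(),
                          default_design(response_scale = scale),
                          noise_model(cv = 0.05, seed = 3))
  lp <- log(c(k1 = 2, k2 = 200, k3 = 0.2))
  r1 <- kinetic_objective(lp, ds1)
  # on the rescaled data the same kinetics live at constants / scale
  r2 <- kinetic_objective(lp - log(scale), ds2)
  expect_equal(r2 / scale, r1, tolerance = 1e-8)
})

test_that("noiseless data recover the generating constants nearly exactly", {
  ds <- generate_dataset(default_truth(), default_design(),
                         noise_model(cv = 0, seed = 1))
  fit <- suppressWarnings(fit_kinetics(ds, fit_options(n_starts = 8, seed = 2)))
  expect_true(fit$converged)
  est <- unlist(fit$estimates)
  expect_equal(est[["k1"]], 2, tolerance = 1e-3)
  expect_equal(est[["k2"]], 200, tolerance = 1e-3)
  expect_equal(est[["k3"]], 0.2, tolerance = 1e-3)
})

test_that("the returned optimum improves on every multistart initial point", {
  ds <- generate_dataset(default_truth(), default_design(),
                         noise_model(cv = 0.05, seed = 7))
  fit <- suppressWarnings(fit_kinetics(ds, fit_options(n_starts = 6, seed = 7)))
  expect_true(all(fit$ssr <= fit$start_ssr + 1e-12))
})

test_that("fitting rejects degenerate designs", {
  ds <- generate_dataset(default_truth(), default_design(),
                         noise_model(cv = 0, seed = 1))
  ds$observations <- ds$observations[ds$observations$time_min == 2, ]
  expect_error(fit_kinetics(ds), "two distinct time points")

  ds2 <- generate_dataset(default_truth(),
                          experiment_descriptor(5e-4, 10, "continuous", 3600,
                                                sample_times = c(2, 60),
                                                n_replicates = 1),
                          noise_model(cv = 0, seed = 1))
  expect_error(fit_kinetics(ds2, fit_options("extended")),
               "invalid design")
})

test_that("an extended fit on standard-truth data finds a negligible k4", {
  ds <- generate_dataset(default_truth(), default_design(),
                         noise_model(cv = 0.05, seed = 11))
  fit <- suppressWarnings(
    fit_kinetics(ds, fit_options("extended", n_starts = 6, seed = 11)))
  ci <- wald_ci(fit)
  k4_row <- ci[ci$parameter == "k4", ]
  # the non-catalytic channel is compatible with values far below k2
  expect_lt(k4_row$lower, 1e-3 * fit$estimates$k2)
})

test_that("log-scale standard errors grow with the noise level", {
  mean_se <- function(cv) {
    mean(vapply(1:4, function(s) {
      ds <- generate_dataset(default_truth(), default_design(),
                             noise_model(cv = cv, seed = 40 + s))
      fit <- suppressWarnings(
        fit_kinetics(ds, fit_options(n_starts = 2, seed = s)))
      fit$log_se[["k1"]]
    }, numeric(1)))
  }
  expect_lt(mean_se(0.02), mean_se(0.1))
})

test_that("initial-response refinement searches a symmetric grid and never hurts", {
  ds <- generate_dataset(default_truth(), default_design(),
                         noise_model(cv = 0, seed = 1))
  fit <- suppressWarnings(fit_kinetics(ds, fit_options(n_starts = 4, seed = 1)))
  # degenerate zero replicate SD: refinement keeps the experimental mean
  expect_message(refined0 <- refine_initial_value(ds, fit), "degenerate")
  expect_equal(refined0$s0_fit, fit$s0_fit)

  # with a supplied global SD the refinement picks a grid candidate (or
  # keeps the incumbent) and cannot worsen the residual SD
  s_glob <- 5e-5
  first <- ds$observations$peak_area[ds$observations$time_min == 2]
  m <- mean(first)
  grid <- seq(m - 3 * s_glob, m + 3 * s_glob, length.out = 20)
  refined <- suppressWarnings(
    refine_initial_value(ds, fit, sd_global = s_glob))
  expect_lte(residual_sd(refined), residual_sd(fit))
  expect_true(any(abs(grid - refined$s0_fit) < 1e-12) ||
                refined$s0_fit == fit$s0_fit)
})

test_that("refinement recovers the true initial response from noisy data", {
  ds <- generate_dataset(default_truth(), default_design(),
                         noise_model(cv = 0.05, seed = 21))
  fit <- suppressWarnings(fit_kinetics(ds, fit_options(n_starts = 4, seed = 21)))
  refined <- suppressWarnings(refine_initial_value(ds, fit))
  first <- ds$observations$peak_area[ds$observations$time_min == 2]
  spacing <- 6 * sd(first) / 19
  # the refit-selected initial response stays within two grid steps of truth
  expect_lt(abs(refined$s0_fit - 5e-4), 2 * spacing + 1e-12)
})
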