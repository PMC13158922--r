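#' Log-scale Wald confidence intervals for the rate constants
#'
#' Intervals `exp(log(k_hat) +/- z * SE_log)` computed on the log-parameter
#' scale and back-transformed, which preserves positivity of the bounds.
#'
#' @param fit a converged `kinetic_fit`.
#' @param level confidence level (default 0.95).
#' @return Data frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`, `unbounded` (TRUE where the standard error is not finite).
#' @examples
#' # SE_log = 1 around estimate 1 gives (exp(-1.96), exp(1.96))
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- exp(fit$log_par)
  se <- fit$log_se
  bad <- !is.finite(se)
  lower <- ifelse(bad, 0, exp(fit$log_par - z * se))
  upper <- ifelse(bad, Inf, exp(fit$log_par + z * se))
  data.frame(parameter = names(est), estimate = unname(est),
             lower = unname(lower), upper = unname(upper),
             unbounded = unname(bad), row.names = NULL)
}

#' Parametric Monte Carlo confidence bands for the trajectories
#'
#' Draws `n_draws` parameter sets around the fitted values, re-integrates
#' the ODE system for each, and returns the pointwise 2.5th and 97.5th
#' percentile envelopes of every species (95% bands by default).
#'
#' Sampling modes: `"lognormal"` (default) draws the log parameters from
#' independent normals centered at the fitted log values with SDs equal to
#' the log-scale standard errors, which keeps every draw positive;
#' `"natural"` draws on the original scale (SD `k_hat * SE_log`, the delta
#' method) truncated at zero. `correlated = TRUE` replaces the independent
#' draws by multivariate normal draws using the fitted log-scale
#' covariance.
#'
#' Draws whose integration fails are dropped and counted; more than 50%
#' failures aborts.
#'
#' @param fit a `kinetic_fit` with finite standard errors.
#' @param descriptor descriptor to simulate under; defaults to the fitted
#'   response-scale descriptor.
#' @param n_draws number of parameter draws.
#' @param seed RNG seed.
#' @param level band level.
#' @param scale `"lognormal"` or `"natural"` sampling.
#' @param correlated use the fitted covariance instead of independent SDs.
#' @param times output grid in seconds (default 601 points).
#' @return Object of class `mc_bands`: list with `times`, per-species
#'   matrices in `lower` and `upper`, the best-fit trajectory `center`,
#'   `n_draws`, `n_failed`, `seed`.
#' @export
monte_carlo_bands <- function(fit, descriptor = NULL, n_draws = 100,
                              seed = 1L, level = 0.95,
                              scale = c("lognormal", "natural"),
                              correlated = FALSE, times = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  scale <- match.arg(scale)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (any(!is.finite(fit$log_se)))
    stop("fit has non-finite standard errors", call. = FALSE)
  if (is.null(descriptor))
    descriptor <- .fit_descriptor(fit$dataset$descriptor, fit$s0_fit)
  if (is.null(times)) times <- seq(0, descriptor$t_max, length.out = 601)
  np <- fit$n_params
  draws <- with_seed(seed, {
    if (correlated) {
      L <- chol(fit$covariance + diag(1e-30, np))
      z <- matrix(stats::rnorm(n_draws * np), n_draws, np)
      sweep(z %*% L, 2, fit$log_par, "+")
    } else {
      matrix(stats::rnorm(n_draws * np, mean = rep(fit$log_par, each = n_draws),
                          sd = rep(fit$log_se, each = n_draws)),
             n_draws, np)
    }
  })
  colnames(draws) <- names(fit$log_par)
  arr <- array(NA_real_, c(n_draws, length(times), length(.species)))
  n_failed <- 0L
  for (i in seq_len(n_draws)) {
    k <- if (scale == "lognormal") exp(draws[i, ])
    else stats::setNames(
      pmax(0, exp(fit$log_par) + (draws[i, ] - fit$log_par) *
             exp(fit$log_par)),  # natural-scale offset, truncated at 0
      names(fit$log_par))
    params <- tryCatch(.as_rate_constants(k, fit$variant),
                       error = function(e) NULL)
    traj <- if (is.null(params)) NULL else
      tryCatch(integrate_kinetics(params, descriptor, times = times),
               error = function(e) NULL)
    if (is.null(traj)) { n_failed <- n_failed + 1L; next }
    arr[i, , ] <- as.matrix(traj[.species])
  }
  if (n_failed > n_draws / 2)
    stop("more than half of the Monte Carlo draws failed to integrate",
         call. = FALSE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  lower <- upper <- matrix(NA_real_, length(times), length(.species),
                           dimnames = list(NULL, .species))
  for (sp in seq_along(.species)) {
    q <- apply(arr[, , sp, drop = FALSE], 2, stats::quantile, probs = probs,
               na.rm = TRUE)
    lower[, sp] <- q[1, ]
    upper[, sp] <- q[2, ]
  }
  center <- integrate_kinetics(fit$estimates, descriptor, times = times)
  structure(list(times = times, lower = lower, upper = upper,
                 center = center, n_draws = n_draws, n_failed = n_failed,
                 seed = as.integer(seed), level = level),
            class = "mc_bands")
}

#' @export
print.mc_bands <- function(x, ...) {
  cat(sprintf("Monte Carlo bands: %d draws (%d failed), %.0f%% level, %d grid points\n",
              x$n_draws, x$n_failed, 100 * x$level, length(x$times)))
  invisible(x)
}

#' Export Monte Carlo bands as tidy CSV
#'
#' Long format with columns `time_s`, `species`, `lower`, `upper`.
#' @param bands an `mc_bands` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bands <- function(bands, path) {
  stopifnot(inherits(bands, "mc_bands"))
  long <- do.call(rbind, lapply(.species, function(sp)
    data.frame(time_s = bands$times, species = sp,
               lower = bands$lower[, sp], upper = bands$upper[, sp])))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
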