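#' Standardized residuals of a kinetic fit
#'
#' Each raw residual divided by the pooled residual scale
#' `sigma_hat = sqrt(SSR / (n_obs - n_params))`, reported against both
#' reaction time and fitted value so systematic bias and heteroscedasticity
#' can be inspected. No leverage correction is applied.
#'
#' @param fit a converged `kinetic_fit`.
#' @param dataset dataset the fit was obtained on (defaults to the one
#'   stored in the fit).
#' @return Data frame with columns `replicate`, `time_min`, `fitted`,
#'   `residual`, `standardized`.
#' @export
standardized_residuals <- function(fit, dataset = fit$dataset) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (fit$n_obs == fit$n_params)
    stop("residual scale undefined: n_obs equals n_params", call. = FALSE)
  sigma <- residual_sd(fit)
  obs <- fit$observations
  data.frame(replicate = obs$replicate, time_min = obs$time_min,
             fitted = fit$fitted, residual = fit$residuals,
             standardized = fit$residuals / sigma, row.names = NULL)
}

#' Slope of |residual| against fitted value
#'
#' Simple heteroscedasticity diagnostic: a positive slope means larger
#' responses carry larger absolute deviations, the signature of
#' multiplicative measurement noise.
#'
#' @param fit a `kinetic_fit`.
#' @return Least-squares slope (area per area, dimensionless).
#' @export
heteroscedasticity_slope <- function(fit) {
  r <- standardized_residuals(fit)
  unname(stats::coef(stats::lm(abs(residual) ~ fitted, data = r))[2])
}

#' Parameter correlation matrix and identifiability flags
#'
#' Normalizes the fitted log-scale covariance to a correlation matrix and
#' flags parameter pairs whose absolute correlation exceeds `threshold`,
#' the practical-identifiability warning sign of strongly interdependent
#' estimates. By default the matrix is restricted to k1-k3 so reports are
#' comparable between standard and extended fits.
#'
#' @param fit a `kinetic_fit`.
#' @param threshold flagging threshold on |r|.
#' @param core_only restrict to k1, k2, k3.
#' @return List with `correlation` (matrix), `high_corr_pairs` (data frame
#'   `par_a`, `par_b`, `r`), `undefined` (parameters with zero variance).
#' @export
parameter_correlation <- function(fit, threshold = 0.9, core_only = TRUE) {
  stopifnot(inherits(fit, "kinetic_fit"))
  keep <- if (core_only) intersect(c("k1", "k2", "k3"), names(fit$log_par))
  else names(fit$log_par)
  v <- fit$covariance[keep, keep, drop = FALSE]
  d <- sqrt(diag(v))
  undefined <- names(d)[d == 0]
  corr <- v / tcrossprod(pmax(d, .Machine$double.xmin))
  diag(corr) <- 1
  corr[] <- pmin(pmax(corr, -1), 1)  # clamp rounding spill
  pairs <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  high <- data.frame(par_a = rownames(corr)[pairs[, 1]],
                     par_b = colnames(corr)[pairs[, 2]],
                     r = corr[pairs], row.names = NULL)
  high <- high[!(high$par_a %in% undefined | high$par_b %in% undefined), ,
               drop = FALSE]
  list(correlation = corr, high_corr_pairs = high, undefined = undefined)
}

#' Akaike information criterion of a least-squares fit
#'
#' Gaussian SSR form with additive constants dropped:
#' `AIC = n * ln(SSR / n) + 2 p`. Only differences between models fitted to
#' the same data are meaningful.
#'
#' @param fit a `kinetic_fit`.
#' @return AIC value; `-Inf` (with a message) when SSR is exactly zero.
#' @export
aic_fit <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (fit$ssr == 0) {
    message("SSR is exactly zero; AIC reported as -Inf")
    return(-Inf)
  }
  fit$n_obs * log(fit$ssr / fit$n_obs) + 2 * fit$n_params
}

#' Adjusted coefficient of determination
#'
#' `R2_adj = 1 - [SSR / (n - p)] / [TSS / (n - 1)]` with the total sum of
#' squares about the observed mean, computed on the fitted (peak-area)
#' scale.
#'
#' @param fit a `kinetic_fit`.
#' @param dataset dataset the fit was obtained on.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(fit, dataset = fit$dataset) {
  stopifnot(inherits(fit, "kinetic_fit"))
  y <- fit$observations$peak_area
  tss <- sum((y - mean(y))^2)
  1 - (fit$ssr / (fit$n_obs - fit$n_params)) / (tss / (fit$n_obs - 1))
}

#' Full diagnostics report for a fit
#'
#' @param fit a `kinetic_fit`.
#' @param threshold correlation flagging threshold.
#' @return List of class `diagnostics_report` with the standardized
#'   residual table, correlation structure, AIC, adjusted R-squared and the
#'   heteroscedasticity slope.
#' @export
diagnostics_report <- function(fit, threshold = 0.9) {
  corr <- parameter_correlation(fit, threshold = threshold)
  structure(list(standardized_residuals = standardized_residuals(fit),
                 correlation = corr$correlation,
                 high_corr_pairs = corr$high_corr_pairs,
                 undefined = corr$undefined,
                 aic = aic_fit(fit), r2_adj = adjusted_r2(fit),
                 heteroscedasticity_slope = heteroscedasticity_slope(fit)),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("Fit diagnostics: AIC = %.2f, adj. R2 = %.4f\n", x$aic,
              x$r2_adj))
  if (nrow(x$high_corr_pairs))
    cat(sprintf("  %d parameter pair(s) with |r| above threshold\n",
                nrow(x$high_corr_pairs)))
  invisible(x)
}

#' Choose between the standard and extended model
#'
#' Parsimony rule: the extended (non-catalytic pathway) model is selected
#' only if it improves AIC by at least `delta_aic_min` AND the fitted k4
#' channel is non-negligible, quantified as
#' `k4 * max([S][tBuOOH]) > frac_min * k2 * max([S][FeTPPS*])` along the
#' fitted extended trajectory. Ties and negligible k4 retain the standard
#' model.
#'
#' @param fit_standard,fit_extended fits of both variants to the same data.
#' @param delta_aic_min required AIC improvement.
#' @param frac_min pathway-flux fraction below which k4 counts as
#'   negligible.
#' @return List with `variant` (`"standard"` or `"extended"`), `aic_standard`,
#'   `aic_extended`, `k4_flux_fraction`, `rationale`.
#' @export
select_model <- function(fit_standard, fit_extended, delta_aic_min = 2,
                         frac_min = 0.05) {
  stopifnot(inherits(fit_standard, "kinetic_fit"),
            inherits(fit_extended, "kinetic_fit"))
  if (fit_standard$variant != "standard" || fit_extended$variant != "extended")
    stop("pass the standard fit first and the extended fit second",
         call. = FALSE)
  if (!identical(dim(fit_standard$observations),
                 dim(fit_extended$observations)) ||
      !isTRUE(all.equal(fit_standard$observations$peak_area,
                        fit_extended$observations$peak_area)))
    stop("fits were not obtained on the same data", call. = FALSE)
  if (!fit_standard$converged || !fit_extended$converged)
    stop("model selection deferred: unconverged fit", call. = FALSE)
  a_std <- aic_fit(fit_standard)
  a_ext <- aic_fit(fit_extended)
  fd <- .fit_descriptor(fit_extended$dataset$descriptor, fit_extended$s0_fit)
  # near-degenerate estimates can be too stiff for the default dense-output
  # integration; fall back to the observation grid at the (tighter)
  # tolerances the fit itself was evaluated under
  traj <- tryCatch(integrate_kinetics(fit_extended$estimates, fd),
                   error = function(e) NULL)
  if (is.null(traj)) {
    obs_times <- sort(unique(c(0, fit_extended$observations$time_min * 60)))
    traj <- integrate_kinetics(fit_extended$estimates, fd, times = obs_times,
                               rtol = 1e-12, atol = 1e-13 * fit_extended$s0_fit)
  }
  k <- fit_extended$estimates
  flux_cat <- k$k2 * max(traj$substrate * traj$fetpps_star)
  flux_noncat <- k$k4 * max(traj$substrate * traj$tbuooh)
  frac <- if (flux_cat > 0) flux_noncat / flux_cat else
    (if (flux_noncat > 0) Inf else 0)
  improved <- a_ext <= a_std - delta_aic_min
  nonneg <- frac > frac_min
  variant <- if (improved && nonneg) "extended" else "standard"
  rationale <- if (!improved)
    "extended model does not improve AIC enough"
  else if (!nonneg)
    "fitted non-catalytic pathway is negligible"
  else "extended model improves AIC and the k4 pathway is substantial"
  list(variant = variant, aic_standard = a_std, aic_extended = a_ext,
       k4_flux_fraction = frac, rationale = rationale)
}
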