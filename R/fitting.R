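#' Fitting options
#'
#' Controls the nonlinear least-squares protocol: model variant, multistart
#' initialization in log-parameter space, Levenberg-Marquardt convergence
#' settings and the optional grid refinement of the initial response.
#'
#' Starts are drawn log-uniformly over `start_box` times a dimensional
#' scale inferred from the data (`1 / (s0_area * t_max)`, the natural
#' magnitude of a bimolecular constant when concentrations are measured in
#' response units); the first start is a fixed, data-scaled guess so that a
#' single-start fit is deterministic without a seed.
#'
#' @param variant `"standard"` (k1-k3) or `"extended"` (adds k4).
#' @param n_starts number of multistart initial points (>= 1).
#' @param start_box multiplier range of the log-uniform start draws.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param ftol relative sum-of-squares convergence tolerance.
#' @param gtol gradient (orthogonality) convergence tolerance.
#' @param seed seed for the random starts.
#' @param refine_s0 refine the initial response over the grid of
#'   [refine_initial_value()] after the multistart fit.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(variant = c("standard", "extended"), n_starts = 16,
                        start_box = c(1e-3, 1e3), max_iter = 500,
                        ftol = 1e-10, gtol = 1e-8, seed = 1L,
                        refine_s0 = FALSE) {
  variant <- match.arg(variant)
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  if (length(start_box) != 2 || !all(is.finite(start_box)) ||
      start_box[1] <= 0 || start_box[1] >= start_box[2])
    stop("start_box must be finite with 0 < lower < upper", call. = FALSE)
  structure(list(variant = variant, n_starts = as.integer(n_starts),
                 start_box = start_box, max_iter = as.integer(max_iter),
                 ftol = ftol, gtol = gtol, seed = as.integer(seed),
                 refine_s0 = isTRUE(refine_s0)),
            class = "fit_options")
}

.par_names <- function(variant)
  if (variant == "extended") c("k1", "k2", "k3", "k4") else c("k1", "k2", "k3")

.as_rate_constants <- function(k, variant) {
  if (variant == "extended")
    rate_constants(k1 = k[["k1"]], k2 = k[["k2"]], k3 = k[["k3"]],
                   k4 = k[["k4"]])
  else rate_constants(k1 = k[["k1"]], k2 = k[["k2"]], k3 = k[["k3"]])
}

# Descriptor used inside the objective: the model is integrated directly on
# the response (peak-area) scale, with the initial response s0_area playing
# the role of the initial substrate concentration. Rescaling areas rescales
# the bimolecular constants reciprocally but leaves the curve shapes and
# normalized residuals unchanged, so fitting areas directly is legitimate.
.fit_descriptor <- function(descriptor, s0_area) {
  experiment_descriptor(
    s0 = s0_area, eqv = descriptor$eqv, mode = descriptor$mode,
    t_max = descriptor$t_max, sample_times = descriptor$sample_times,
    n_replicates = descriptor$n_replicates, response_scale = 1)
}

# Pooled earliest-time observations: the experimental stand-in for the
# initial response before refinement.
.earliest_obs <- function(dataset) {
  obs <- substrate_observations(dataset)
  first <- min(obs$time_min)
  obs$peak_area[obs$time_min == first]
}

#' Least-squares residuals of the kinetic model
#'
#' Residuals `observed - predicted` of the substrate peak areas, pooled
#' over replicates and times in fixed (replicate, time) order. Parameters
#' enter on the log scale, which enforces positivity and is the scale on
#' which standard errors and Wald intervals are computed. If the ODE
#' integration fails at a parameter point, a large finite penalty residual
#' is returned so the optimizer can retreat.
#'
#' @param log_params named log rate constants (`k1`, `k2`, `k3`, and `k4`
#'   for the extended variant).
#' @param dataset a `kinetic_dataset`.
#' @param descriptor experiment descriptor; defaults to the dataset's.
#' @param variant model variant.
#' @param s0_area initial response; defaults to the mean earliest-time
#'   observation.
#' @return Numeric residual vector of length
#'   `n_replicates * length(sample_times)`.
#' @export
kinetic_objective <- function(log_params, dataset,
                              descriptor = dataset$descriptor,
                              variant = c("standard", "extended"),
                              s0_area = NULL) {
  variant <- match.arg(variant)
  obs <- substrate_observations(dataset)
  if (is.null(s0_area)) s0_area <- .nominal_s0(descriptor)
  pred <- .predict_areas(exp(log_params), variant, descriptor, s0_area, obs)
  obs$peak_area - pred
}

# Nominal initial response declared by the experiment descriptor; the grid
# refinement (refine_initial_value) re-estimates it from the data when the
# declared value is not trusted.
.nominal_s0 <- function(descriptor) descriptor$s0 * descriptor$response_scale

# Predicted substrate areas at the observation rows; penalty on failure.
# Tolerances are well below the simulator defaults: the least-squares
# Jacobian is differenced over tiny log-parameter steps, and integration
# error at the usual 1e-8 relative tolerance is large enough to corrupt it
# along the weakly identified parameter combinations.
.predict_areas <- function(k, variant, descriptor, s0_area, obs,
                           penalty_env = NULL, rtol = 1e-11, atol = 1e-12) {
  k <- stats::setNames(k, .par_names(variant))
  params <- .as_rate_constants(k, variant)
  fd <- .fit_descriptor(descriptor, s0_area)
  traj <- tryCatch(
    integrate_kinetics(params, fd,
                       times = sort(unique(c(0, obs$time_min * 60))),
                       rtol = rtol, atol = atol * s0_area),
    error = function(e) e)
  if (inherits(traj, "error")) {
    if (!is.null(penalty_env)) penalty_env$failures <- penalty_env$failures + 1
    return(rep(-1e3 * max(s0_area, max(obs$peak_area)), nrow(obs)))
  }
  substrate_at(traj, obs$time_min * 60)
}

#' Fit the kinetic model to a dataset
#'
#' Multistart Levenberg-Marquardt least squares on the log rate constants
#' (via `minpack.lm::nls.lm`), minimizing the sum of squared differences
#' between observed substrate peak areas and model-predicted substrate
#' responses. The best of `n_starts` local fits is kept. Standard errors of
#' the log parameters come from the Gauss-Newton covariance
#' `sigma^2 (J'J)^-1` with `sigma^2 = SSR / (n_obs - n_params)`; a singular
#' `J'J` is inverted by pseudo-inverse and flagged as an identifiability
#' warning. With `refine_s0 = TRUE` the initial response is subsequently
#' refined by [refine_initial_value()].
#'
#' @param dataset a `kinetic_dataset` with a substrate channel and at least
#'   two distinct time points.
#' @param options a [fit_options()].
#' @return An object of class `kinetic_fit` with elements `estimates`
#'   ([rate_constants()]), `log_par`, `log_se`, `covariance` (log scale),
#'   `ssr`, `n_obs`, `n_params`, `s0_fit`, `converged`, `variant`,
#'   `identifiability_warning`, `residuals`, `fitted`, `start_ssr` (the
#'   objective value at every multistart initial point), and the dataset.
#' @param extra_starts optional list of additional log-parameter start
#'   vectors appended to the generated multistart set (used e.g. to warm
#'   start the extended variant from a standard fit).
#' @rdname fit_kinetics
#' @export
fit_kinetics <- function(dataset, options = fit_options(),
                         extra_starts = NULL) {
  stopifnot(inherits(dataset, "kinetic_dataset"),
            inherits(options, "fit_options"))
  obs <- substrate_observations(dataset)
  if (length(unique(obs$time_min)) < 2)
    stop("need at least two distinct time points", call. = FALSE)
  pnames <- .par_names(options$variant)
  if (nrow(obs) <= length(pnames))
    stop("more parameters than observations: invalid design", call. = FALSE)
  s0_area <- .nominal_s0(dataset$descriptor)
  fit <- .fit_at_s0(dataset, obs, options, s0_area,
                    extra_starts = extra_starts)
  if (options$refine_s0) fit <- refine_initial_value(dataset, fit)
  fit
}

#' Fit both model variants with symmetric nested warm starts
#'
#' Fits the standard model, then the extended model with the standard
#' estimates (plus a vanishing k4) appended to its multistart set, and
#' finally re-polishes the standard model from the extended optimum's
#' k1-k3, keeping whichever standard fit is better. The extended model
#' contains the standard one at k4 = 0, so each optimum is a competitive
#' start for the other variant; warm-starting in both directions keeps the
#' AIC comparison between the two fits an honest comparison between the
#' two models rather than between two optimizer runs of unequal luck.
#'
#' @param dataset a `kinetic_dataset`.
#' @param options a [fit_options()]; its `variant` field is ignored.
#' @return List with elements `standard` and `extended` (two `kinetic_fit`
#'   objects on the same data).
#' @export
fit_both_variants <- function(dataset, options = fit_options()) {
  opts_std <- options; opts_std$variant <- "standard"
  opts_ext <- options; opts_ext$variant <- "extended"
  fit_std <- fit_kinetics(dataset, opts_std)
  mu <- 1 / (.nominal_s0(dataset$descriptor) * dataset$descriptor$t_max)
  opts_warm_std <- opts_std; opts_warm_std$n_starts <- 1L
  opts_warm_ext <- opts_ext; opts_warm_ext$n_starts <- 1L
  warm <- c(fit_std$log_par, k4 = log(1e-3 * mu))
  fit_ext <- fit_kinetics(dataset, opts_ext, extra_starts = list(warm))
  # alternate warm starts between the nested pair until neither improves;
  # warm restarts from an optimum converge immediately, so extra rounds
  # are nearly free once the pair is consistent
  for (round in 1:3) {
    improved <- FALSE
    back <- tryCatch(
      fit_kinetics(dataset, opts_warm_std,
                   extra_starts = list(fit_ext$log_par[c("k1", "k2", "k3")])),
      error = function(e) NULL)
    if (!is.null(back) && back$ssr < fit_std$ssr * (1 - 1e-10)) {
      fit_std <- back; improved <- TRUE
    }
    fwd <- tryCatch(
      fit_kinetics(dataset, opts_warm_ext,
                   extra_starts = list(c(fit_std$log_par,
                                         k4 = log(1e-3 * mu)))),
      error = function(e) NULL)
    if (!is.null(fwd) && fwd$ssr < fit_ext$ssr * (1 - 1e-10)) {
      fit_ext <- fwd; improved <- TRUE
    }
    if (!improved) break
  }
  list(standard = fit_std, extended = fit_ext)
}

# Core multistart fit at a fixed initial response.
.fit_at_s0 <- function(dataset, obs, options, s0_area, starts = NULL,
                       extra_starts = NULL) {
  descriptor <- dataset$descriptor
  pnames <- .par_names(options$variant)
  np <- length(pnames)
  mu <- 1 / (s0_area * descriptor$t_max)  # dimensional scale of the constants
  if (is.null(starts)) {
    first <- log(mu * c(1, 10, 0.1, 0.01)[seq_len(np)])
    starts <- list(first)
    if (options$n_starts > 1) {
      draws <- with_seed(options$seed, matrix(
        stats::runif((options$n_starts - 1) * np,
                     log(options$start_box[1]), log(options$start_box[2])),
        ncol = np))
      for (i in seq_len(nrow(draws)))
        starts[[i + 1]] <- draws[i, ] + log(mu)
    }
    starts <- c(starts, extra_starts)
  }
  penalty_env <- new.env(); penalty_env$failures <- 0L
  # Two-stage optimization: every start is explored at moderate ODE
  # tolerance (cheap), then the best candidate is polished with a much
  # tighter integration so the difference Jacobian stays clean along the
  # weakly identified valley of the SSR surface.
  resid_explore <- function(lp) {
    obs$peak_area - .predict_areas(exp(lp), options$variant, descriptor,
                                   s0_area, obs, penalty_env,
                                   rtol = 1e-8, atol = 1e-10)
  }
  resid_polish <- function(lp) {
    obs$peak_area - .predict_areas(exp(lp), options$variant, descriptor,
                                   s0_area, obs, penalty_env,
                                   rtol = 1e-12, atol = 1e-13)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(options$max_iter, 1024),
                                     ftol = options$ftol, gtol = options$gtol,
                                     ptol = 1e-15)
  best <- NULL
  start_ssr <- numeric(length(starts))
  for (i in seq_along(starts)) {
    start_ssr[i] <- sum(resid_explore(starts[[i]])^2)
    res <- tryCatch(minpack.lm::nls.lm(par = starts[[i]], fn = resid_explore,
                                       control = ctrl),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("all multistart fits failed", call. = FALSE)
  polished <- tryCatch(minpack.lm::nls.lm(par = best$par, fn = resid_polish,
                                          control = ctrl),
                       error = function(e) NULL)
  if (!is.null(polished) && polished$deviance <= best$deviance)
    best <- polished
  if (penalty_env$failures > 0)
    warning(sprintf("%d parameter points failed to integrate and were penalized",
                    penalty_env$failures), call. = FALSE)
  lp <- stats::setNames(best$par, pnames)
  # evaluate the optimum with the same residual functions that produced it:
  # extremely stiff ridge points can integrate at one tolerance setting
  # and fail at another
  pf <- penalty_env$failures
  r <- resid_polish(lp)
  tol <- c(rtol = 1e-12, atol = 1e-13)
  if (penalty_env$failures > pf) {   # polish tolerances fail here; the
    r <- resid_explore(lp)           # optimum came from the explore stage
    tol <- c(rtol = 1e-8, atol = 1e-10)
  }
  ssr <- sum(r^2)
  n <- nrow(obs)
  sigma2 <- ssr / (n - np)
  J <- .log_jacobian(lp, options$variant, descriptor, s0_area, obs,
                     rtol = tol[["rtol"]], atol = tol[["atol"]])
  jtj <- crossprod(J)
  inv <- .pinv(jtj)
  covariance <- sigma2 * inv$inverse
  dimnames(covariance) <- list(pnames, pnames)
  log_se <- sqrt(pmax(diag(covariance), 0))
  structure(list(
    estimates = .as_rate_constants(exp(lp), options$variant),
    log_par = lp, log_se = stats::setNames(log_se, pnames),
    covariance = covariance, ssr = ssr, n_obs = n, n_params = np,
    s0_fit = s0_area, converged = best$info %in% 1:4,
    variant = options$variant,
    identifiability_warning = inv$singular,
    residuals = r, fitted = obs$peak_area - r,
    observations = obs, start_ssr = start_ssr,
    options = options, dataset = dataset),
    class = "kinetic_fit")
}

# Forward-difference Jacobian of the predicted areas w.r.t. log parameters.
.log_jacobian <- function(lp, variant, descriptor, s0_area, obs, h = 1e-6,
                          rtol = 1e-11, atol = 1e-12) {
  base <- .predict_areas(exp(lp), variant, descriptor, s0_area, obs,
                         rtol = rtol, atol = atol)
  J <- matrix(0, nrow(obs), length(lp))
  for (j in seq_along(lp)) {
    lpj <- lp; lpj[j] <- lpj[j] + h
    J[, j] <- (.predict_areas(exp(lpj), variant, descriptor, s0_area, obs,
                              rtol = rtol, atol = atol) - base) / h
  }
  J
}

# SVD pseudo-inverse; reports whether truncation (rank deficiency) occurred.
.pinv <- function(m, rtol = 1e-10) {
  s <- svd(m)
  keep <- s$d > rtol * max(s$d)
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inverse = inv, singular = any(!keep))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit (%s variant): SSR = %.4g on %d obs, converged: %s\n",
              x$variant, x$ssr, x$n_obs, x$converged))
  est <- unlist(x$estimates)
  tab <- data.frame(estimate = est, log_se = x$log_se)
  print(tab)
  if (x$identifiability_warning)
    cat("NOTE: singular information matrix; pseudo-inverse covariance\n")
  invisible(x)
}

#' Residual standard deviation of a fit
#' @param fit a `kinetic_fit`.
#' @return `sqrt(SSR / (n_obs - n_params))`.
#' @export
residual_sd <- function(fit) sqrt(fit$ssr / (fit$n_obs - fit$n_params))

#' Refine the initial response over a perturbation grid
#'
#' Re-estimates the model's initial response (the t = 0 peak area) by
#' evaluating `n_grid` evenly spaced candidates within `width` global
#' standard deviations of the experimental mean of the earliest-time
#' observations, refitting the rate constants at each (warm-started from
#' the incoming fit), and keeping whichever candidate minimizes the
#' residual standard deviation. The incoming fit is retained if no
#' candidate improves on it. The "global SD" is taken as the replicate SD
#' of the earliest sampled time unless `sd_global` is supplied.
#'
#' @param dataset the `kinetic_dataset` the fit was obtained on.
#' @param fit a `kinetic_fit`.
#' @param n_grid number of candidate initial responses.
#' @param width half-width of the grid in global SDs.
#' @param sd_global overrides the experimental SD.
#' @return The refined `kinetic_fit` (with `s0_fit` updated).
#' @export
refine_initial_value <- function(dataset, fit, n_grid = 20, width = 3,
                                 sd_global = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  first <- .earliest_obs(dataset)
  m <- mean(first)
  s <- if (is.null(sd_global)) stats::sd(first) else sd_global
  if (!is.finite(s) || s == 0) {
    message("degenerate zero SD of the earliest observations; ",
            "initial response kept at the experimental mean")
    return(fit)
  }
  candidates <- seq(m - width * s, m + width * s, length.out = n_grid)
  candidates <- candidates[candidates > 0]
  obs <- substrate_observations(dataset)
  warm <- fit$options
  best <- fit
  for (s0 in candidates) {
    cand <- tryCatch(
      .fit_at_s0(dataset, obs, warm, s0, starts = list(fit$log_par)),
      error = function(e) NULL)
    if (!is.null(cand) && residual_sd(cand) < residual_sd(best)) best <- cand
  }
  best
}
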