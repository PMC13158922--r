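#' Experiment descriptor
#'
#' Describes one kinetic run: initial substrate concentration, oxidant
#' charge and dosing mode, reaction duration, the chromatographic sampling
#' grid and replication, and the detector response scale relating substrate
#' concentration to peak area.
#'
#' @param s0 initial substrate concentration (> 0).
#' @param eqv oxidant equivalents (> 0).
#' @param mode `"one_shot"` or `"continuous"`.
#' @param t_max reaction duration in seconds.
#' @param sample_times observation times in minutes, strictly increasing,
#'   all within the reaction window.
#' @param n_replicates number of parallel runs (>= 1).
#' @param response_scale peak-area units per unit substrate concentration
#'   (> 0). With the default 1 peak areas are numerically equal to
#'   concentrations.
#' @return An object of class `experiment_descriptor`; its `$schedule` field
#'   holds the matching [dosing_schedule()].
#' @seealso [default_design()] for the standard continuous-dosing design.
#' @export
experiment_descriptor <- function(s0, eqv, mode, t_max, sample_times,
                                  n_replicates = 3, response_scale = 1) {
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  if (!is.finite(response_scale) || response_scale <= 0)
    stop("response_scale must be > 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(sample_times) < 1 || any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing", call. = FALSE)
  if (any(sample_times < 0) || any(sample_times * 60 > t_max + 1e-9))
    stop("sample_times must lie within [0, t_max]", call. = FALSE)
  schedule <- dosing_schedule(mode, eqv = eqv, t_max = t_max, s0 = s0)
  structure(list(s0 = s0, eqv = eqv, mode = schedule$mode, t_max = t_max,
                 sample_times = sample_times,
                 n_replicates = as.integer(n_replicates),
                 response_scale = response_scale, schedule = schedule),
            class = "experiment_descriptor")
}

#' @export
print.experiment_descriptor <- function(x, ...) {
  cat(sprintf(
    "Kinetic design: s0 = %g, %g eqv oxidant (%s), t_max = %g s\n",
    x$s0, x$eqv, x$mode, x$t_max))
  cat(sprintf("  %d sample times (min): %s; %d replicate(s)\n",
              length(x$sample_times),
              paste(x$sample_times, collapse = ", "), x$n_replicates))
  invisible(x)
}

#' Integrate the kinetic ODE system
#'
#' Solves the catalytic-cycle rate equations with a stiff-capable solver
#' (`deSolve::ode`, lsoda, compiled right-hand side). The system can be
#' stiff when substrate oxidation is much faster than catalyst activation,
#' so tight default tolerances are used. Small negative undershoots are
#' clipped to zero on output; an undershoot larger than `1e3 * atol`
#' aborts with an integration-failure error.
#'
#' @param params a [rate_constants()] object.
#' @param descriptor an [experiment_descriptor()].
#' @param times output grid in seconds; default 601 evenly spaced points
#'   over the reaction window.
#' @param rtol,atol relative and absolute integration tolerances.
#' @return A `trajectory` object: data frame with column `time_s` and one
#'   column per tracked species, plus attributes `descriptor` and `params`.
#' @export
integrate_kinetics <- function(params, descriptor, times = NULL,
                               rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "rate_constants"),
            inherits(descriptor, "experiment_descriptor"))
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (is.null(times))
    times <- seq(0, descriptor$t_max, length.out = 601)
  if (times[1] > 0) times <- c(0, times)
  if (any(times < 0) || any(times > descriptor$t_max + 1e-9))
    stop("output grid must lie within [0, t_max]", call. = FALSE)
  y0 <- initial_conditions(descriptor$s0, descriptor$schedule)
  sol <- deSolve::ode(y = y0, times = times, func = "mimox_derivs",
                      parms = .c_parms(params, descriptor$schedule$delta),
                      dllname = "mimoxkin", initfunc = "mimox_init",
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 10000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  out <- as.data.frame(unclass(sol))
  names(out)[1] <- "time_s"
  vals <- as.matrix(out[.species])
  worst <- min(vals)
  if (worst < -1e3 * atol)
    stop(sprintf("integration undershoot %.3g exceeds tolerance", worst),
         call. = FALSE)
  vals[vals < 0] <- 0
  out[.species] <- vals
  structure(out, descriptor = descriptor, params = params,
            class = c("trajectory", "data.frame"))
}

#' Predicted peak areas at the sampling times
#'
#' Maps the simulated substrate concentration to the chromatographic
#' observation scale: `response_scale * [S](t)` interpolated at the
#' descriptor's sample times. Metabolite channels use `metabolite_scale`
#' times the substrate response scale (their molar response factors are
#' unknown in practice, so they are never fitted).
#'
#' @param traj a `trajectory` from [integrate_kinetics()].
#' @param descriptor the experiment descriptor; defaults to the one the
#'   trajectory was integrated under.
#' @param channels subset of `"substrate"`, `"metabolite_cat"`,
#'   `"metabolite_noncat"` to report.
#' @param metabolite_scale response scale of the metabolite channels
#'   relative to the substrate channel.
#' @return Data frame with columns `time_min`, `channel`, `peak_area`.
#' @export
observe <- function(traj, descriptor = attr(traj, "descriptor"),
                    channels = "substrate", metabolite_scale = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  channels <- match.arg(channels,
                        c("substrate", "metabolite_cat", "metabolite_noncat"),
                        several.ok = TRUE)
  t_s <- descriptor$sample_times * 60
  if (any(t_s < min(traj$time_s) - 1e-9) || any(t_s > max(traj$time_s) + 1e-9))
    stop("sample times fall outside the trajectory span", call. = FALSE)
  out <- do.call(rbind, lapply(channels, function(ch) {
    scale <- descriptor$response_scale *
      if (ch == "substrate") 1 else metabolite_scale
    conc <- stats::approx(traj$time_s, traj[[ch]], xout = t_s)$y
    data.frame(time_min = descriptor$sample_times, channel = ch,
               peak_area = scale * conc)
  }))
  rownames(out) <- NULL
  out
}

#' Substrate concentrations at arbitrary times
#'
#' Convenience interpolation used by the fitting objective.
#' @param traj a `trajectory`.
#' @param times_s times in seconds.
#' @return numeric vector of substrate concentrations.
#' @keywords internal
substrate_at <- function(traj, times_s) {
  stats::approx(traj$time_s, traj$substrate, xout = times_s)$y
}

#' Time to 50 percent substrate conversion
#'
#' First time at which the substrate falls to half its initial value,
#' by linear interpolation of the simulated trajectory; `NA` if conversion
#' never reaches 50 percent within the window. Used to contrast dosing
#' modes: a one-shot bolus converts faster than the same oxidant charge
#' fed continuously.
#'
#' @param traj a `trajectory`.
#' @return time in seconds, or `NA`.
#' @export
half_conversion_time <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  target <- traj$substrate[1] / 2
  below <- which(traj$substrate <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(traj$time_s[1])
  # linear interpolation across the crossing
  t0 <- traj$time_s[i - 1]; t1 <- traj$time_s[i]
  s0 <- traj$substrate[i - 1]; s1 <- traj$substrate[i]
  t0 + (s0 - target) / (s0 - s1) * (t1 - t0)
}

#' Export a trajectory as tidy CSV
#'
#' Long format with columns `time_s`, `species`, `value`.
#' @param traj a `trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  long <- do.call(rbind, lapply(.species, function(sp)
    data.frame(time_s = traj$time_s, species = sp, value = traj[[sp]])))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
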