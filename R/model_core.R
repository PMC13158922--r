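#' Rate constants of the biomimetic oxidation scheme
#'
#' Bundles the bimolecular rate constants of the catalytic cycle:
#' `k1` (catalyst activation, FeTPPS + tBuOOH -> FeTPPS*), `k2` (substrate
#' oxidation by the activated species, regenerating FeTPPS), `k3` (apparent
#' oxidative catalyst degradation to inactive FeTPPS0), and, for the
#' `"extended"` variant only, `k4` (direct, non-catalytic oxidation of the
#' substrate by the oxidant).
#'
#' Units are concentration^-1 s^-1 in whatever concentration unit the data
#' carry: mol/L when true concentrations are supplied, response units when
#' chromatographic peak areas are fitted directly (the two differ only by
#' the detector response factor, which rescales the bimolecular constants
#' without changing the trajectories' shape).
#'
#' @param k1,k2,k3 non-negative bimolecular rate constants (conc^-1 s^-1).
#' @param k4 non-catalytic oxidation constant; supplying it selects the
#'   extended model variant.
#' @param variant `"standard"` or `"extended"`; inferred from `k4` when
#'   missing.
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants(k1 = 2, k2 = 200, k3 = 0.2)
#' rate_constants(k1 = 2, k2 = 20, k3 = 0.2, k4 = 0.5)
#' @export
rate_constants <- function(k1, k2, k3, k4 = NULL, variant = NULL) {
  if (is.null(variant)) variant <- if (is.null(k4)) "standard" else "extended"
  variant <- match.arg(variant, c("standard", "extended"))
  if (variant == "standard" && !is.null(k4))
    stop("k4 must be absent for the standard variant", call. = FALSE)
  if (variant == "extended" && is.null(k4))
    stop("the extended variant requires k4", call. = FALSE)
  ks <- c(k1 = k1, k2 = k2, k3 = k3)
  if (!is.null(k4)) ks <- c(ks, k4 = k4)
  if (any(!is.finite(ks)) || any(ks < 0))
    stop("rate constants must be finite and >= 0", call. = FALSE)
  structure(as.list(ks), variant = variant, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (", attr(x, "variant"), " variant, conc^-1 s^-1):\n",
      sep = "")
  print(unlist(x))
  invisible(x)
}

#' Oxidant dosing schedule
#'
#' One-shot dosing places the full oxidant charge (`eqv` equivalents of the
#' initial substrate) in the reactor at t = 0; continuous dosing starts from
#' zero oxidant and feeds it linearly at rate `delta = eqv * s0 / t_max` so
#' that the same total charge is delivered by the end of the run.
#'
#' @param mode `"one_shot"` or `"continuous"`.
#' @param eqv oxidant equivalents (total oxidant / initial substrate), > 0.
#' @param t_max reaction duration in seconds, > 0.
#' @param s0 initial substrate concentration; required for `"continuous"`
#'   to fix the feed rate.
#' @return An object of class `dosing_schedule` with fields `mode`, `eqv`,
#'   `t_max` and `delta` (conc s^-1, zero for one-shot dosing).
#' @export
dosing_schedule <- function(mode = c("one_shot", "continuous"), eqv, t_max,
                            s0 = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(eqv) || eqv <= 0) stop("eqv must be > 0", call. = FALSE)
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  delta <- 0
  if (mode == "continuous") {
    if (is.null(s0)) stop("continuous dosing requires s0", call. = FALSE)
    delta <- feed_rate(s0, eqv, t_max)
  }
  structure(list(mode = mode, eqv = eqv, t_max = t_max, delta = delta),
            class = "dosing_schedule")
}

#' Linear oxidant feed rate
#'
#' `delta = eqv * s0 / t_max`: the constant feed rate that delivers `eqv`
#' substrate-equivalents of oxidant over the full reaction window.
#'
#' @param s0 initial substrate concentration (> 0).
#' @param eqv oxidant equivalents (> 0).
#' @param t_max reaction duration in seconds (> 0).
#' @return Feed rate in conc s^-1.
#' @examples
#' feed_rate(5e-4, 10, 3600)  # the default continuous design
#' @export
feed_rate <- function(s0, eqv, t_max) {
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  if (!is.finite(eqv) || eqv <= 0) stop("eqv must be > 0", call. = FALSE)
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  eqv * s0 / t_max
}

# State vector layout shared by the R and C right-hand sides. The three
# cumulative pools (catalytic metabolite, non-catalytic metabolite, degraded
# catalyst) close the mass balances so conservation is testable; the kinetics
# of the first four species do not depend on them.
.species <- c("fetpps", "fetpps_star", "tbuooh", "substrate",
              "metabolite_cat", "metabolite_noncat", "fetpps_dead")

#' Initial conditions of the oxidation experiment
#'
#' The catalyst loading is tied to the substrate via the oxidant equivalents
#' (`fetpps = s0 / eqv`), no catalyst is activated or degraded at t = 0, and
#' the oxidant is either fully present (`tbuooh = eqv * s0`, one-shot) or
#' absent and fed in linearly (continuous).
#'
#' @param s0 initial substrate concentration (> 0).
#' @param schedule a [dosing_schedule()].
#' @return Named numeric state vector over all seven tracked pools.
#' @examples
#' initial_conditions(5e-4, dosing_schedule("one_shot", eqv = 10, t_max = 3600))
#' @export
initial_conditions <- function(s0, schedule) {
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  stopifnot(inherits(schedule, "dosing_schedule"))
  y <- c(fetpps = s0 / schedule$eqv,
         fetpps_star = 0,
         tbuooh = if (schedule$mode == "one_shot") schedule$eqv * s0 else 0,
         substrate = s0,
         metabolite_cat = 0,
         metabolite_noncat = 0,
         fetpps_dead = 0)
  y[.species]
}

#' Right-hand side of the kinetic ODE system
#'
#' Mass-action rate laws of the catalytic cycle:
#' \deqn{d[FeTPPS]/dt = -(k_1+k_3)[FeTPPS][tBuOOH] + k_2[S][FeTPPS^*]}
#' \deqn{d[FeTPPS^*]/dt = k_1[FeTPPS][tBuOOH] - k_2[S][FeTPPS^*]}
#' \deqn{d[tBuOOH]/dt = -(k_1+k_3)[FeTPPS][tBuOOH] + \delta}
#' \deqn{d[S]/dt = -k_2[S][FeTPPS^*]}
#' The extended variant adds the non-catalytic channel \eqn{-k_4[S][tBuOOH]}
#' to both the oxidant and substrate balances. Cumulative product and
#' degraded-catalyst pools are integrated alongside so that catalyst and
#' substrate conservation hold exactly.
#'
#' This R implementation is the reference definition; numerical integration
#' uses an equivalent compiled version (see [integrate_kinetics()]).
#'
#' @param state named state vector as from [initial_conditions()].
#' @param params a [rate_constants()] object.
#' @param delta oxidant feed rate (conc s^-1); 0 for one-shot dosing.
#' @return Named vector of time derivatives, same layout as `state`.
#' @export
kinetic_rhs <- function(state, params, delta = 0) {
  stopifnot(inherits(params, "rate_constants"))
  k4 <- if (attr(params, "variant") == "extended") params$k4 else 0
  f  <- state[["fetpps"]]
  fs <- state[["fetpps_star"]]
  x  <- state[["tbuooh"]]
  s  <- state[["substrate"]]
  act <- params$k1 * f * x        # activation flux
  ox  <- params$k2 * s * fs       # catalytic oxidation flux
  deg <- params$k3 * f * x        # catalyst degradation flux
  nc  <- k4 * s * x               # non-catalytic oxidation flux
  c(fetpps            = -act - deg + ox,
    fetpps_star       = act - ox,
    tbuooh            = -act - deg - nc + delta,
    substrate         = -ox - nc,
    metabolite_cat    = ox,
    metabolite_noncat = nc,
    fetpps_dead       = deg)
}

# Parameter vector handed to the compiled right-hand side.
.c_parms <- function(params, delta) {
  k4 <- if (attr(params, "variant") == "extended") params$k4 else 0
  c(k1 = params$k1, k2 = params$k2, k3 = params$k3, k4 = k4, delta = delta)
}
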