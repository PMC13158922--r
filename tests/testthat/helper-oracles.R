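# Independent brute-force oracles for the integration tests. The rate laws
# are written out inline, NOT shared with the package's right-hand side.

# Fixed-step explicit-Euler integration of the oxidation scheme.
# Returns a matrix of states at `report_times` (seconds, multiples of h).
euler_oracle <- function(k1, k2, k3, k4 = 0, s0, eqv, mode, t_max,
                         report_times, h = 1e-3) {
  f <- s0 / eqv
  fs <- 0
  x <- if (mode == "one_shot") eqv * s0 else 0
  s <- s0
  mc <- 0; mn <- 0; fd <- 0
  delta <- if (mode == "continuous") eqv * s0 / t_max else 0
  n_steps <- round(max(report_times) / h)
  report_idx <- round(report_times / h)
  out <- matrix(NA_real_, length(report_times), 7,
                dimnames = list(NULL, c("fetpps", "fetpps_star", "tbuooh",
                                        "substrate", "metabolite_cat",
                                        "metabolite_noncat", "fetpps_dead")))
  take <- match(0L, report_idx)
  if (!is.na(take)) out[take, ] <- c(f, fs, x, s, mc, mn, fd)
  for (i in seq_len(n_steps)) {
    a <- k1 * f * x
    o <- k2 * s * fs
    d <- k3 * f * x
    nc <- k4 * s * x
    f_n  <- f + h * (-a - d + o)
    fs_n <- fs + h * (a - o)
    x_n  <- x + h * (-a - d - nc + delta)
    s_n  <- s + h * (-o - nc)
    mc <- mc + h * o
    mn <- mn + h * nc
    fd <- fd + h * d
    f <- f_n; fs <- fs_n; x <- x_n; s <- s_n
    take <- match(i, report_idx)
    if (!is.na(take)) out[take, ] <- c(f, fs, x, s, mc, mn, fd)
  }
  out
}

# Direct transcription of the mass-action derivatives for spot checks,
# independent of the package implementation.
rhs_oracle <- function(f, fs, x, s, k1, k2, k3, k4 = 0, delta = 0) {
  c(fetpps = -(k1 + k3) * f * x + k2 * s * fs,
    fetpps_star = k1 * f * x - k2 * s * fs,
    tbuooh = -(k1 + k3) * f * x - k4 * s * x + delta,
    substrate = -k2 * s * fs - k4 * s * x,
    metabolite_cat = k2 * s * fs,
    metabolite_noncat = k4 * s * x,
    fetpps_dead = k3 * f * x)
}

# Random non-degenerate state for property-style loops.
random_state <- function() {
  v <- stats::runif(7, 0, 1e-3)
  names(v) <- c("fetpps", "fetpps_star", "tbuooh", "substrate",
                "metabolite_cat", "metabolite_noncat", "fetpps_dead")
  v
}
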