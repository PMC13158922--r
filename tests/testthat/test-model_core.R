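test_that("rate constants validate their invariants", {
  expect_s3_class(rate_constants(1, 2, 3), "rate_constants")
  expect_identical(attr(rate_constants(1, 2, 3), "variant"), "standard")
  expect_identical(attr(rate_constants(1, 2, 3, 0.1), "variant"), "extended")
  expect_error(rate_constants(-1, 2, 3), "finite and >= 0")
  expect_error(rate_constants(1, Inf, 3), "finite and >= 0")
  expect_error(rate_constants(1, 2, 3, variant = "extended"), "requires k4")
  expect_error(rate_constants(1, 2, 3, k4 = 1, variant = "standard"),
               "must be absent")
})

test_that("initial conditions follow the dosing mode", {
  one <- dosing_schedule("one_shot", eqv = 10, t_max = 3600)
  y <- initial_conditions(5e-4, one)
  expect_equal(y[["fetpps"]], 5e-5)
  expect_equal(y[["tbuooh"]], 5e-3)
  expect_equal(y[["fetpps_star"]], 0)
  expect_equal(y[["substrate"]], 5e-4)
  expect_true(all(y[c("metabolite_cat", "metabolite_noncat",
                      "fetpps_dead")] == 0))

  cont <- dosing_schedule("continuous", eqv = 10, t_max = 3600, s0 = 5e-4)
  yc <- initial_conditions(5e-4, cont)
  expect_equal(yc[["tbuooh"]], 0)
  expect_equal(yc[c("fetpps", "substrate")], y[c("fetpps", "substrate")])

  ident <- initial_conditions(1, dosing_schedule("one_shot", 1, 1))
  expect_equal(ident[["fetpps"]], 1)
  expect_equal(ident[["tbuooh"]], 1)

  expect_error(initial_conditions(-1, one), "s0 must be > 0")
  expect_error(dosing_schedule("one_shot", eqv = 0, t_max = 10), "eqv")
})

test_that("feed rate is eqv * s0 / t_max and linear in eqv", {
  expect_equal(feed_rate(5e-4, 10, 3600), 10 * 5e-4 / 3600)
  expect_equal(feed_rate(1, 1, 1), 1)
  expect_equal(feed_rate(2e-4, 20, 1800), 2 * feed_rate(2e-4, 10, 1800))
  expect_error(feed_rate(1, 1, 0), "t_max")
  expect_error(feed_rate(1, 1, -5), "t_max")
})

test_that("rhs matches direct substitution into the rate laws", {
  p <- rate_constants(0.1, 0.2, 0.05)
  st <- c(fetpps = 1, fetpps_star = 0.5, tbuooh = 2, substrate = 3,
          metabolite_cat = 0, metabolite_noncat = 0, fetpps_dead = 0)
  d <- kinetic_rhs(st, p, delta = 0)
  expect_equal(d[["fetpps"]], 0)            # -0.3 + 0.3
  expect_equal(d[["fetpps_star"]], -0.1)    # 0.2 - 0.3
  expect_equal(d[["tbuooh"]], -0.3)
  expect_equal(d[["substrate"]], -0.3)

  zero <- kinetic_rhs(st * 0, p, delta = 0)
  expect_true(all(zero == 0))

  # delta only feeds the oxidant when the system is otherwise at rest
  p0 <- rate_constants(0, 0, 0)
  d0 <- kinetic_rhs(st, p0, delta = 7)
  expect_equal(unname(d0), c(0, 0, 7, 0, 0, 0, 0))
})

test_that("extended rhs with k4 = 0 reduces to the standard model", {
  p_std <- rate_constants(0.3, 1.1, 0.07)
  p_ext <- rate_constants(0.3, 1.1, 0.07, k4 = 0)
  withr::with_seed(42, {
    for (i in 1:10) {
      st <- random_state()
      expect_equal(kinetic_rhs(st, p_ext, delta = 0.5),
                   kinetic_rhs(st, p_std, delta = 0.5))
    }
  })
})

test_that("catalyst and substrate pools are conserved by the rhs", {
  withr::with_seed(7, {
    for (i in 1:25) {
      p <- if (i %% 2) rate_constants(runif(1, 0, 5), runif(1, 0, 5),
                                      runif(1, 0, 5))
      else rate_constants(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 5),
                          k4 = runif(1, 0, 5))
      st <- random_state()
      d <- kinetic_rhs(st, p, delta = runif(1, 0, 1e-5))
      expect_equal(d[["fetpps"]] + d[["fetpps_star"]] + d[["fetpps_dead"]], 0)
      expect_equal(d[["substrate"]] + d[["metabolite_cat"]] +
                     d[["metabolite_noncat"]], 0)
    }
  })
})

test_that("rhs matches an independent transcription on random states", {
  withr::with_seed(11, {
    for (i in 1:10) {
      k <- runif(4, 0, 3)
      delta <- runif(1, 0, 1e-4)
      st <- random_state()
      p <- rate_constants(k[1], k[2], k[3], k4 = k[4])
      expect_equal(
        kinetic_rhs(st, p, delta),
        rhs_oracle(st[["fetpps"]], st[["fetpps_star"]], st[["tbuooh"]],
                   st[["substrate"]], k[1], k[2], k[3], k[4], delta))
    }
  })
})

test_that("rhs is homogeneous under joint concentration/constant rescaling", {
  # scaling concentrations by c and bimolecular constants by 1/c scales all
  # derivatives by 1: d(c*y)/dt = c * dy/dt with k -> k/c
  withr::with_seed(3, {
    for (cc in c(10, 2000)) {
      k <- runif(3, 0.1, 3)
      st <- random_state()
      p <- rate_constants(k[1], k[2], k[3])
      p_sc <- rate_constants(k[1] / cc, k[2] / cc, k[3] / cc)
      d <- kinetic_rhs(st, p, delta = 1e-5)
      d_sc <- kinetic_rhs(st * cc, p_sc, delta = 1e-5 * cc)
      expect_equal(d_sc, d * cc)
    }
  })
})

test_that("compiled and R right-hand sides agree through the integrator", {
  # one lsoda step comparison: integrate a short window and compare against
  # the R-function rhs driven through deSolve directly
  p <- rate_constants(2, 200, 0.2)
  d <- default_design()
  y0 <- initial_conditions(d$s0, d$schedule)
  r_fun <- function(t, y, parms) {
    list(unname(kinetic_rhs(y, p, delta = d$schedule$delta)))
  }
  times <- seq(0, 600, by = 60)
  sol_r <- deSolve::ode(y0, times, r_fun, parms = NULL, rtol = 1e-10,
                        atol = 1e-14)
  traj <- integrate_kinetics(p, d, times = times, rtol = 1e-10, atol = 1e-14)
  for (sp in c("fetpps", "fetpps_star", "tbuooh", "substrate"))
    expect_equal(traj[[sp]], unname(sol_r[, sp]), tolerance = 1e-7)
})
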