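test_that("zero kinetics leave the state frozen (one-shot) or feed oxidant linearly (continuous)", {
  d_one <- default_design(mode = "one_shot")
  p0 <- rate_constants(0, 0, 0)
  tr <- integrate_kinetics(p0, d_one)
  y0 <- initial_conditions(d_one$s0, d_one$schedule)
  for (sp in names(y0))
    expect_equal(tr[[sp]], rep(y0[[sp]], nrow(tr)), tolerance = 1e-10)

  d_cont <- default_design()
  trc <- integrate_kinetics(p0, d_cont)
  delta <- d_cont$schedule$delta
  expect_equal(trc$tbuooh, delta * trc$time_s, tolerance = 1e-8)
  expect_equal(trc$substrate, rep(5e-4, nrow(trc)), tolerance = 1e-10)
})

test_that("trajectories match the fixed-step explicit-Euler oracle", {
  # short-window check at the default truth; the full-horizon comparison is
  # part of the acceptance suite
  d <- default_design()
  report <- c(60, 120, 300, 600)
  orc <- euler_oracle(2, 200, 0.2, 0, s0 = 5e-4, eqv = 10,
                      mode = "continuous", t_max = 3600,
                      report_times = report, h = 1e-3)
  tr <- integrate_kinetics(default_truth(), d, times = c(0, report))
  for (j in seq_along(report)) {
    got <- unlist(tr[tr$time_s == report[j], colnames(orc)])
    scale <- pmax(abs(orc[j, ]), 5e-4 * 1e-6)
    expect_lt(max(abs(got - orc[j, ]) / scale), 1e-4)
  }
})

test_that("conservation sums hold along integrated trajectories", {
  withr::with_seed(5, {
    for (i in 1:5) {
      k <- exp(runif(4, log(0.01), log(300)))
      p <- rate_constants(k[1], k[2], k[3], k4 = k[4] / 100)
      d <- default_design(mode = sample(c("one_shot", "continuous"), 1))
      tr <- integrate_kinetics(p, d)
      cat_tot <- tr$fetpps + tr$fetpps_star + tr$fetpps_dead
      sub_tot <- tr$substrate + tr$metabolite_cat + tr$metabolite_noncat
      expect_lt(max(abs(cat_tot - 5e-5)) / 5e-5, 1e-6)
      expect_lt(max(abs(sub_tot - 5e-4)) / 5e-4, 1e-6)
    }
  })
})

test_that("substrate decays monotonically; oxidant respects the dosing mode", {
  tr1 <- integrate_kinetics(default_truth(), default_design())
  expect_true(all(diff(tr1$substrate) <= 1e-15))
  expect_true(all(tr1$tbuooh <= default_design()$schedule$delta *
                    tr1$time_s + 1e-12))
  tr2 <- integrate_kinetics(default_truth(), default_design("one_shot"))
  expect_true(all(diff(tr2$substrate) <= 1e-15))
  expect_true(all(diff(tr2$tbuooh) <= 1e-15))
})

test_that("activated catalyst shows an interior maximum when degradation bites", {
  # one-shot dosing: ample oxidant from t = 0, so FeTPPS* spikes early and
  # then decays as catalyst degradation consumes the pool
  tr <- integrate_kinetics(default_truth(), default_design("one_shot"))
  i_max <- which.max(tr$fetpps_star)
  expect_gt(i_max, 1)
  expect_lt(i_max, nrow(tr))
  expect_gt(tr$fetpps_star[i_max], tr$fetpps_star[1])
  expect_gt(tr$fetpps_star[i_max], tr$fetpps_star[nrow(tr)])
})

test_that("with k3 = 0 substrate + catalytic product stays at s0", {
  p <- rate_constants(2, 200, 0)
  tr <- integrate_kinetics(p, default_design())
  expect_lt(max(abs(tr$substrate + tr$metabolite_cat - 5e-4)) / 5e-4, 1e-6)
  expect_equal(max(tr$fetpps_dead), 0, tolerance = 1e-12)
})

test_that("one-shot dosing reaches 50% conversion before continuous dosing", {
  t_one <- half_conversion_time(
    integrate_kinetics(default_truth(), default_design("one_shot")))
  t_cont <- half_conversion_time(
    integrate_kinetics(default_truth(), default_design("continuous")))
  expect_false(is.na(t_one))
  expect_false(is.na(t_cont))
  expect_lt(t_one, t_cont)
})

test_that("observation maps concentration to peak area linearly", {
  d1 <- default_design()
  tr <- integrate_kinetics(default_truth(), d1)
  ob1 <- observe(tr, d1)
  expect_equal(nrow(ob1), 12)
  expect_equal(ob1$peak_area,
               approx(tr$time_s, tr$substrate, d1$sample_times * 60)$y)

  d2 <- default_design(response_scale = 2000)
  tr2 <- integrate_kinetics(default_truth(), d2)
  ob2 <- observe(tr2, d2)
  expect_equal(ob2$peak_area, 2000 * ob1$peak_area, tolerance = 1e-9)

  # t = 0 would observe the full initial response
  d0 <- experiment_descriptor(5e-4, 10, "continuous", 3600,
                              sample_times = c(1e-9, 30), response_scale = 3)
  ob0 <- observe(integrate_kinetics(default_truth(), d0), d0)
  expect_equal(ob0$peak_area[1], 3 * 5e-4, tolerance = 1e-6)
})

test_that("trajectory CSV export is tidy and round-trips numerically", {
  tr <- integrate_kinetics(default_truth(), default_design(),
                           times = seq(0, 3600, length.out = 25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path)
  expect_named(back, c("time_s", "species", "value"))
  expect_equal(nrow(back), 25 * 7)
  sub <- back[back$species == "substrate", ]
  expect_equal(sub$value, tr$substrate, tolerance = 1e-12)
})

test_that("invalid descriptors and grids are rejected", {
  expect_error(experiment_descriptor(5e-4, 10, "continuous", 3600,
                                     sample_times = c(5, 4)),
               "strictly increasing")
  expect_error(experiment_descriptor(5e-4, 10, "continuous", 60,
                                     sample_times = c(2, 61)),
               "within")
  expect_error(integrate_kinetics(default_truth(), default_design(),
                                  times = c(0, 4000)),
               "within")
  tr <- integrate_kinetics(default_truth(), default_design(),
                           times = c(0, 60, 120))
  d_far <- default_design()
  expect_error(observe(tr, d_far), "outside the trajectory span")
})
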