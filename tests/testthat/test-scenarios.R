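test_that("population size trajectory honours its limiting regimes", {
  # constant when N0 = N20, whatever the steepness
  d <- list(N0 = 500, N20 = 500, uN = 0.3)
  expect_identical(population_size_at(d, 0:20), rep(500L, 21))

  # uN = 0.5 is rounded linear interpolation
  d <- list(N0 = 100, N20 = 100000, uN = 0.5)
  expect_equal(population_size_at(d, 10), 50050L)
  lin <- round(100 + (100000 - 100) * (0:20) / 20)
  expect_true(all(abs(population_size_at(d, 0:20) - lin) <= 1))

  # uN -> 0 stays at N0 until the final generation
  d <- list(N0 = 100, N20 = 100000, uN = 1e-12)
  expect_true(all(population_size_at(d, 0:19) <= 101))
  expect_equal(population_size_at(d, 20), 100000L)

  expect_error(population_size_at(d, 21), "0, 20")
  expect_error(population_size_at(list(N0 = 5, N20 = 500, uN = 0.2), 3),
               "invalid demography")
  expect_error(population_size_at(list(N0 = 600, N20 = 500, uN = 0.2), 3),
               "invalid demography")
})

test_that("population size trajectory is monotone and endpoint-exact", {
  set.seed(11)
  for (i in 1:300) {
    N0 <- sample(10:1000, 1)
    N20 <- sample(max(100, N0):100000, 1)
    d <- list(N0 = N0, N20 = N20, uN = runif(1, 0, 0.5))
    traj <- population_size_at(d, 0:20)
    expect_equal(traj[1], N0)
    expect_equal(traj[21], N20)
    expect_true(all(diff(traj) >= 0))
  }
})

test_that("recurring intensity interpolates between its endpoints", {
  # constant when s_t1 = s_t2
  p <- list(t_t1 = 3, t_t2 = 11, s_t1 = 0.2, s_t2 = 0.2, u = 0.37)
  expect_equal(recurring_intensity_at(p, 3:11), rep(0.2, 9))

  # linear at u = 0.5
  p <- list(t_t1 = 3, t_t2 = 11, s_t1 = 0.4, s_t2 = 0.0, u = 0.5)
  expect_equal(recurring_intensity_at(p, 7), 0.2)
  expect_equal(recurring_intensity_at(p, 3), 0.4)
  expect_equal(recurring_intensity_at(p, 11), 0)

  # u -> 0: sharp pulse at t_t1 then the floor intensity
  p <- list(t_t1 = 3, t_t2 = 11, s_t1 = 0.4, s_t2 = 0.1, u = 1e-6)
  expect_equal(recurring_intensity_at(p, 3), 0.4)
  expect_equal(recurring_intensity_at(p, 4), 0.1, tolerance = 1e-3)

  # monotone non-increasing over the period
  p <- list(t_t1 = 2, t_t2 = 19, s_t1 = 0.8, s_t2 = 0.15, u = 0.22)
  expect_true(all(diff(recurring_intensity_at(p, 2:19)) <= 0))

  expect_error(recurring_intensity_at(p, 20), "outside")
  expect_error(recurring_intensity_at(
    list(t_t1 = 5, t_t2 = 5, s_t1 = 0.4, s_t2 = 0.1, u = 0.3), 5), "t_t2")
})

test_that("contribution schedules place pulses, periods and drift rows", {
  pv <- make_params("Afr2Pulses-Eur2Pulses", 0.4,
                    make_pulse("African", 15, 6, 0.3, 0.2),
                    make_pulse("European", 12, 3, 0.25, 0.15))
  sched <- build_schedule(pv)
  expect_equal(dim(sched), c(21, 3))
  expect_equal(sched[1, ], c(s_afr = 0.4, s_eur = 0.6, h = 0))
  # founding row + 4 distinct pulses -> exactly 5 rows with source input
  expect_equal(sum(sched[, "s_afr"] + sched[, "s_eur"] > 0), 5)
  expect_equal(sched["15", "s_afr"], 0.3)
  expect_equal(sched["3", "s_eur"], 0.15)
  # untouched generations are pure drift
  expect_equal(sched["10", ], c(s_afr = 0, s_eur = 0, h = 1))

  # zero intensities -> h = 1 everywhere after founding
  pv0 <- make_params("Afr2Pulses-Eur2Pulses", 0.4,
                     make_pulse("African", 15, 6, 0, 0),
                     make_pulse("European", 12, 3, 0, 0))
  expect_true(all(build_schedule(pv0)[-1, "h"] == 1))

  # simultaneous over-committed pulses are rejected
  pvbad <- make_params("Afr2Pulses-Eur2Pulses", 0.4,
                       make_pulse("African", 10, 2, 0.7, 0.1),
                       make_pulse("European", 10, 3, 0.7, 0.1))
  expect_error(build_schedule(pvbad), class = "admixabc_constraint_error")
})

test_that("parameter draws satisfy every prior condition", {
  prior <- default_priors("desk")
  set.seed(42)
  for (sc in admix_scenarios()) {
    draws <- replicate(250, draw_parameters(prior, sc), simplify = FALSE)
    for (pv in draws) {
      expect_true(pv$s_Afr_0 >= 0 && pv$s_Afr_0 <= 1)
      d <- pv$demography
      expect_true(d$N0 >= 10 && d$N0 <= 1000 && d$N20 >= 100 &&
                    d$N20 <= prior$N20_range[2] && d$N0 <= d$N20)
      for (proc in list(pv$african, pv$european)) {
        if (proc$kind == "pulse") {
          expect_true(proc$t_p1 > proc$t_p2)
          expect_true(all(c(proc$t_p1, proc$t_p2) %in% 1:20))
          expect_true(all(c(proc$s_p1, proc$s_p2) >= 0 &
                            c(proc$s_p1, proc$s_p2) <= 1))
        } else {
          expect_true(proc$t_t2 >= proc$t_t1 + 1)
          expect_true(proc$s_t1 >= proc$s_t2)
          expect_true(proc$u >= 0 && proc$u <= 0.5)
        }
      }
      sched <- build_schedule(pv)
      expect_true(max(abs(rowSums(sched) - 1)) < 1e-12)
    }
  }
})

test_that("parameter draws are deterministic under a seed", {
  prior <- default_priors("desk")
  set.seed(7)
  a <- draw_parameters(prior, "AfrRecurring-EurRecurring")
  set.seed(7)
  b <- draw_parameters(prior, "AfrRecurring-EurRecurring")
  expect_identical(a, b)
})

test_that("parameter vectors survive a serialisation round trip", {
  prior <- default_priors("desk")
  set.seed(3)
  for (sc in admix_scenarios()) {
    pv <- draw_parameters(prior, sc)
    row <- params_to_row(pv)
    expect_identical(names(row), param_columns())
    back <- row_to_params(row)
    expect_equal(back$s_Afr_0, pv$s_Afr_0)
    expect_equal(back$african[order(names(back$african))],
                 pv$african[order(names(pv$african))])
    expect_equal(back$demography, pv$demography)
    # parameters foreign to the scenario stay NA
    foreign <- setdiff(param_columns(),
                       c("scenario", scenario_params(sc)))
    expect_true(all(is.na(row[foreign])))
  }
})
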