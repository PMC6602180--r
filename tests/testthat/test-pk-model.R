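test_that("macro/micro conversion reproduces the reference estimates and round-trips", {
  p <- macro_to_micro(cl = 154.225, q = 4.1761, vc = 37.6571, vp = 7.7825)
  expect_equal(p$k10 / 24, 4.0955, tolerance = 1e-4)
  expect_equal(p$k12 / 24, 0.1109, tolerance = 1e-3)
  expect_equal(p$k21 / 24, 0.5366, tolerance = 1e-3)

  unit <- macro_to_micro(cl = 1, q = 1, vc = 1, vp = 1)
  expect_equal(unname(c(unit$k10, unit$k12, unit$k21) / 24), c(1, 1, 1))

  withr::with_seed(42, {
    for (i in 1:10) {
      m <- exp(runif(4, -2, 2)) * c(100, 5, 40, 8)
      p <- macro_to_micro(m[1], m[2], m[3], m[4])
      back <- micro_to_macro(p)
      expect_equal(unname(back), m, tolerance = 1e-12)
    }
  })
  expect_error(macro_to_micro(-1, 1, 1, 1), "> 0")
  expect_error(pk_params(1, 1, 0, 1), "> 0")
})

test_that("simulated infusions match the matrix-exponential oracle", {
  pk <- ref_pk()
  sched <- single_infusion()
  check_t <- c(0.05, 0.125, 0.2, 0.5, 1)
  sim <- simulate_pk(pk, sched, check_t)
  for (i in seq_along(check_t)) {
    t <- check_t[i]
    oracle <- if (t <= 0.125) {
      expm_pk_oracle(pk, c(0, 0), 5340 / 0.125, t)
    } else {
      at_end <- expm_pk_oracle(pk, c(0, 0), 5340 / 0.125, 0.125)
      expm_pk_oracle(pk, at_end, 0, t - 0.125)
    }
    expect_equal(c(sim$x1[i], sim$x2[i]), oracle, tolerance = 1e-8)
  }
  expect_equal(sim$conc, sim$x1 / pk$vc)
})

test_that("PK simulation is linear in dose, mass-bounded and zero without dosing", {
  pk <- ref_pk()
  times <- seq(0, 6, by = 0.05)
  d135 <- build_schedule("D135")
  sim1 <- simulate_pk(pk, d135, times)
  double <- infusion_schedule(
    dplyr::mutate(tibble::as_tibble(d135), amount = amount * 2),
    bsa = 1.78, label = "2xD135")
  sim2 <- simulate_pk(pk, double, times)
  expect_equal(sim2$x1, 2 * sim1$x1, tolerance = 1e-10)
  expect_equal(sim2$x2, 2 * sim1$x2, tolerance = 1e-10)

  ev <- tibble::as_tibble(d135)
  administered <- vapply(times, function(t) {
    sum(pmin(pmax(t - ev$start, 0), ev$duration) / ev$duration * ev$amount)
  }, numeric(1))
  expect_true(all(sim1$x1 + sim1$x2 <= administered + 1e-8))
  expect_true(all(sim1$x1 >= -1e-12 & sim1$x2 >= -1e-12))

  empty <- infusion_schedule(
    tibble::tibble(start = numeric(), duration = numeric(),
                   amount = numeric()), bsa = 1.78, label = "none")
  sim0 <- simulate_pk(pk, empty, times)
  expect_true(all(abs(c(sim0$x1, sim0$x2)) < 1e-12))
})

test_that("a single high-dose infusion washes out below 1e-6 mg well before 16.35 days", {
  pk <- ref_pk()
  sched <- single_infusion()
  tw <- pk_washout_time(pk, sched)
  expect_lte(tw, 16.35)
  at_bound <- simulate_pk(pk, sched, c(16.35))
  expect_lt(at_bound$x1, 1e-6)
  expect_lt(at_bound$x2, 1e-6)
  # just before the washout time at least one compartment is still above
  before <- simulate_pk(pk, sched, tw - 0.01)
  expect_gt(max(before$x1, before$x2), 1e-6)
})
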