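test_that("parameter sampling is reproducible, bounded and centred on the medians", {
  spec <- cohort_spec(seed = 5)
  p1 <- sample_parameters(spec)
  p2 <- sample_parameters(spec)
  expect_equal(p1, p2)

  degenerate <- cohort_spec(n_patients = 6, cv = c(B = 0, slope = 0,
                                                   k_tr = 0, gamma = 0),
                            seed = 2)
  pd <- sample_parameters(degenerate)
  expect_equal(unique(pd$B), 5.5)
  expect_equal(unique(pd$slope), degenerate$medians[["slope"]])

  big <- sample_parameters(cohort_spec(n_patients = 500, seed = 9))
  bb <- default_fit_bounds()
  for (nm in c("B", "slope", "k_tr", "gamma")) {
    expect_true(all(big[[nm]] >= bb[[nm]][1] & big[[nm]] <= bb[[nm]][2]))
    expect_lt(abs(median(big[[nm]]) / cohort_spec()$medians[[nm]] - 1), 0.06)
  }
  counts <- table(big$schedule) / nrow(big)
  expect_lt(max(abs(counts[names(cohort_spec()$schedule_prob)] -
                      cohort_spec()$schedule_prob)), 0.07)
})

test_that("noise-free cohorts lie exactly on the generating trajectories", {
  spec <- cohort_spec(n_patients = 2, sigma_log = 0, dropout = 0, seed = 8)
  model <- model_spec("M10")
  co <- simulate_cohort(spec, model)
  truth <- attr(co, "truth")
  cst <- model_constants(vc = ref_pk()$vc)
  for (id in names(co)) {
    cy <- co[[id]]
    tr <- truth[truth$cycle == id, ]
    bbm <- tr$B * cst$k_ma / tr$k_tr
    par <- pd_params(B = tr$B, slope = tr$slope, k_tr = tr$k_tr,
                     gamma = tr$gamma, B0 = tr$B0, xpr0 = bbm, xtr0 = bbm)
    sim <- simulate_wbc(model, par, cst, ref_pk(), cy$schedule,
                        horizon = max(cy$observations$time) + 1e-6,
                        times = cy$observations$time)
    expect_equal(cy$observations$wbc, sim$wbc, tolerance = 1e-9)
  }
})

test_that("cohort generation is seed-stable and carries between-cycle carry-over", {
  spec <- cohort_spec(n_patients = 4, seed = 3)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_equal(attr(c1, "truth"), attr(c2, "truth"))
  expect_equal(lapply(c1, function(x) x$observations),
               lapply(c2, function(x) x$observations))
  truth <- attr(c1, "truth")
  expect_true(any(abs(truth$B0 / truth$B - 1) > 0.01)) # B0 varies around B
  expect_true(all(vapply(c1, function(x) all(x$observations$wbc > 0),
                         logical(1))))
})

test_that("synthetic concentration records scale linearly with dose and respect the seed", {
  pk <- ref_pk()
  sched <- kern_sampling_schedule()
  tt <- kern_sampling_times()
  d0 <- gen_pk_concentration_data(pk, sched, tt, sigma_log = 0)
  expect_true(all(d0$conc > 0))
  double <- infusion_schedule(
    dplyr::mutate(tibble::as_tibble(sched), amount = amount * 2),
    bsa = 1.78, label = "2x")
  d2 <- gen_pk_concentration_data(pk, double, tt, sigma_log = 0)
  expect_equal(d2$conc, 2 * d0$conc, tolerance = 1e-10)

  n1 <- gen_pk_concentration_data(pk, sched, tt, sigma_log = 0.2, seed = 6)
  n2 <- gen_pk_concentration_data(pk, sched, tt, sigma_log = 0.2, seed = 6)
  expect_equal(n1, n2)
})
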