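test_that("discrimination reports account for every personalised cycle", {
  spec10 <- model_spec("M10")
  strong <- make_cycle("D_C1", spec10, nominal_truth(), sigma = 0.1,
                       seed = 51)
  weak_truth <- nominal_truth(slope = 1.2) # too weak for leukopenia
  weak <- make_cycle("D_C2", spec10, weak_truth, sigma = 0.1, seed = 52)
  fits <- suppressWarnings(list(
    fit_cycle(strong, spec10, n_starts = 1),
    fit_cycle(weak, spec10, n_starts = 1)
  ))
  rep <- discrimination_study(fits)
  expect_setequal(c(rep$included, rep$excluded), c("D_C1", "D_C2"))
  expect_true("D_C2" %in% rep$excluded)
  expect_equal(nrow(rep$stats), length(unique(rep$stats$model)) * 2)
  expect_true(all(c("t_rec_median", "t_rec_sd", "t_rec_min", "t_rec_max")
                  %in% names(rep$stats)))
  expect_error(discrimination_study(list()), "No personalised")
})

test_that("the timing study returns one nadir per shift and matches the unshifted case", {
  fit <- fixture_overshoot_fit()
  ts <- timing_study(fit, shifts = c(-3:-1, 1:3), pad = 4, horizon = 30)
  expect_equal(nrow(ts), 6)
  expect_equal(ts$shift, c(-3:-1, 1:3))
  expect_true(all(is.finite(ts$nadir)))
  expect_gt(attr(ts, "nominal_nadir"), 0)
  # shift 0 equals the nominal simulation by construction
  ts0 <- timing_study(fit, shifts = 0, pad = 4, horizon = 30)
  expect_equal(ts0$nadir, attr(ts0, "nominal_nadir"), tolerance = 1e-12)
  expect_error(timing_study(fit, shifts = -11, pad = 10), "origin")
})

test_that("dose intensification never raises the nadir (M5)", {
  cst <- ref_consts()
  pk <- ref_pk()
  d135 <- build_schedule("D135")
  d1235 <- infusion_schedule(
    dplyr::bind_rows(tibble::as_tibble(d135),
                     tibble::tibble(start = c(1, 1.5), duration = 0.125,
                                    amount = 5340)),
    bsa = 1.78, label = "D1235")
  for (slope in c(3, 5.2)) {
    for (gamma in c(0.3, 0.6)) {
      par <- nominal_truth(slope = slope, gamma = gamma)
      n1 <- recovery_stats(simulate_wbc(model_spec("M5"), par, cst, pk,
                                        d135, horizon = 45))$nadir
      n2 <- recovery_stats(simulate_wbc(model_spec("M5"), par, cst, pk,
                                        d1235, horizon = 45))$nadir
      expect_lte(n2, n1 + 1e-9)
    }
  }
})

test_that("PK variability draws have the requested spread and degenerate to a point at CV 0", {
  pd <- pd_params(B = 5.5, slope = 5.2, k_tr = 0.19, gamma = 0.45)
  fixed <- iiv_study(pd, models = "M3", schedules = "D135", cv_cl = 0,
                     cv_vc = 0, n = 5, seed = 2, horizon = 45)
  expect_equal(length(unique(fixed$t_rec)), 1)
  expect_equal(length(unique(fixed$cl)), 1)

  # short horizon: the draw mechanism is under test, not the recovery times
  draws <- iiv_study(pd, models = "M3", schedules = "D135", n = 2000,
                     seed = 3, horizon = 3, grid_by = 0.5)
  one <- dplyr::distinct(draws, draw, cl, vc)
  cv_emp <- function(x) sd(x) / mean(x)
  expect_lt(abs(cv_emp(one$cl) - 0.45), 0.05)
  expect_lt(abs(cv_emp(one$vc) - 0.70), 0.05)
  # medians are preserved by the lognormal parameterisation
  expect_lt(abs(median(one$cl) / 154.225 - 1), 0.1)
})

test_that("schedule sensitivity under PK variability separates M10 from M3", {
  pd <- pd_params(B = 5.5, slope = 5.2, k_tr = 0.19, gamma = 0.45)
  res <- iiv_study(pd, n = 60, seed = 4, horizon = 50, grid_by = 0.1)
  med <- res |>
    dplyr::group_by(model, schedule) |>
    dplyr::summarise(t_rec = median(t_rec, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = schedule, values_from = t_rec)
  sep <- med$D135 - med$D123
  names(sep) <- med$model
  expect_gt(sep[["M10"]], sep[["M3"]])
})
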