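cst <- ref_consts()
pk <- ref_pk()

test_that("residual vectors carry penalty rows only for I3, zero at the steady state", {
  cy <- make_cycle("R1", model_spec("M5"), nominal_truth(), sigma = 0.1,
                   seed = 3)
  # I1 problem: data residuals only
  pr1 <- myelokin:::fit_problem(cy, model_spec("M3"), cst, pk)
  r1 <- residual_vector(pr1, pr1$start)
  expect_length(as.numeric(r1), nrow(cy$observations))

  # I3 problem: two penalty rows per cycle, exactly zero at xpr0 = xtr0 = B_bm
  pr3 <- myelokin:::fit_problem(cy, model_spec("M5"), cst, pk)
  th <- pr3$start
  bbm <- th[["B"]] * cst$k_ma / th[["k_tr"]]
  th[c("xpr0", "xtr0")] <- bbm
  r3 <- as.numeric(residual_vector(pr3, th))
  expect_length(r3, nrow(cy$observations) + 2)
  expect_equal(tail(r3, 2), c(0, 0), tolerance = 1e-12)

  # away from the steady state the rows are sqrt(alpha)-scaled deviations
  th["xpr0"] <- bbm + 10
  r3b <- as.numeric(residual_vector(pr3, th))
  expect_equal(tail(r3b, 2)[1], sqrt(pr3$alpha) * 10, tolerance = 1e-12)
})

test_that("noise-free synthetic cycles are recovered to optimiser tolerance", {
  spec <- model_spec("M5")
  truth <- nominal_truth()
  cy <- make_cycle("NF1", spec, truth, sigma = 0, seed = 1)
  fit <- suppressWarnings(fit_cycle(cy, spec, n_starts = 1))
  core <- c("B", "slope", "k_tr", "gamma")
  tru <- unlist(truth[core])
  expect_lt(max(abs(fit$estimates[core] / tru - 1)), 0.02)
  expect_lt(fit$objective, 1e-4)
  expect_lt(fit$rmse, 0.05)
})

test_that("a large steady-state penalty reproduces the I1-style fit", {
  spec5 <- model_spec("M5")
  truth <- nominal_truth() # B0 = B, marrow at steady state
  cy <- make_cycle("A1", spec5, truth, sigma = 0.1, seed = 11)
  fit_i1 <- suppressWarnings(fit_cycle(cy, model_spec("M3"), n_starts = 1))
  fit_pen <- suppressWarnings(fit_cycle(cy, spec5, alpha = 1e6, n_starts = 1))
  core <- c("B", "slope", "k_tr", "gamma")
  expect_lt(max(abs(fit_pen$estimates[core] / fit_i1$estimates[core] - 1)),
            0.05)
  # the penalty pins the initial marrow states to B_bm
  bbm_hat <- fit_pen$estimates[["B"]] * cst$k_ma / fit_pen$estimates[["k_tr"]]
  expect_equal(unname(fit_pen$estimates["xpr0"]), bbm_hat, tolerance = 1e-3)
  expect_equal(unname(fit_pen$estimates["xtr0"]), bbm_hat, tolerance = 1e-3)
})

test_that("fitting is invariant to observation ordering and patient fits generalise cycle fits", {
  spec <- model_spec("M10")
  cy <- make_cycle("O1", spec, nominal_truth(b0_factor = 1.2), sigma = 0.12,
                   seed = 5)
  shuffled <- withr::with_seed(9, {
    idx <- sample(nrow(cy$observations))
    cycle_data("O1", cy$observations[idx, ], cy$schedule)
  })
  f1 <- suppressWarnings(fit_cycle(cy, spec, n_starts = 1))
  f2 <- suppressWarnings(fit_cycle(shuffled, spec, n_starts = 1))
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-10)

  fp <- suppressWarnings(fit_patient(list(cy), spec, n_starts = 1))
  expect_equal(fp$estimates, f1$estimates, tolerance = 1e-10)
  expect_equal(fp$rmse, f1$rmse, tolerance = 1e-10)
})

test_that("joint patient fits use the shared information across cycles", {
  spec <- model_spec("M10")
  truth <- nominal_truth()
  core <- c("B", "slope", "k_tr", "gamma")
  tru <- unlist(truth[core])
  cys <- list(make_cycle("J_C1", spec, truth, sigma = 0.15, seed = 31,
                         patient_id = "J"),
              make_cycle("J_C2", spec, truth, sigma = 0.15, seed = 32,
                         patient_id = "J"))
  joint <- suppressWarnings(fit_patient(cys, spec, n_starts = 1))
  singles <- lapply(cys, function(cy)
    suppressWarnings(fit_cycle(cy, spec, n_starts = 1)))
  err <- function(f) sqrt(mean((f$estimates[core] / tru - 1)^2))
  expect_lte(err(joint), mean(vapply(singles, err, numeric(1))) + 1e-6)
  expect_length(joint$params, 2)
  # per-cycle initial-state parameters are separate
  expect_true(all(c("B0.1", "B0.2", "xpr0.1", "xpr0.2") %in%
                    names(joint$estimates)))
})

test_that("the multistart optimum is no worse than any start and pooled RMSE is exact", {
  spec <- model_spec("M5")
  cy <- make_cycle("MS1", spec, nominal_truth(), sigma = 0.15, seed = 13)
  problem <- myelokin:::fit_problem(cy, spec, cst, pk)
  fit <- suppressWarnings(fit_cycle(cy, spec, n_starts = 3, seed = 1))
  obj_start <- sum(as.numeric(residual_vector(problem, problem$start))^2)
  expect_lte(fit$objective, obj_start + 1e-12)

  expect_equal(pooled_rmse(c(1, 1), c(1, 1)), 0)
  expect_equal(pooled_rmse(c(2, 3), c(1, 3)), sqrt(0.5))
  expect_equal(pooled_rmse(list(fit)), fit$rmse)
  expect_error(pooled_rmse(numeric(0), numeric(0)), "non-empty")
  # covariance is symmetric and tidied output is consistent
  expect_equal(fit$covariance, t(fit$covariance), tolerance = 1e-10)
  td <- tidy(fit)
  expect_equal(td$estimate, unname(fit$estimates))
  expect_equal(glance(fit)$rmse, fit$rmse)
})
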