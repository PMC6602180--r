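cst <- ref_consts()
pk <- ref_pk()
all_ids <- paste0("M", 1:12)

test_that("drug effect and secondary scaling have their closed forms", {
  expect_equal(pd_effect(0, 5, cst$c_v), 0)
  expect_equal(pd_effect(1 / cst$c_v, 0.2, cst$c_v), 0.2 * log(2))
  # E crosses 1 exactly at c_V x1 = e^(1/slope) - 1
  for (slope in c(0.3, 1, 5)) {
    x1_star <- (exp(1 / slope) - 1) / cst$c_v
    expect_equal(pd_effect(x1_star, slope, cst$c_v), 1, tolerance = 1e-12)
  }
  expect_equal(saturation(0, cst$c_v), 1)
  expect_equal(saturation((exp(1) - 1) / cst$c_v, cst$c_v), 2)
  grid <- seq(0, 500, length.out = 40)
  expect_true(all(diff(saturation(grid, cst$c_v)) > 0))
  expect_true(all(diff(pd_effect(grid, 2, cst$c_v)) > 0))
  expect_error(pd_effect(-1, 1, cst$c_v), "non-negative")
  expect_error(saturation(-1, cst$c_v), "non-negative")
})

test_that("all models reduce to F = G = k_tr at drug-free homeostasis", {
  par <- nominal_truth()
  bbm <- par$B * cst$k_ma / par$k_tr
  for (id in all_ids) {
    spec <- model_spec(id)
    expect_equal(
      proliferation_rate(spec, par, cst, x1 = 0, xma = par$B,
                         xpr = bbm, xtr = bbm),
      par$k_tr, tolerance = 1e-12, label = id)
    expect_equal(maturation_rate(spec, par, cst, x1 = 0), par$k_tr)
  }
})

test_that("the proliferation rate of M5 changes sign exactly at the drug-effect threshold", {
  par <- nominal_truth()
  spec <- model_spec("M5")
  for (slope in c(0.5, 2, 5, 8)) {
    p <- pd_params(B = par$B, slope = slope, k_tr = par$k_tr,
                   gamma = par$gamma)
    x1_star <- (exp(1 / slope) - 1) / cst$c_v
    expect_equal(proliferation_rate(spec, p, cst, x1_star, xma = par$B), 0,
                 tolerance = 1e-10)
    for (f in c(0.2, 0.9)) {
      expect_gt(proliferation_rate(spec, p, cst, f * x1_star, xma = par$B), 0)
    }
    for (f in c(1.1, 5)) {
      expect_lt(proliferation_rate(spec, p, cst, f * x1_star, xma = par$B), 0)
    }
  }
})

test_that("the secondary gamma scaling amplifies the suppressed-state response (M10 vs M5)", {
  par <- nominal_truth()
  for (x1 in c(50, 200, 430)) {
    for (xma in c(0.5, 2, 4)) { # below baseline
      f5 <- proliferation_rate(model_spec("M5"), par, cst, x1, xma)
      f10 <- proliferation_rate(model_spec("M10"), par, cst, x1, xma)
      expect_gt(abs(f10), abs(f5))
    }
  }
})

test_that("M7 halves its maturation rate when S = 2 and M6 applies a net direct-kill rate", {
  par <- nominal_truth()
  x1_s2 <- (exp(1) - 1) / cst$c_v
  expect_equal(maturation_rate(model_spec("M7"), par, cst, x1_s2),
               par$k_tr / 2)
  expect_equal(maturation_rate(model_spec("M7"), par, cst, 0), par$k_tr)
  expect_equal(maturation_rate(model_spec("M5"), par, cst, 1000), par$k_tr)
  # M6: F = k_tr (B/xma)^gamma - E, unclipped
  x1 <- 400; xma <- 3
  expect_equal(
    proliferation_rate(model_spec("M6"), par, cst, x1, xma),
    par$k_tr * (par$B / xma)^par$gamma -
      par$slope * log(1 + cst$c_v * x1))
})

test_that("vector fields agree with an independently coded implementation", {
  withr::with_seed(7, {
    for (id in all_ids) {
      spec <- model_spec(id)
      par <- nominal_truth()
      for (rep in 1:5) {
        y <- exp(runif(spec$n_tr + 2, log(0.05), log(80)))
        names(y) <- c("xpr", paste0("xtr", seq_len(spec$n_tr)), "xma")
        x1 <- runif(1, 0, 450)
        expect_equal(myelokin:::wbc_rhs(spec, par, cst, x1, y),
                     unname(naive_wbc_rhs(id, par, cst, x1, y)),
                     tolerance = 1e-12, label = id)
        fast <- myelokin:::make_fast_rhs(spec, par, cst)
        expect_equal(unname(fast(x1, unname(y))),
                     unname(naive_wbc_rhs(id, par, cst, x1, y)),
                     tolerance = 1e-12, label = paste0(id, "-fast"))
      }
    }
  })
})

test_that("initial-condition strategies give the documented states and derivatives", {
  # I1: full steady state, zero vector field without drug
  p1 <- pd_params(B = 5, slope = 1, k_tr = cst$k_ma / 2, gamma = 0.4)
  spec1 <- model_spec("M3")
  st <- initial_state(spec1, p1, cst)
  expect_equal(unname(st), c(10, 10, 5)) # B_bm = B*k_ma/k_tr = 2B
  expect_equal(myelokin:::wbc_rhs(spec1, p1, cst, 0, st),
               rep(0, 3), tolerance = 1e-12)

  # I2: transit derivative zero, xma rate = G*B*k_ma/k_tr - k_ma*B0
  spec2 <- model_spec("M4")
  p2 <- pd_params(B = 5, slope = 1, k_tr = 0.2, gamma = 0.4, B0 = 3.5)
  st2 <- initial_state(spec2, p2, cst)
  d2 <- myelokin:::wbc_rhs(spec2, p2, cst, 0, st2)
  expect_equal(d2[2], 0, tolerance = 1e-12)
  expect_equal(d2[3], p2$k_tr * (p2$B * cst$k_ma / p2$k_tr) -
                 cst$k_ma * p2$B0)
  expect_equal(sign(d2[3]), sign(p2$B - p2$B0))

  # I3 at (B_bm, B_bm, B) reduces to I1
  spec3 <- model_spec("M5")
  bbm <- 5 * cst$k_ma / 0.2
  p3 <- pd_params(B = 5, slope = 1, k_tr = 0.2, gamma = 0.4,
                  B0 = 5, xpr0 = bbm, xtr0 = bbm)
  expect_equal(initial_state(spec3, p3, cst),
               initial_state(model_spec("M3"), p3, cst))
  expect_error(initial_state(spec3, pd_params(5, 1, 0.2, 0.4), cst), "I3")
})

test_that("drug-free trajectories are constant from steady state and model-independent", {
  empty <- infusion_schedule(
    tibble::tibble(start = numeric(), duration = numeric(),
                   amount = numeric()), bsa = 1.78, label = "none")
  times <- seq(0, 100, by = 1)
  for (id in c("M1", "M3", "M5", "M10")) {
    spec <- model_spec(id)
    par <- nominal_truth()
    traj <- simulate_wbc(spec, par, cst, pk, empty, horizon = 100,
                         times = times)
    expect_lt(max(abs(traj$wbc - par$B)), 1e-6)
  }

  # off steady state and without drug, M5-M10 share a vector field and
  # M11/M12 collapse onto each other
  par_ns <- nominal_truth(b0_factor = 1.4, marrow_factor = 0.8)
  times2 <- seq(0, 40, by = 0.5)
  trajs <- lapply(paste0("M", 5:12), function(id) {
    simulate_wbc(model_spec(id), par_ns, cst, pk, empty, horizon = 40,
                 times = times2)$wbc
  })
  names(trajs) <- paste0("M", 5:12)
  for (id in paste0("M", 6:10)) {
    expect_equal(trajs[[id]], trajs$M5, tolerance = 1e-8, label = id)
  }
  expect_equal(trajs$M12, trajs$M11, tolerance = 1e-8)
})

test_that("trajectories stay non-negative and rebound above baseline after a cycle", {
  par <- nominal_truth()
  traj <- simulate_wbc(model_spec("M5"), par, cst, pk,
                       build_schedule("D135"), horizon = 150,
                       times = seq(0, 150, 0.1))
  expect_true(all(traj$wbc >= -1e-9))
  expect_true(all(traj$xpr >= -1e-9))
  st <- recovery_stats(traj)
  expect_lt(st$nadir, par$B)
  i_min <- which.min(traj$wbc)
  after <- traj$wbc[seq(i_min, nrow(traj))]
  expect_gt(max(after), par$B)            # feedback overshoot
  expect_lt(abs(traj$wbc[nrow(traj)] - par$B) / par$B, 0.05) # settles back
})

test_that("mean maturation time follows both conventions", {
  expect_equal(mean_maturation_time(model_spec("M3"), k_tr = 0.5),
               c(corrected = 48, original = 96))
  expect_equal(unname(mean_maturation_time(model_spec("M2"), 0.3)["corrected"]),
               24 * 3 / 0.3)
  for (id in c("M1", "M2", "M3")) {
    mmt <- mean_maturation_time(model_spec(id), 0.2)
    expect_lt(mmt["corrected"], mmt["original"])
  }
})
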