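test_that("with no conversion risk, QALYs match the closed forms exactly", {
  prof <- one_profile(age = 62, death_age = 85)  # T = 23 remaining years
  T_rem <- 23

  p0 <- no_conversion_params(discount = 0)
  rec0 <- simulate_patient(prof, FALSE, p0, seed = 4)
  expect_false(rec0$converted)
  expect_equal(rec0$qaly, 0.8015 * T_rem, tolerance = 1e-9)

  p35 <- no_conversion_params(discount = 0.035)
  rec35 <- simulate_patient(prof, FALSE, p35, seed = 4)
  closed <- 0.8015 * (1 - 1.035^(-T_rem)) / log(1.035)
  expect_equal(rec35$qaly, closed, tolerance = 1e-9)
  # numerical-quadrature oracle for the same quantity
  quad <- integrate(function(t) 0.8015 * exp(-log(1.035) * t), 0, T_rem,
                    rel.tol = 1e-12)$value
  expect_equal(rec35$qaly, quad, tolerance = 1e-8)
})

test_that("an early death closes the record after a single event", {
  prof <- one_profile(age = 62, death_age = 62.2)
  rec <- simulate_patient(prof, FALSE, model_params(), seed = 1)
  expect_equal(rec$events, 1L)
  expect_equal(rec$final_stage, oht_stages[["OHT"]])
})

test_that("strategy runs are bitwise reproducible under a fixed master seed", {
  coh <- tiny_cohort(150, seed = 5)
  a <- run_strategy(coh, "rp", model_params(), master_seed = 77)
  b <- run_strategy(coh, "rp", model_params(), master_seed = 77)
  expect_identical(a, b)
})

test_that("undiscounted QALYs equal a trapezoid oracle on the event log", {
  p <- model_params(econ = econ_params(discount = 0))
  coh <- tiny_cohort(25, seed = 31)
  util <- p$econ$utilities
  for (i in seq_len(10)) {
    rec <- simulate_patient(coh[i, ], TRUE, p, seed = 100 + i, trace = TRUE)
    log <- rec$log
    # stage is piecewise constant between logged events
    oracle <- sum(util[log$stage[-nrow(log)]] * diff(log$time))
    expect_equal(rec$qaly, oracle, tolerance = 1e-9)
  }
})

test_that("raising the discount rate strictly lowers discounted totals", {
  coh <- tiny_cohort(80, seed = 17)
  q <- sapply(c(0, 0.035, 0.07), function(d) {
    p <- model_params(econ = econ_params(discount = d))
    r <- run_strategy(coh, "sc", p, master_seed = 6)
    c(r$mean_qalys, r$mean_cost)
  })
  expect_true(all(diff(q[1, ]) < 0))
  expect_true(all(diff(q[2, ]) < 0))
})

test_that("end states conserve mass and converters end in glaucoma states", {
  coh <- tiny_cohort(400, seed = 23)
  res <- run_strategy(coh, "sc", model_params(), master_seed = 9)
  expect_equal(sum(res$end_state), 1, tolerance = 1e-9)
  in_glaucoma <- sum(res$end_state[-1])
  expect_gte(res$prop_converted, in_glaucoma - 1e-12)
  # conversion is absorbing, so the two fractions coincide
  expect_equal(res$prop_converted, in_glaucoma, tolerance = 1e-12)
})

test_that("treating everyone weakly dominates treating no one on QALYs", {
  coh <- tiny_cohort(600, seed = 41)
  p <- model_params()
  all_t <- run_strategy(coh, "all", p, master_seed = 12)
  none_t <- run_strategy(coh, "none", p, master_seed = 12)
  expect_gte(all_t$mean_qalys, none_t$mean_qalys)
  expect_lt(all_t$prop_converted, none_t$prop_converted)
})

test_that("a single-patient cohort aggregates to that patient's record", {
  coh <- tiny_cohort(1, seed = 2)
  res <- run_strategy(coh, "rp", model_params(), master_seed = 3)
  expect_equal(res$n, 1)
  expect_equal(res$mean_cost, res$patients$cost[1])
  expect_equal(res$mean_qalys, res$patients$qaly[1])
  expect_error(run_strategy(coh[0, ], "rp", model_params()), "empty")
})
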