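test_that("discounted accrual matches its closed form and quadrature", {
  expect_equal(discounted_accrual(0.8015, 0, 1, 0), 0.8015)
  v <- discounted_accrual(0.8015, 0, 1, 0.035)
  expect_equal(v, 0.7879, tolerance = 1e-4)
  quad <- integrate(function(t) 0.8015 * exp(-log(1.035) * t), 0, 1,
                    rel.tol = 1e-12)$value
  expect_equal(v, quad, tolerance = 1e-10)
  expect_equal(discounted_accrual(5, 2, 2, 0.035), 0)
  expect_error(discounted_accrual(1, 2, 1), "t1 >= t0")
})

test_that("the ICER quadrant logic labels dominance correctly", {
  mk <- function(cost, qaly) list(mean_cost = cost, mean_qalys = qaly)
  ce <- icer(mk(4662, 10.89), mk(4924, 10.913))
  expect_equal(ce$delta_cost, 262)
  expect_equal(ce$delta_qalys, 0.023)
  expect_equal(ce$icer, 262 / 0.023, tolerance = 1e-9)  # ~11391
  expect_equal(icer(mk(100, 10), mk(90, 10.01))$label, "RP dominant")
  expect_equal(icer(mk(100, 10), mk(200, 9.99))$label, "RP dominated")
  expect_equal(icer(mk(100, 10), mk(200, 10))$label, "undefined, compare costs")
})

test_that("moment-matched second-order distributions hit their moments", {
  set.seed(8)
  b <- rbeta_mm(100000, 0.7471, 0.04)
  expect_lt(abs(mean(b) - 0.7471) / 0.7471, 0.01)
  expect_lt(abs(sd(b) - 0.04) / 0.04, 0.01)
  g <- rgamma_mm(100000, 294, 0.2 * 294)
  expect_lt(abs(mean(g) - 294) / 294, 0.01)
  expect_lt(abs(sd(g) - 58.8) / 58.8, 0.01)
})

test_that("PSA draws preserve parameter validity and utility ordering", {
  set.seed(3)
  for (i in 1:20) {
    p <- psa_draw(model_params())
    u <- p$econ$utilities
    expect_true(all(u >= 0 & u <= 1))
    expect_true(all(diff(u) <= 1e-12))
    expect_true(all(p$lines$effect_mean >= 0))
    expect_true(all(p$lines$annual_cost >= 0))
    expect_true(p$schedule$cost_secondary_full > 0)
  }
})

test_that("the CEAC is a proper probability curve consistent with NMB logic", {
  set.seed(12)
  dc <- rnorm(400, 300, 400)
  dq <- rnorm(400, 0.03, 0.02)
  cc <- ceac(dc, dq, lambda = seq(0, 50000, by = 5000))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_equal(cc$probability[cc$lambda == 0], mean(dc < 0))

  # all-positive QALY gains make the curve non-decreasing
  dq_pos <- abs(dq) + 1e-6
  cc2 <- ceac(dc, dq_pos, lambda = seq(0, 50000, by = 5000))
  expect_true(all(diff(cc2$probability) >= 0))

  # independent oracle: accept via ICER-with-dominance case analysis
  lambda <- 20000
  accept_cases <- ifelse(dq > 0 & dc <= 0, TRUE,
                  ifelse(dq <= 0 & dc >= 0, FALSE,
                  ifelse(dq > 0, dc / dq < lambda,    # NE quadrant
                         dc / dq > lambda)))          # SW quadrant: ok to lose
  # boundary handling: NMB exactly zero counts as not cost-effective
  nmb_accept <- lambda * dq - dc > 0
  expect_equal(mean(nmb_accept), mean(accept_cases))

  expect_equal(ceac(numeric(0), numeric(0))$probability,
               rep(NaN, 21))
})

test_that("a do-nothing perturbation reproduces the baseline exactly", {
  scen <- data.frame(name = c("pga_x1", "thr_base"),
                     kind = c("pga_cost_mult", "rp_threshold"),
                     value = c(1, 0.06))
  sa <- one_way_sa(scen, model_params(), n = 400, seed = 19)
  expect_equal(sa$icer[2], sa$icer[1], tolerance = 1e-12)
  expect_equal(sa$icer[3], sa$icer[1], tolerance = 1e-12)
  expect_error(one_way_sa(data.frame(name = "x", kind = "bogus", value = 1),
                          model_params(), n = 10, seed = 1), "unknown")
})

test_that("an identical strategy compared with itself has zero increments", {
  coh <- tiny_cohort(200, seed = 8)
  a <- run_strategy(coh, "sc", model_params(), master_seed = 5)
  b <- run_strategy(coh, "sc", model_params(), master_seed = 5)
  ce <- icer(a, b)
  expect_equal(ce$delta_cost, 0)
  expect_equal(ce$delta_qalys, 0)
  expect_equal(ce$label, "undefined, compare costs")
})
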