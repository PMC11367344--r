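test_that("treatment effects scale IOP multiplicatively with adherence", {
  # PGA at its mean effect: 26.51 * (1 - 0.29) = 18.8221
  expect_equal(apply_treatment_effect(26.51, 1L, 1, 0.29), 26.51 * 0.71)
  # zero adherence leaves a medication ineffective
  expect_equal(apply_treatment_effect(26.51, 1L, 0, 0.29), 26.51)
  # procedures ignore adherence
  expect_equal(apply_treatment_effect(26.51, 3L, 0, 0.312), 26.51 * 0.688)
  # a negative draw is clamped: treatment never worsens IOP
  expect_equal(apply_treatment_effect(26.51, 1L, 1, -0.1), 26.51)
  # truncation cap at 0.9
  expect_equal(apply_treatment_effect(20, 4L, 1, 0.95), 20 * 0.1)
})

test_that("the on-target rule is a 20% reduction, boundary inclusive", {
  expect_true(on_target(25, 20))
  expect_false(on_target(25, 20.01))
  expect_false(on_target(25, 25))
})

test_that("escalation walks the sequence and is absorbed at trabeculectomy", {
  expect_equal(escalate(0L), 1L)  # NONE -> PGA
  expect_equal(escalate(1L), 2L)  # PGA -> PGA+BB
  expect_equal(escalate(2L), 3L)  # PGA+BB -> SLT
  expect_equal(escalate(3L), 4L)  # SLT -> TRAB
  expect_equal(escalate(4L), 4L)  # terminal
})

test_that("initial allocation charges the entry assessment and routes by target", {
  prof <- list(age = 62, iop_baseline = 26.51, death_age = 85)
  p <- model_params()
  # untreated: primary care, annual check-up, entry assessment only
  s0 <- initial_allocation(prof, FALSE, p, u_alloc = 0.5,
                           effects = c(0.29, 0.14, 0.312, 0.447))
  expect_equal(s0$cost, p$schedule$cost_secondary_full)
  expect_equal(s0$setting, 1L)
  expect_equal(s0$line, 0L)
  expect_equal(s0$t_checkup, 1)

  # treated on the PGA branch at the mean effect: on target, back to primary
  s1 <- initial_allocation(prof, TRUE, p, u_alloc = 0.5,
                           effects = c(0.29, 0.14, 0.312, 0.447))
  expect_equal(s1$line, 1L)
  expect_equal(s1$iop, 26.51 * 0.71)
  expect_equal(s1$setting, 1L)
  expect_equal(s1$t_checkup, p$schedule$primary_treated_interval)

  # weak PGA response: off target, stays in secondary care
  s2 <- initial_allocation(prof, TRUE, p, u_alloc = 0.5,
                           effects = c(0.1, 0.14, 0.312, 0.447))
  expect_equal(s2$setting, 2L)
  expect_equal(s2$t_checkup, p$schedule$secondary_interval)

  # the SLT branch charges the procedure
  s3 <- initial_allocation(prof, TRUE, p, u_alloc = 0.9,
                           effects = c(0.29, 0.14, 0.312, 0.447))
  expect_equal(s3$line, 3L)
  expect_equal(s3$cost, p$schedule$cost_secondary_full + 151)
})

test_that("check-ups charge the right tests and route referrals", {
  p <- model_params(econ = econ_params(discount = 0))  # undiscounted for exact costs
  prof <- list(age = 62, iop_baseline = 26.51, death_age = 85)

  # untreated primary patient, nothing new: sight-test fee, next visit +1y
  s <- initial_allocation(prof, FALSE, p, u_alloc = 0.5,
                          effects = c(0.29, 0.14, 0.312, 0.447))
  s$t <- 1
  s1 <- process_checkup(s, p)
  expect_equal(s1$last_visit_cost, 23.14)
  expect_equal(s1$t_checkup, 2)
  expect_equal(s1$setting, 1L)

  # true conversion since the last visit: sight test + immediate secondary
  # assessment, transfer to secondary care
  s$converted <- TRUE
  s$true_stage <- oht_stages[["MILD"]]
  s$md <- -2.94
  s2 <- process_checkup(s, p)
  expect_equal(s2$last_visit_cost, 23.14 + 294)
  expect_equal(s2$setting, 2L)
  expect_equal(s2$obs_stage, oht_stages[["MILD"]])
  # confirmed glaucoma is scheduled at the glaucoma interval
  expect_equal(s2$t_checkup, 1 + p$schedule$glaucoma_interval)
  # untreated converter is off target and starts escalation: NONE -> PGA
  expect_equal(s2$line, 1L)

  # treated on-target OHT patient in secondary care returns to primary
  st <- initial_allocation(prof, TRUE, p, u_alloc = 0.5,
                           effects = c(0.29, 0.14, 0.312, 0.447))
  st$setting <- 2L
  st$t <- 0.5
  st1 <- process_checkup(st, p)
  expect_equal(st1$setting, 1L)

  # a dead patient can never be examined
  sd <- s
  sd$t <- 40
  expect_error(process_checkup(sd, p), "dead")
})

test_that("confirmed glaucoma stays in secondary care and escalations are bounded", {
  coh <- tiny_cohort(300, seed = 9)
  res <- run_strategy(coh, "sc", model_params(), master_seed = 3)
  expect_true(all(res$patients$escalations <= 4))
})

test_that("lower adherence weakly raises IOP and lowers aggregate QALYs", {
  prof <- list(age = 62, iop_baseline = 26.51, death_age = 85)
  p1 <- model_params(adherence = 1)
  p75 <- model_params(adherence = 0.75)
  s1 <- initial_allocation(prof, TRUE, p1, u_alloc = 0.5,
                           effects = c(0.29, 0.14, 0.312, 0.447))
  s75 <- initial_allocation(prof, TRUE, p75, u_alloc = 0.5,
                            effects = c(0.29, 0.14, 0.312, 0.447))
  expect_gt(s75$iop, s1$iop)

  coh <- tiny_cohort(400, seed = 13)
  r1 <- run_strategy(coh, "all", p1, master_seed = 2)
  r75 <- run_strategy(coh, "all", p75, master_seed = 2)
  expect_lte(r75$mean_qalys, r1$mean_qalys)
})
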