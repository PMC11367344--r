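test_that("null coefficients give the baseline risk for everyone", {
  coh <- tiny_cohort(50)
  coef <- risk_coefficients(baseline_risk = 0.15, age = 0, iop = 0, cct = 0,
                            psd = 0, vcd = 0)
  expect_equal(five_year_risk(coh, coef), rep(0.15, 50))
})

test_that("risk is monotone in each predictor with conventional signs", {
  coef <- risk_coefficients()
  base <- one_profile()
  bump <- function(field, delta) {
    p <- base
    p[[field]] <- p[[field]] + delta
    p
  }
  expect_gt(five_year_risk(bump("iop_baseline", 4), coef),
            five_year_risk(base, coef))
  expect_gt(five_year_risk(bump("age", 10), coef), five_year_risk(base, coef))
  expect_gt(five_year_risk(bump("psd", 0.5), coef), five_year_risk(base, coef))
  expect_gt(five_year_risk(bump("vcd", 0.2), coef), five_year_risk(base, coef))
  expect_lt(five_year_risk(bump("cct", 40), coef), five_year_risk(base, coef))
  # risks always proper probabilities
  r <- five_year_risk(tiny_cohort(500), coef)
  expect_true(all(r > 0 & r < 1))
})

test_that("the risk threshold is inclusive and monotone in the treated fraction", {
  expect_true(treat_decision_rp(0.06, 0.06))
  expect_false(treat_decision_rp(0.0599, 0.06))
  expect_true(all(treat_decision_rp(c(0, 0.5, 1), 0)))

  risk <- five_year_risk(tiny_cohort(2000), risk_coefficients())
  frac <- vapply(c(0.02, 0.06, 0.10, 0.14, 0.2, 0.5),
                 function(th) mean(treat_decision_rp(risk, th)), numeric(1))
  expect_true(all(diff(frac) <= 0))
})

test_that("the standard-care decision table is a first-match lookup", {
  coh <- tiny_cohort(500)
  always <- data.frame(iop_min = -Inf, iop_max = Inf, age_min = -Inf,
                       age_max = Inf, cct_min = -Inf, cct_max = Inf,
                       treat = TRUE)
  never <- always; never$treat <- FALSE
  expect_equal(mean(treat_decision_sc(coh, always)), 1)
  expect_equal(mean(treat_decision_sc(coh, never)), 0)

  # first matching rule wins: a specific no-treat rule shadows the catch-all
  shadow <- rbind(
    data.frame(iop_min = 30, iop_max = Inf, age_min = -Inf, age_max = Inf,
               cct_min = -Inf, cct_max = Inf, treat = FALSE),
    always)
  dec <- treat_decision_sc(coh, shadow)
  expect_true(all(dec[coh$iop_baseline < 30]))
  expect_false(any(dec[coh$iop_baseline >= 30]))

  # a non-exhaustive table names the uncovered covariate point
  partial <- data.frame(iop_min = 28, iop_max = Inf, age_min = -Inf,
                        age_max = Inf, cct_min = -Inf, cct_max = Inf,
                        treat = TRUE)
  expect_error(treat_decision_sc(coh, partial), "not exhaustive")
})

test_that("the bundled table reads back identically from its text fixture", {
  path <- system.file("extdata", "sc_decision_table.tsv", package = "ohtsim")
  expect_true(nzchar(path))
  tab <- read_sc_table(path)
  coh <- tiny_cohort(1000)
  expect_identical(treat_decision_sc(coh, tab),
                   treat_decision_sc(coh, sc_decision_table()))
})
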