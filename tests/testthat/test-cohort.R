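test_that("cohort sampling is reproducible and respects its bounds", {
  spec <- cohort_spec(n = 2000, seed = 11)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a, b)

  expect_true(all(a$iop_baseline >= 24))
  expect_true(all(a$vcd >= 0 & a$vcd <= 1))
  expect_true(all(a$cct > 0))
  expect_true(all(a$psd > 0))
  expect_true(all(a$death_age > a$age))
  expect_gte(mean(a$iop_baseline), 24)

  empty <- sample_cohort(cohort_spec(n = 0, seed = 1))
  expect_equal(nrow(empty), 0)

  # point-mass limit: zero sd pins every continuous variable at its mean
  pm_spec <- cohort_spec(
    n = 50, seed = 3,
    age = list(mean = 62.01, sd = 0, lower = 35, upper = 95),
    iop = list(mean = 26.51, sd = 0, lower = 24, upper = 40),
    cct = list(mean = 558.66, sd = 0, lower = 400, upper = 700))
  pm <- sample_cohort(pm_spec)
  expect_true(all(pm$age == 62.01))
  expect_true(all(pm$iop_baseline == 26.51))
  expect_true(all(pm$cct == 558.66))
})

test_that("cohort marginals match their targets within 3 standard errors", {
  n <- 20000
  coh <- sample_cohort(cohort_spec(n = n, seed = 7))
  spec <- cohort_spec(n = n, seed = 7)

  # oracle: mean of a normal truncated to [lo, hi]
  trunc_mean <- function(m) {
    a <- (m$lower - m$mean) / m$sd
    b <- (m$upper - m$mean) / m$sd
    m$mean + m$sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  for (v in c("age", "iop", "cct", "psd", "vcd")) {
    col <- c(age = "age", iop = "iop_baseline", cct = "cct", psd = "psd",
             vcd = "vcd")[[v]]
    target <- trunc_mean(spec[[v]])
    se <- sd(coh[[col]]) / sqrt(n)
    expect_lt(abs(mean(coh[[col]]) - target), 3 * se)
  }
  # binary prevalences (exact binomial check at the 99.9% level)
  for (v in names(spec$prevalence)) {
    p <- spec$prevalence[[v]]
    bt <- binom.test(sum(coh[[v]]), n, p)
    expect_gt(bt$p.value, 0.001)
  }
})

test_that("sampled death ages agree with the life table's period life expectancy", {
  lt <- synthetic_life_table()
  # independent oracle: annual cumulative-product life expectancy at age 62
  qx <- lt$qx[lt$age >= 62]
  surv <- cumprod(1 - qx)
  le_oracle <- sum(surv) + 0.5
  set.seed(99)
  draws <- sample_death_age(rep(62, 10000), lt)
  expect_lt(abs(mean(draws - 62) - le_oracle) / le_oracle, 0.02)
  # package closed form agrees with the oracle too
  expect_lt(abs(life_expectancy(lt, 62) - le_oracle) / le_oracle, 0.02)
})

test_that("degenerate life tables pin the death time", {
  certain <- data.frame(age = 0:109, qx = 1)
  set.seed(1)
  d <- sample_death_age(rep(62, 200), certain)
  expect_true(all(d > 62 & d < 63))

  survive <- data.frame(age = 0:109, qx = c(rep(0, 109), 1))
  set.seed(1)
  d2 <- sample_death_age(rep(62, 200), survive)
  expect_true(all(d2 >= 109 & d2 < 110))
})

test_that("MD at conversion follows the moment-matched gamma on the magnitude", {
  set.seed(5)
  x <- sample_md_at_conversion(100000, mean = -2.94, sd = 2.67)
  expect_true(all(x < 0))
  expect_lt(abs(mean(x) - (-2.94)) / 2.94, 0.01)
  expect_lt(abs(sd(x) - 2.67) / 2.67, 0.02)
  # degenerate sd returns the mean exactly
  expect_equal(sample_md_at_conversion(5, mean = -2.94, sd = 0),
               rep(-2.94, 5))
})

test_that("cohorts round-trip losslessly through delimited text", {
  coh <- tiny_cohort(100, seed = 21)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
})

test_that("invalid cohort specifications fail naming the offending field", {
  expect_error(cohort_spec(n = -1), "'n'")
  expect_error(cohort_spec(age = list(mean = 62, sd = -1, lower = 35, upper = 95)),
               "'age'")
  expect_error(cohort_spec(prevalence = c(hypertension = 1.2, family_history = 0.26,
                                          diabetes = 0.14, male = 0.43,
                                          previously_treated = 0.36)),
               "hypertension")
  expect_error(cohort_spec(md_conversion = list(mean = 2.94, sd = 2.67)),
               "md_conversion")
})
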