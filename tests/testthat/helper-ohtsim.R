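# shared test helpers: small cohorts and convenience parameter sets

tiny_cohort <- function(n = 200, seed = 1) {
  sample_cohort(cohort_spec(n = n, seed = seed))
}

# one hand-built profile row for unit tests
one_profile <- function(age = 62, iop = 26.51, cct = 558.66, psd = 1.63,
                        vcd = 0.46, death_age = 85, id = 1L) {
  data.frame(id = id, age = age, iop_baseline = iop, cct = cct, psd = psd,
             vcd = vcd, hypertension = 0L, family_history = 0L, diabetes = 0L,
             male = 0L, previously_treated = 0L, death_age = death_age)
}

# parameters with an effectively zero conversion hazard (no glaucoma)
no_conversion_params <- function(discount = 0.035) {
  coef <- risk_coefficients(age = 0, iop = 0, cct = 0, psd = 0, vcd = 0)
  model_params(risk = coef,
               nh = natural_history_params(h0 = 1e-12, coef = coef),
               econ = econ_params(discount = discount))
}
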