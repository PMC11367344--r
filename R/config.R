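#' Default run configuration
#'
#' The fully expanded configuration of a base-case run as a nested list:
#' cohort spec, risk coefficients, risk threshold, standard-care decision
#' table (inline rows or a file path), natural-history constants, monitoring
#' schedule, treatment lines, economic parameters, adherence and run settings
#' (`n_patients`, `seed`, `mode`). [load_config()] merges a partial YAML file over
#' these defaults.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    n_patients = 50000L,
    seed = 1L,
    mode = "base",
    adherence = 1,
    pga_fraction = 0.8,
    rp_threshold = 0.06,
    cohort = list(
      age = list(mean = 62.01, sd = 10.56, lower = 35, upper = 95),
      iop = list(mean = 26.51, sd = 2.13, lower = 24, upper = 40),
      cct = list(mean = 558.66, sd = 35.83, lower = 400, upper = 700),
      psd = list(mean = 1.63, sd = 0.34, lower = 0.3, upper = 4),
      vcd = list(mean = 0.46, sd = 0.17, lower = 0.05, upper = 0.95),
      prevalence = list(hypertension = 0.12, family_history = 0.26,
                        diabetes = 0.14, male = 0.43,
                        previously_treated = 0.36),
      md_conversion = list(mean = -2.94, sd = 2.67)
    ),
    risk = list(baseline_risk = 1 - exp(-5 * .oht_h0_default),
                age = 0.35, iop = 0.05, cct = 0.22, psd = 0.08, vcd = 0.08,
                hypertension = 0, family_history = 0, diabetes = 0, male = 0),
    natural_history = list(h0 = .oht_h0_default, prog_intercept = 0,
                           prog_slope = 0.15, iop_ref_md = 13,
                           prog_sdlog = 1),
    schedule = list(primary_interval = 1, primary_treated_interval = 0.5,
                    secondary_interval = 0.5,
                    glaucoma_interval = 1 / 3, glaucoma_alternate = TRUE,
                    cost_primary_iop = 11.57, cost_primary_full = 23.14,
                    cost_secondary_iop = 147, cost_secondary_full = 294),
    econ = list(utilities = list(OHT = 0.8015, MILD = 0.8015,
                                 MODERATE = 0.7471, SEVERE = 0.7133,
                                 VI = 0.535),
                discount = 0.035, wtp = 20000),
    sc_table = NULL,      # NULL = bundled default table; or a file path
    life_table = NULL     # NULL = bundled synthetic table; or a file path
  )
}

# recursive merge of user values over defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, "$", key)
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, merges it over [default_config()] (partial overrides
#' keep all other defaults), rejects unknown keys, and validates the values
#' by constructing the corresponding parameter objects. Returns the validated
#' configuration with a `params` ([model_params()]) and `cohort_spec`
#' ([cohort_spec()]) attached.
#'
#' @param path Path to a YAML configuration file, or `NULL` for pure defaults.
#' @return A list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- .merge_config(cfg, user)
  }
  if (cfg$n_patients <= 0) {
    stop("configuration key n_patients must be > 0", call. = FALSE)
  }
  spec <- cohort_spec(
    n = cfg$n_patients, seed = cfg$seed,
    age = cfg$cohort$age, iop = cfg$cohort$iop, cct = cfg$cohort$cct,
    psd = cfg$cohort$psd, vcd = cfg$cohort$vcd,
    prevalence = unlist(cfg$cohort$prevalence),
    md_conversion = cfg$cohort$md_conversion)
  coef <- risk_coefficients(
    baseline_risk = cfg$risk$baseline_risk, age = cfg$risk$age,
    iop = cfg$risk$iop, cct = cfg$risk$cct, psd = cfg$risk$psd,
    vcd = cfg$risk$vcd, hypertension = cfg$risk$hypertension,
    family_history = cfg$risk$family_history, diabetes = cfg$risk$diabetes,
    male = cfg$risk$male)
  nh <- natural_history_params(
    h0 = cfg$natural_history$h0, coef = coef,
    prog_intercept = cfg$natural_history$prog_intercept,
    prog_slope = cfg$natural_history$prog_slope,
    iop_ref_md = cfg$natural_history$iop_ref_md,
    prog_sdlog = cfg$natural_history$prog_sdlog,
    md_conversion = cfg$cohort$md_conversion)
  sched <- do.call(monitoring_schedule, cfg$schedule)
  econ <- econ_params(utilities = unlist(cfg$econ$utilities),
                      discount = cfg$econ$discount, wtp = cfg$econ$wtp)
  sc_tab <- if (is.null(cfg$sc_table)) sc_decision_table()
            else read_sc_table(cfg$sc_table)
  lt <- if (is.null(cfg$life_table)) synthetic_life_table()
        else read_life_table(cfg$life_table)
  params <- model_params(risk = coef, sc_table = sc_tab,
                         rp_threshold = cfg$rp_threshold, nh = nh,
                         schedule = sched, econ = econ,
                         adherence = cfg$adherence,
                         pga_fraction = cfg$pga_fraction)
  cfg$params <- params
  cfg$cohort_spec <- spec
  cfg$life_table <- lt
  class(cfg) <- "run_config"
  cfg
}
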