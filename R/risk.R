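#' Risk-prediction tool coefficients
#'
#' Parameterizes the 5-year glaucoma conversion risk calculator used by the
#' risk-prediction (RP) treatment strategy. The predictor follows the familiar
#' OHTS-EGPS structure: a baseline 5-year conversion probability at reference
#' covariates and per-predictor log-hazard-ratios for age (per decade), IOP
#' (per mmHg), CCT (per 40 um thinner), PSD (per 0.2 dB) and vertical
#' cup-to-disc ratio (per 0.1), plus hooks for hypertension, family history,
#' diabetes and sex (zero by default).
#'
#' The default coefficients are deliberately modest (the tool emulated here has
#' limited discrimination) and are calibrated jointly with the natural-history
#' defaults so that (a) the untreated synthetic cohort converts at about 17%
#' over five years and (b) about 99% of the cohort crosses the 6% treatment
#' threshold. They are configuration, not estimates, and can be replaced.
#'
#' @param baseline_risk Baseline 5-year conversion probability at the reference
#'   covariates (cohort means).
#' @param age,iop,cct,psd,vcd Log-hazard-ratio per decade of age, per mmHg of
#'   IOP, per 40 um of corneal thinning, per 0.2 dB of PSD, per 0.1 of vCD.
#' @param hypertension,family_history,diabetes,male Optional log-hazard-ratios
#'   for the binary risk factors.
#' @param reference Named list of reference covariate values at which the
#'   linear predictor is zero.
#' @return An object of class `risk_coefficients`.
#' @export
risk_coefficients <- function(baseline_risk = 1 - exp(-5 * .oht_h0_default),
                              age = 0.35, iop = 0.05, cct = 0.22,
                              psd = 0.08, vcd = 0.08,
                              hypertension = 0, family_history = 0,
                              diabetes = 0, male = 0,
                              reference = list(age = 62.01, iop = 26.51,
                                               cct = 558.66, psd = 1.63,
                                               vcd = 0.46)) {
  if (baseline_risk <= 0 || baseline_risk >= 1) {
    stop("baseline_risk must be in (0, 1)", call. = FALSE)
  }
  out <- list(baseline_risk = baseline_risk, age = age, iop = iop, cct = cct,
              psd = psd, vcd = vcd, hypertension = hypertension,
              family_history = family_history, diabetes = diabetes,
              male = male, reference = reference)
  class(out) <- "risk_coefficients"
  out
}

# Linear predictor of centred covariates. `iop` and `age` may be overridden so
# the natural-history hazard can share the same predictor with current IOP and
# attained age.
risk_linear_predictor <- function(profile, coef,
                                  iop = profile$iop_baseline,
                                  age = profile$age) {
  ref <- coef$reference
  coef$age * (age - ref$age) / 10 +
    coef$iop * (iop - ref$iop) +
    coef$cct * (ref$cct - profile$cct) / 40 +
    coef$psd * (profile$psd - ref$psd) / 0.2 +
    coef$vcd * (profile$vcd - ref$vcd) / 0.1 +
    coef$hypertension * profile$hypertension +
    coef$family_history * profile$family_history +
    coef$diabetes * profile$diabetes +
    coef$male * profile$male
}

#' Five-year conversion risk
#'
#' Computes each patient's 5-year probability of conversion to glaucoma from
#' baseline covariates via a proportional-hazards transform of the baseline
#' risk: \eqn{risk = 1 - (1 - p_0)^{\exp(LP)}}, where LP is the linear
#' predictor of centred covariates. The result is strictly inside (0, 1),
#' increasing in IOP, age, PSD and vCD and decreasing in CCT when the
#' coefficients carry their conventional signs.
#'
#' @param profile A patient profile data frame (rows are patients) with the
#'   [sample_cohort()] columns.
#' @param coef A [risk_coefficients()] object.
#' @return Numeric vector of 5-year conversion probabilities.
#' @export
#' @examples
#' coh <- sample_cohort(cohort_spec(n = 100, seed = 1))
#' summary(five_year_risk(coh, risk_coefficients()))
five_year_risk <- function(profile, coef = risk_coefficients()) {
  lp <- risk_linear_predictor(profile, coef)
  1 - (1 - coef$baseline_risk)^exp(lp)
}

#' Risk-prediction treatment decision
#'
#' Treat if and only if the 5-year conversion risk is at or above the
#' threshold (boundary inclusive).
#'
#' @param risk Numeric vector of 5-year risks in [0, 1].
#' @param threshold Risk threshold (default 6\%).
#' @return Logical vector.
#' @export
treat_decision_rp <- function(risk, threshold = 0.06) {
  stopifnot(all(risk >= 0 & risk <= 1), threshold >= 0, threshold <= 1.01)
  risk >= threshold
}

#' Default standard-care decision table
#'
#' An ordered rule table over IOP, age and CCT bands deciding treatment
#' initiation under standard care. Each row is a half-open box
#' `[min, max)` in the three covariates with a treat flag; the first matching
#' row wins and the final catch-all row makes the table exhaustive. The
#' bundled defaults encode a clinically conventional pattern (treat high IOP;
#' treat moderate IOP with thin corneas; spare the very elderly and low-IOP
#' thick-cornea patients) and are calibrated so that about 47\% of the default
#' synthetic cohort is treated. Users can replace the table with their own via
#' [read_sc_table()].
#'
#' @return A `data.frame` with columns `iop_min`, `iop_max`, `age_min`,
#'   `age_max`, `cct_min`, `cct_max`, `treat`.
#' @export
sc_decision_table <- function() {
  data.frame(
    iop_min = c(30, 28, 26, 24, -Inf),
    iop_max = c(Inf, 30, 28, 26, Inf),
    age_min = c(-Inf, -Inf, -Inf, -Inf, -Inf),
    age_max = c(Inf, 80, 80, 55, Inf),
    cct_min = c(-Inf, -Inf, -Inf, -Inf, -Inf),
    cct_max = c(Inf, Inf, 555, 555, Inf),
    treat = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Read a standard-care decision table from delimited text
#'
#' One rule per row, tab-separated, with the [sc_decision_table()] columns.
#' Empty bound cells may be written as `-Inf`/`Inf`.
#'
#' @param path File path.
#' @return The validated rule table.
#' @export
read_sc_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("iop_min", "iop_max", "age_min", "age_max", "cct_min", "cct_max",
            "treat")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("decision table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$treat <- as.logical(tab$treat)
  tab
}

#' Standard-care treatment decision
#'
#' Deterministic first-match lookup of each patient in the decision table. If
#' any patient matches no rule the table is not exhaustive and a configuration
#' error naming the uncovered covariate point is raised.
#'
#' @param profile Patient profile data frame.
#' @param table Rule table as from [sc_decision_table()].
#' @return Logical vector: treat or not.
#' @export
treat_decision_sc <- function(profile, table = sc_decision_table()) {
  n <- nrow(profile)
  out <- rep(NA, n)
  for (r in seq_len(nrow(table))) {
    hit <- is.na(out) &
      profile$iop_baseline >= table$iop_min[r] & profile$iop_baseline < table$iop_max[r] &
      profile$age >= table$age_min[r] & profile$age < table$age_max[r] &
      profile$cct >= table$cct_min[r] & profile$cct < table$cct_max[r]
    out[hit] <- table$treat[r]
  }
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop(sprintf(
      "standard-care decision table is not exhaustive: no rule covers IOP=%.2f, age=%.1f, CCT=%.1f",
      profile$iop_baseline[i], profile$age[i], profile$cct[i]), call. = FALSE)
  }
  as.logical(out)
}
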