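# Baseline annual conversion hazard at the reference covariates. Calibrated
# (jointly with the default risk/natural-history coefficients) so that the
# untreated default synthetic cohort converts to glaucoma at ~17% in 5 years.
.oht_h0_default <- 0.0335

#' Glaucoma stages
#'
#' Ordered disease stages used throughout the model: ocular hypertension,
#' then mild / moderate / severe open-angle glaucoma, then visual impairment
#' (absorbing; patients cannot progress further).
#'
#' @format Named integer vector.
#' @export
oht_stages <- c(OHT = 1L, MILD = 2L, MODERATE = 3L, SEVERE = 4L, VI = 5L)

#' Natural-history parameters
#'
#' Constants governing conversion to glaucoma and visual-field progression.
#' Conversion is a proportional-hazards process on the risk-factor linear
#' predictor, with the IOP term evaluated at the *current* (possibly treated)
#' IOP and the age term at attained age. Mean deviation (MD) after conversion
#' declines linearly in time at a rate that increases with current IOP:
#' \eqn{rate = -f_i \max(0, a + b (IOP - iop_ref_md))} dB/year, where
#' \eqn{f_i} is a patient-level heterogeneity factor (lognormal, mean 1)
#' capturing the well-documented spread between slow and fast progressors.
#'
#' Defaults are calibrated to two published anchors: a 17\% untreated 5-year
#' conversion rate and a standard-care end-state distribution of roughly
#' 43/17/24/11/5\% across OHT/mild/moderate/severe/visual impairment.
#'
#' @param h0 Baseline conversion hazard per year at reference covariates.
#' @param coef A [risk_coefficients()] object supplying the log-hazard-ratios
#'   (shared with the risk tool by default).
#' @param prog_intercept Intercept `a` of the MD decline rate (dB/year).
#' @param prog_slope Slope `b` (dB/year per mmHg above `iop_ref_md`).
#' @param iop_ref_md Reference IOP for progression (mmHg); below it (net of
#'   the intercept) MD does not decline.
#' @param prog_sdlog Lognormal sd (log scale) of the patient-level progression
#'   heterogeneity factor; 0 disables heterogeneity. The factor has mean 1.
#' @param stage_thresholds MD cutpoints (dB) separating mild/moderate,
#'   moderate/severe and severe/visual impairment.
#' @param md_conversion List with `mean` (negative dB) and `sd`: the gamma law
#'   (on the magnitude) of MD at the moment of conversion.
#' @return An object of class `natural_history_params`.
#' @export
natural_history_params <- function(h0 = .oht_h0_default,
                                   coef = risk_coefficients(),
                                   prog_intercept = 0,
                                   prog_slope = 0.15,
                                   iop_ref_md = 13,
                                   prog_sdlog = 1,
                                   stage_thresholds = c(mild = -6,
                                                        moderate = -12,
                                                        severe = -20),
                                   md_conversion = list(mean = -2.94,
                                                        sd = 2.67)) {
  if (h0 <= 0) stop("h0 must be > 0", call. = FALSE)
  if (prog_sdlog < 0) stop("prog_sdlog must be >= 0", call. = FALSE)
  if (any(diff(stage_thresholds) >= 0)) {
    stop("stage_thresholds must be strictly decreasing (dB)", call. = FALSE)
  }
  out <- list(h0 = h0, coef = coef, prog_intercept = prog_intercept,
              prog_slope = prog_slope, iop_ref_md = iop_ref_md,
              prog_sdlog = prog_sdlog, stage_thresholds = stage_thresholds,
              md_conversion = md_conversion)
  class(out) <- "natural_history_params"
  out
}

#' Conversion hazard
#'
#' Annual hazard of conversion from OHT to glaucoma,
#' \eqn{h = h_0 \exp(LP)} with the linear predictor evaluated at the current
#' IOP and attained age. Strictly increasing in IOP when the IOP coefficient
#' is positive.
#'
#' @param profile Patient profile rows (baseline covariates).
#' @param current_iop Current (possibly treated) IOP, mmHg.
#' @param params [natural_history_params()].
#' @param attained_age Attained age (defaults to baseline age).
#' @return Hazard per year (vector).
#' @export
conversion_hazard <- function(profile, current_iop, params = natural_history_params(),
                              attained_age = profile$age) {
  stopifnot(all(current_iop > 0))
  lp <- risk_linear_predictor(profile, params$coef,
                              iop = current_iop, age = attained_age)
  params$h0 * exp(lp)
}

#' Sample time to conversion
#'
#' Exponential draw \eqn{t = -\log(U)/h}; memoryless, so the clock may be
#' redrawn whenever the hazard changes. Zero hazard returns `Inf`.
#'
#' @param hazard Hazard per year (vector).
#' @return Time in years (vector).
#' @export
time_to_conversion <- function(hazard) {
  stopifnot(all(hazard >= 0))
  out <- rep(Inf, length(hazard))
  pos <- hazard > 0
  out[pos] <- stats::rexp(sum(pos)) / hazard[pos]
  out
}

#' MD decline rate
#'
#' Rate of mean-deviation loss after conversion,
#' \eqn{rate = -f \max(0, a + b(IOP - ref))} dB/year (never positive: MD does
#' not improve). The magnitude is non-decreasing in IOP.
#'
#' @param current_iop Current IOP, mmHg.
#' @param params [natural_history_params()].
#' @param factor Patient-level heterogeneity factor (default 1).
#' @return dB/year, `<= 0`.
#' @export
md_decline_rate <- function(current_iop, params = natural_history_params(),
                            factor = 1) {
  -factor * pmax(0, params$prog_intercept +
                   params$prog_slope * (current_iop - params$iop_ref_md))
}

#' Stage from mean deviation
#'
#' Maps a (post-conversion) MD value to a glaucoma stage: mild above -6 dB,
#' moderate in (-12, -6], severe in (-20, -12], visual impairment at or below
#' -20 dB. Boundaries are upper-inclusive: an MD exactly at a cutpoint belongs
#' to the worse stage.
#'
#' @param md MD values (dB).
#' @param thresholds Stage cutpoints, as in [natural_history_params()].
#' @return Integer stages (see [oht_stages]).
#' @export
stage_from_md <- function(md, thresholds = c(mild = -6, moderate = -12,
                                             severe = -20)) {
  stage <- rep(oht_stages[["MILD"]], length(md))
  stage[md <= thresholds[[1]]] <- oht_stages[["MODERATE"]]
  stage[md <= thresholds[[2]]] <- oht_stages[["SEVERE"]]
  stage[md <= thresholds[[3]]] <- oht_stages[["VI"]]
  stage
}

#' Time to the next stage boundary
#'
#' Deterministic crossing time of the next stage cutpoint under linear MD
#' decline: \eqn{(md - next\_threshold)/|rate|}. `Inf` when the rate is zero
#' or the patient is already visually impaired. An MD exactly at a cutpoint
#' (already in the worse stage) yields the time to the following cutpoint.
#'
#' @param md Current MD (dB).
#' @param rate Decline rate (dB/year, `<= 0`).
#' @param thresholds Stage cutpoints.
#' @return Years until the next stage is entered.
#' @export
time_to_next_stage <- function(md, rate, thresholds = c(mild = -6,
                                                        moderate = -12,
                                                        severe = -20)) {
  stopifnot(all(rate <= 0))
  stage <- stage_from_md(md, thresholds)
  out <- rep(Inf, length(md))
  for (i in seq_along(md)) {
    if (stage[i] >= oht_stages[["VI"]] || rate[i] == 0) next
    nxt <- thresholds[[stage[i] - 1L]]  # cutpoint into the following stage
    out[i] <- (md[i] - nxt) / abs(rate[i])
  }
  out
}
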