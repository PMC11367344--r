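# Treatment line codes (escalation order; TRAB is terminal)
LINE_NONE <- 0L
LINE_PGA <- 1L
LINE_PGA_BB <- 2L
LINE_SLT <- 3L
LINE_TRAB <- 4L

#' Treatment lines and their effects and costs
#'
#' The escalation sequence NONE -> PGA -> PGA+BB -> SLT -> trabeculectomy with
#' each line's proportional IOP reduction (mean, sd of a normal truncated to
#' [0, 0.9]) and its cost: an annual drug cost for the medication lines
#' (latanoprost \eqn{149.76}/yr; latanoprost+timolol combination
#' \eqn{171.84}/yr) or a one-off procedure cost (SLT \eqn{151};
#' trabeculectomy \eqn{1694}). The PGA+BB effect (0.14) is the *additional*
#' reduction applied on top of the PGA-reduced IOP.
#'
#' @return A `data.frame`, one row per line in escalation order.
#' @export
treatment_lines <- function() {
  data.frame(
    line = c("NONE", "PGA", "PGA_BB", "SLT", "TRAB"),
    code = c(LINE_NONE, LINE_PGA, LINE_PGA_BB, LINE_SLT, LINE_TRAB),
    effect_mean = c(0, 0.29, 0.14, 0.312, 0.447),
    effect_sd = c(0, 0.08, 0.08, 0.08, 0.189),
    annual_cost = c(0, 149.76, 171.84, 0, 0),
    oneoff_cost = c(0, 0, 0, 151, 1694),
    medication = c(FALSE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Apply a treatment effect to the current IOP
#'
#' `new_iop = current_iop * (1 - adherence_eff * r)`, where `r` is the line's
#' proportional reduction (drawn once per patient and line, truncated to
#' [0, 0.9]) and `adherence_eff` is the adherence fraction for medication
#' lines and 1 for procedures (SLT, trabeculectomy ignore adherence).
#'
#' @param current_iop Current IOP (mmHg).
#' @param line Line code (see [treatment_lines()]).
#' @param adherence Adherence fraction in [0, 1].
#' @param r The line's drawn proportional reduction, already truncated.
#' @return New IOP (mmHg).
#' @export
apply_treatment_effect <- function(current_iop, line, adherence, r) {
  stopifnot(all(current_iop > 0), adherence >= 0, adherence <= 1)
  med <- line %in% c(LINE_PGA, LINE_PGA_BB)
  eff <- ifelse(med, adherence, 1) * pmin(pmax(r, 0), 0.9)
  current_iop * (1 - eff)
}

#' Draw per-patient treatment-effect reductions
#'
#' One truncated-normal draw per escalation line (PGA, PGA+BB, SLT, TRAB),
#' clamped to [0, 0.9], using the current RNG stream. Means may be overridden
#' (used by the probabilistic sensitivity analysis).
#'
#' @param lines The [treatment_lines()] table (possibly with perturbed means).
#' @return Numeric vector of length 4, indexed by line code 1..4.
#' @export
draw_treatment_effects <- function(lines = treatment_lines()) {
  act <- lines[lines$code > 0, ]
  pmin(pmax(stats::rnorm(4, act$effect_mean, act$effect_sd), 0), 0.9)
}

#' On-target IOP rule
#'
#' A treated patient is "on target" when the current IOP is reduced by 20\% or
#' more from the baseline IOP at model entry (boundary inclusive).
#'
#' @param baseline_iop Baseline IOP at entry (mmHg).
#' @param current_iop Current IOP (mmHg).
#' @return Logical.
#' @export
on_target <- function(baseline_iop, current_iop) {
  stopifnot(all(baseline_iop > 0), all(current_iop > 0))
  current_iop <= 0.8 * baseline_iop
}

#' Escalate the treatment line
#'
#' Next line in the sequence NONE -> PGA -> PGA+BB -> SLT -> TRAB;
#' trabeculectomy is terminal (escalating it returns TRAB again).
#'
#' @param line Line code(s).
#' @return Next line code(s).
#' @export
escalate <- function(line) {
  pmin(as.integer(line) + 1L, LINE_TRAB)
}

#' Monitoring schedule and test costs
#'
#' Visit intervals and unit costs per care setting. Defaults: annual IOP+VF
#' checks in primary care (NHS sight-test fee 23.14); 6-monthly visits in
#' secondary care, alternating IOP-only (147) and IOP+VF (294) for OHT
#' patients and always IOP+VF (294) for confirmed glaucoma. A newly observed
#' conversion in primary care triggers an immediate secondary IOP+VF
#' assessment (294).
#'
#' @param primary_interval,secondary_interval Years between visits for OHT
#'   monitoring in each setting (untreated patients in primary care).
#' @param primary_treated_interval Years between primary-care reviews of
#'   treated OHT patients (medication reviews are more frequent).
#' @param glaucoma_interval Years between secondary-care visits after a
#'   confirmed conversion.
#' @param glaucoma_alternate Alternate IOP-only and IOP+VF visits for
#'   confirmed glaucoma (otherwise every glaucoma visit is IOP+VF).
#' @param cost_primary_iop,cost_primary_full Primary-care unit costs.
#' @param cost_secondary_iop,cost_secondary_full Secondary-care unit costs.
#' @return An object of class `monitoring_schedule`.
#' @export
monitoring_schedule <- function(primary_interval = 1,
                                primary_treated_interval = 0.5,
                                secondary_interval = 0.5,
                                glaucoma_interval = 1 / 3,
                                glaucoma_alternate = TRUE,
                                cost_primary_iop = 11.57,
                                cost_primary_full = 23.14,
                                cost_secondary_iop = 147,
                                cost_secondary_full = 294) {
  if (primary_interval <= 0 || primary_treated_interval <= 0 ||
      secondary_interval <= 0 || glaucoma_interval <= 0) {
    stop("monitoring intervals must be > 0", call. = FALSE)
  }
  out <- list(primary_interval = primary_interval,
              primary_treated_interval = primary_treated_interval,
              secondary_interval = secondary_interval,
              glaucoma_interval = glaucoma_interval,
              glaucoma_alternate = isTRUE(glaucoma_alternate),
              cost_primary_iop = cost_primary_iop,
              cost_primary_full = cost_primary_full,
              cost_secondary_iop = cost_secondary_iop,
              cost_secondary_full = cost_secondary_full)
  class(out) <- "monitoring_schedule"
  out
}

#' Bundle all model parameters
#'
#' One container for everything a simulation run needs besides the cohort:
#' risk coefficients, the standard-care decision table, the risk threshold,
#' natural-history constants, treatment lines, monitoring schedule, economic
#' parameters, the medication adherence fraction and the PGA/SLT initial
#' allocation split.
#'
#' @param risk [risk_coefficients()].
#' @param sc_table Standard-care decision table.
#' @param rp_threshold 5-year-risk treatment threshold for the RP strategy.
#' @param nh [natural_history_params()].
#' @param lines [treatment_lines()].
#' @param schedule [monitoring_schedule()].
#' @param econ [econ_params()].
#' @param adherence Medication adherence fraction (base case 1; one-way
#'   sensitivity analysis uses 0.75).
#' @param pga_fraction Fraction of initially treated patients given PGA (the
#'   rest receive SLT).
#' @return An object of class `model_params`.
#' @export
model_params <- function(risk = risk_coefficients(),
                         sc_table = sc_decision_table(),
                         rp_threshold = 0.06,
                         nh = natural_history_params(coef = risk),
                         lines = treatment_lines(),
                         schedule = monitoring_schedule(),
                         econ = econ_params(),
                         adherence = 1,
                         pga_fraction = 0.8) {
  if (adherence < 0 || adherence > 1) {
    stop("adherence must be in [0, 1]", call. = FALSE)
  }
  if (rp_threshold < 0 || rp_threshold > 1.01) {
    stop("rp_threshold must be a probability", call. = FALSE)
  }
  out <- list(risk = risk, sc_table = sc_table, rp_threshold = rp_threshold,
              nh = nh, lines = lines, schedule = schedule, econ = econ,
              adherence = adherence, pga_fraction = pga_fraction)
  class(out) <- "model_params"
  out
}

# settings
SETTING_PRIMARY <- 1L
SETTING_SECONDARY <- 2L

#' Initial treatment allocation
#'
#' Builds a patient's starting state under a strategy's treatment decision.
#' Every patient is charged one secondary-care IOP+VF visit at entry (the
#' initial decision is made by a secondary-care professional). Treated
#' patients receive PGA (with probability `pga_fraction`) or SLT (procedure
#' cost charged), have the treatment effect applied, and start in primary
#' care if on target or in secondary care otherwise. Untreated patients start
#' in primary care with an annual check-up.
#'
#' @param profile One patient profile (single row or list).
#' @param treat Logical treatment decision (from the strategy rule).
#' @param params [model_params()].
#' @param u_alloc Uniform draw deciding PGA vs SLT.
#' @param effects Per-line effect draws from [draw_treatment_effects()].
#' @return A patient state list (fields documented in [process_checkup()]).
#' @export
initial_allocation <- function(profile, treat, params,
                               u_alloc = stats::runif(1),
                               effects = draw_treatment_effects(params$lines)) {
  iop0 <- profile$iop_baseline
  s <- list(t = 0, age0 = profile$age, baseline_iop = iop0, iop = iop0,
            md = NA_real_, true_stage = oht_stages[["OHT"]],
            obs_stage = oht_stages[["OHT"]],
            setting = SETTING_PRIMARY, line = LINE_NONE,
            adherence = params$adherence,
            treated = isTRUE(treat), converted = FALSE,
            effects = effects, sec_parity = 0L, escalations = 0L,
            cost = params$schedule$cost_secondary_full,  # entry assessment, t = 0
            t_checkup = params$schedule$primary_interval,
            t_death = profile$death_age - profile$age)
  if (isTRUE(treat)) {
    if (u_alloc < params$pga_fraction) {
      s$line <- LINE_PGA
    } else {
      s$line <- LINE_SLT
      s$cost <- s$cost + params$lines$oneoff_cost[params$lines$code == LINE_SLT]
    }
    s$iop <- apply_treatment_effect(s$iop, s$line, s$adherence, effects[s$line])
    if (on_target(s$baseline_iop, s$iop)) {
      s$setting <- SETTING_PRIMARY
      s$t_checkup <- params$schedule$primary_treated_interval
    } else {
      s$setting <- SETTING_SECONDARY
      s$t_checkup <- params$schedule$secondary_interval
    }
  }
  s
}

# escalate once, charging procedure costs and re-applying effects; returns the
# state with updated line/iop/cost. Discount factor df applies to the charge.
.escalate_once <- function(s, params, df) {
  if (s$line >= LINE_TRAB) return(s)
  s$line <- s$line + 1L
  s$escalations <- s$escalations + 1L
  oneoff <- params$lines$oneoff_cost[s$line + 1L]
  if (oneoff > 0) s$cost <- s$cost + oneoff * df
  r <- s$effects[s$line]
  if (r < 0) r <- 0 else if (r > 0.9) r <- 0.9
  eff <- if (s$line <= 2L) s$adherence * r else r
  s$iop <- s$iop * (1 - eff)
  s
}

#' Process a monitoring check-up
#'
#' Fires one check-up event at `state$t`: charges the setting's test cost,
#' synchronizes the observed stage with the true stage, and applies the
#' referral and escalation logic: a newly observed conversion in primary care
#' triggers an immediate secondary IOP+VF assessment and transfer to secondary
#' care (confirmed glaucoma never returns to primary care); treated off-target
#' patients are escalated one line (procedure costs charged, IOP effect
#' re-applied) and, if in primary care, transferred to secondary care; treated
#' on-target OHT patients in secondary care are returned to primary care after
#' the one visit. Finally the next check-up is scheduled per the setting's
#' interval. Costs are discounted to model entry at the economic discount
#' rate.
#'
#' @param state Patient state list (see [initial_allocation()]).
#' @param params [model_params()].
#' @return The updated state; the incurred (discounted) cost is accumulated in
#'   `state$cost` and the change is returned in attribute-free field
#'   `state$last_visit_cost`.
#' @export
process_checkup <- function(state, params) {
  s <- state
  if (s$t >= s$t_death) stop("check-up fired for a dead patient", call. = FALSE)
  sched <- params$schedule
  rho <- log1p(params$econ$discount)
  df <- exp(-rho * s$t)
  cost0 <- s$cost
  glaucoma_known <- s$obs_stage > 1L
  # visit cost by setting and (observed) state
  if (s$setting == SETTING_PRIMARY) {
    s$cost <- s$cost + sched$cost_primary_full * df
  } else if (glaucoma_known) {
    if (sched$glaucoma_alternate) {
      s$cost <- s$cost + (if (s$sec_parity == 0L) sched$cost_secondary_iop
                          else sched$cost_secondary_full) * df
      s$sec_parity <- 1L - s$sec_parity
    } else {
      s$cost <- s$cost + sched$cost_secondary_full * df
    }
  } else {
    s$cost <- s$cost + (if (s$sec_parity == 0L) sched$cost_secondary_iop
                        else sched$cost_secondary_full) * df
    s$sec_parity <- 1L - s$sec_parity
  }
  newly_observed <- s$converted && !glaucoma_known
  s$obs_stage <- s$true_stage
  if (newly_observed && s$setting == SETTING_PRIMARY) {
    # immediate confirmatory assessment in secondary care
    s$cost <- s$cost + sched$cost_secondary_full * df
    s$setting <- SETTING_SECONDARY
  } else if (newly_observed) {
    s$setting <- SETTING_SECONDARY
  }
  on_tgt <- s$iop <= 0.8 * s$baseline_iop
  if (s$obs_stage > 1L) {
    # confirmed glaucoma: stay in secondary care; escalate while off target
    s$setting <- SETTING_SECONDARY
    if (!on_tgt && s$line < LINE_TRAB) {
      s <- .escalate_once(s, params, df)
    }
  } else if (s$line > LINE_NONE) {
    # treated OHT
    if (!on_tgt) {
      s$setting <- SETTING_SECONDARY
      if (s$line < LINE_TRAB) s <- .escalate_once(s, params, df)
    } else if (s$setting == SETTING_SECONDARY) {
      s$setting <- SETTING_PRIMARY  # returned after one clinical visit
    }
  }
  s$t_checkup <- s$t +
    (if (s$setting == SETTING_PRIMARY) {
       if (s$line > 0L) sched$primary_treated_interval
       else sched$primary_interval
     } else if (s$obs_stage > 1L) sched$glaucoma_interval
     else sched$secondary_interval)
  s$last_visit_cost <- s$cost - cost0
  s
}
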