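# discounted accrual of a constant annual value over [t0, t1]
.disc_int <- function(value, t0, t1, rho) {
  if (rho == 0) return(value * (t1 - t0))
  value * (exp(-rho * t0) - exp(-rho * t1)) / rho
}

# scalar time-to-next-stage (engine hot path)
.next_stage_time <- function(md, rate, thr) {
  if (rate == 0) return(Inf)
  if (md <= thr[[3L]]) return(Inf)       # visual impairment: absorbing
  nxt <- if (md > thr[[1L]]) thr[[1L]] else if (md > thr[[2L]]) thr[[2L]] else thr[[3L]]
  (md - nxt) / abs(rate)
}

#' Simulate one patient
#'
#' Runs the full competing-events loop for a single patient under a given
#' treatment decision: repeatedly computes the three event clocks (next
#' check-up, next natural-history event, death) and fires the earliest.
#' Conversion samples the MD at conversion and enters the corresponding
#' glaucoma stage; stage progression follows the linear MD decline; death
#' closes the record. Utilities accrue continuously at the *true* stage's
#' utility between events; costs are charged at event times. Both are
#' discounted to model entry.
#'
#' @param profile One patient profile (single-row data frame or list).
#' @param treat Logical: initial treatment decision.
#' @param params [model_params()].
#' @param seed Integer seed for this patient's random stream (common random
#'   numbers across strategies reuse the same per-patient seed).
#' @param trace Keep an event log (slower; for inspection).
#' @return A list with `cost`, `qaly` (discounted totals), `converted`,
#'   `conv_time` (years to conversion, `NA` if never), `treated`,
#'   `final_stage`, `events`, `escalations`, and `log` (a data frame when
#'   `trace = TRUE`).
#' @export
simulate_patient <- function(profile, treat, params, seed = 1L, trace = FALSE) {
  coef <- params$nh$coef
  lp_full <- risk_linear_predictor(profile, coef)
  lp_static <- lp_full - coef$iop * (profile$iop_baseline - coef$reference$iop) -
    coef$age * (profile$age - coef$reference$age) / 10
  .simulate_one(age0 = profile$age, iop0 = profile$iop_baseline,
                death_age = profile$death_age, lp_static = lp_static,
                treat = treat, params = params, seed = as.integer(seed),
                trace = trace, pid = profile$id)
}

.simulate_one <- function(age0, iop0, death_age, lp_static, treat, params,
                          seed, trace = FALSE, pid = NA_integer_) {
  set.seed(seed)
  nh <- params$nh
  coef <- nh$coef
  sched <- params$schedule
  rho <- log1p(params$econ$discount)
  util <- params$econ$utilities
  ann_cost <- params$lines$annual_cost
  thr <- nh$stage_thresholds
  b_iop <- coef$iop
  b_age10 <- coef$age / 10
  ref_iop <- coef$reference$iop
  ref_age <- coef$reference$age
  h0 <- nh$h0

  # fixed per-patient draw order: allocation, line effects, MD at conversion,
  # progression heterogeneity; in-loop draws follow
  u_alloc <- stats::runif(1)
  effects <- draw_treatment_effects(params$lines)
  md_conv <- sample_md_at_conversion(1, nh$md_conversion$mean,
                                     nh$md_conversion$sd)
  prog_factor <- if (nh$prog_sdlog > 0) {
    stats::rlnorm(1, -nh$prog_sdlog^2 / 2, nh$prog_sdlog)
  } else 1

  s <- initial_allocation(list(age = age0, iop_baseline = iop0,
                               death_age = death_age),
                          treat, params, u_alloc, effects)
  hz <- function(iop, t) h0 * exp(lp_static + b_iop * (iop - ref_iop) +
                                    b_age10 * (age0 + t - ref_age))
  t <- 0
  qaly <- 0
  rate <- 0
  conv_time <- NA_real_
  t_conv <- stats::rexp(1) / hz(s$iop, 0)
  t_prog <- Inf
  events <- 0L
  log <- if (trace) list(list(time = 0, event = "ALLOCATION",
                              setting = s$setting, line = s$line,
                              cost = s$cost, md = NA_real_, iop = s$iop,
                              stage = s$true_stage)) else NULL

  repeat {
    events <- events + 1L
    if (events > 10000L) {
      stop(sprintf("simulation error: patient %s exceeded 10000 events", pid),
           call. = FALSE)
    }
    t_nh <- min(t_conv, t_prog)
    t_next <- min(s$t_checkup, t_nh, s$t_death)
    # continuous accrual between events: utility at the true stage, annual
    # medication cost while a medication line is active
    qaly <- qaly + .disc_int(util[[s$true_stage]], t, t_next, rho)
    med <- ann_cost[s$line + 1L]
    if (med > 0) s$cost <- s$cost + .disc_int(med, t, t_next, rho)
    if (s$converted && rate < 0) s$md <- s$md + rate * (t_next - t)
    t <- t_next

    if (t >= s$t_death) {
      if (trace) log[[length(log) + 1L]] <- list(time = t, event = "DEATH",
                                                 setting = s$setting,
                                                 line = s$line, cost = s$cost,
                                                 md = s$md, iop = s$iop,
                                                 stage = s$true_stage)
      break
    }
    if (t_nh <= s$t_checkup) {
      if (!s$converted) {
        # conversion: enter the stage implied by the sampled MD
        s$converted <- TRUE
        conv_time <- t
        s$md <- md_conv
        s$true_stage <- stage_from_md(md_conv, thr)
        rate <- md_decline_rate(s$iop, nh, prog_factor)
        t_prog <- t + .next_stage_time(s$md, rate, thr)
        t_conv <- Inf
        if (trace) log[[length(log) + 1L]] <- list(time = t, event = "CONVERSION",
                                                   setting = s$setting,
                                                   line = s$line, cost = s$cost,
                                                   md = s$md, iop = s$iop,
                                                   stage = s$true_stage)
      } else {
        # progression to the next stage (VI is absorbing)
        s$true_stage <- s$true_stage + 1L
        s$md <- thr[[s$true_stage - 2L]]  # cutpoint just crossed
        t_prog <- t + .next_stage_time(s$md, rate, thr)
        if (trace) log[[length(log) + 1L]] <- list(time = t, event = "PROGRESSION",
                                                   setting = s$setting,
                                                   line = s$line, cost = s$cost,
                                                   md = s$md, iop = s$iop,
                                                   stage = s$true_stage)
      }
    } else {
      # check-up
      old_iop <- s$iop
      s$t <- t
      s <- process_checkup(s, params)
      if (s$iop != old_iop) {
        if (s$converted) {
          rate <- md_decline_rate(s$iop, nh, prog_factor)
          t_prog <- t + .next_stage_time(s$md, rate, thr)
        }
      }
      if (!s$converted) t_conv <- t + stats::rexp(1) / hz(s$iop, t)
      if (trace) log[[length(log) + 1L]] <- list(time = t, event = "CHECKUP",
                                                 setting = s$setting,
                                                 line = s$line, cost = s$cost,
                                                 md = s$md, iop = s$iop,
                                                 stage = s$true_stage)
    }
  }
  list(id = pid, cost = s$cost, qaly = qaly, converted = s$converted,
       conv_time = conv_time,
       treated = s$treated, final_stage = s$true_stage, events = events,
       escalations = s$escalations,
       log = if (trace) do.call(rbind, lapply(log, as.data.frame)) else NULL)
}

#' Run a strategy over a cohort
#'
#' Simulates every patient in the cohort under the named strategy. The
#' treatment decision is computed once per patient at model entry (the
#' risk-prediction rule at `rp_threshold`, or the standard-care decision
#' table). Per-patient random substreams are derived deterministically from
#' the master seed and the patient id, so the two strategies can be run with
#' common random numbers on the identical cohort.
#'
#' @param cohort An `oht_cohort` data frame (non-empty).
#' @param strategy `"sc"` (standard care), `"rp"` (risk prediction), or the
#'   diagnostic variants `"none"` / `"all"`.
#' @param params [model_params()].
#' @param master_seed Integer master seed for the per-patient substreams.
#' @return An object of class `strategy_result`: strategy name, `n`, mean
#'   discounted cost and QALYs, fraction initially treated, fraction ever
#'   converted, the end-state distribution, and the per-patient summary in
#'   `$patients`.
#' @export
run_strategy <- function(cohort, strategy = c("sc", "rp", "none", "all"),
                         params = model_params(), master_seed = 1L) {
  strategy <- match.arg(strategy)
  n <- nrow(cohort)
  if (is.null(n) || n == 0) {
    stop("configuration error: cohort is empty", call. = FALSE)
  }
  decisions <- switch(strategy,
    sc = treat_decision_sc(cohort, params$sc_table),
    rp = treat_decision_rp(five_year_risk(cohort, params$risk),
                           params$rp_threshold),
    none = rep(FALSE, n),
    all = rep(TRUE, n))
  coef <- params$nh$coef
  lp_full <- risk_linear_predictor(cohort, coef)
  lp_static <- lp_full - coef$iop * (cohort$iop_baseline - coef$reference$iop) -
    coef$age * (cohort$age - coef$reference$age) / 10

  cost <- numeric(n); qaly <- numeric(n); converted <- logical(n)
  conv_time <- rep(NA_real_, n)
  stage <- integer(n); events <- integer(n); escal <- integer(n)
  seeds <- (as.numeric(master_seed) + as.numeric(cohort$id) * 10007) %% 2147483647
  age <- cohort$age; iop <- cohort$iop_baseline; death <- cohort$death_age
  for (i in seq_len(n)) {
    rec <- .simulate_one(age[i], iop[i], death[i], lp_static[i], decisions[i],
                         params, as.integer(seeds[i]), FALSE, cohort$id[i])
    cost[i] <- rec$cost; qaly[i] <- rec$qaly
    converted[i] <- rec$converted; conv_time[i] <- rec$conv_time
    stage[i] <- rec$final_stage
    events[i] <- rec$events; escal[i] <- rec$escalations
  }
  end_state <- tabulate(stage, nbins = 5L) / n
  names(end_state) <- names(oht_stages)
  out <- list(strategy = strategy, n = n,
              mean_cost = mean(cost), mean_qalys = mean(qaly),
              prop_treated = mean(decisions), prop_converted = mean(converted),
              end_state = end_state,
              patients = data.frame(id = cohort$id, cost = cost, qaly = qaly,
                                    treated = decisions, converted = converted,
                                    conv_time = conv_time,
                                    final_stage = stage, events = events,
                                    escalations = escal))
  class(out) <- "strategy_result"
  out
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s strategy, n = %d\n", toupper(x$strategy), x$n))
  cat(sprintf("  initially treated: %.1f%%   converted: %.1f%%\n",
              100 * x$prop_treated, 100 * x$prop_converted))
  cat(sprintf("  mean discounted cost:  %.0f\n", x$mean_cost))
  cat(sprintf("  mean discounted QALYs: %.3f\n", x$mean_qalys))
  cat("  end-state distribution (%):\n")
  print(round(100 * x$end_state, 1))
  invisible(x)
}
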