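#' Economic parameters
#'
#' Stage utilities (EQ-5D-style), the annual discount rate and the
#' willingness-to-pay threshold. Default utilities: OHT and mild glaucoma
#' 0.8015, moderate 0.7471, severe 0.7133, visual impairment 0.535; discount
#' 3.5\%/year; threshold 20,000 per QALY.
#'
#' @param utilities Named numeric vector over the five stages, non-increasing
#'   with severity, each in [0, 1].
#' @param discount Annual discount rate (applied continuously as
#'   \eqn{\rho = \log(1 + rate)}).
#' @param wtp Willingness-to-pay threshold (currency per QALY).
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(utilities = c(OHT = 0.8015, MILD = 0.8015,
                                      MODERATE = 0.7471, SEVERE = 0.7133,
                                      VI = 0.535),
                        discount = 0.035,
                        wtp = 20000) {
  if (length(utilities) != 5) stop("utilities must have 5 stages", call. = FALSE)
  if (any(utilities < 0 | utilities > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(utilities) > 1e-12)) {
    stop("utilities must be non-increasing with stage severity", call. = FALSE)
  }
  if (discount < 0) stop("discount must be >= 0", call. = FALSE)
  out <- list(utilities = utilities, discount = discount, wtp = wtp)
  class(out) <- "econ_params"
  out
}

#' Discounted accrual of a constant annual value
#'
#' Continuous-time discounting of a constant rate over an interval:
#' \eqn{v (e^{-\rho t_0} - e^{-\rho t_1})/\rho} with
#' \eqn{\rho = \log(1 + rate)}; the zero-discount limit is \eqn{v (t_1-t_0)}.
#'
#' @param value Annual value (utility or cost rate).
#' @param t0,t1 Interval bounds in years, `t1 >= t0 >= 0`.
#' @param rate Annual discount rate (default 3.5\%).
#' @return Discounted accrued amount.
#' @export
#' @examples
#' discounted_accrual(0.8015, 0, 1, 0.035)  # ~0.7879
discounted_accrual <- function(value, t0, t1, rate = 0.035) {
  if (any(t1 < t0) || any(t0 < 0)) {
    stop("need t1 >= t0 >= 0", call. = FALSE)
  }
  rho <- log1p(rate)
  if (rho == 0) return(value * (t1 - t0))
  value * (exp(-rho * t0) - exp(-rho * t1)) / rho
}

#' Incremental cost-effectiveness of RP versus SC
#'
#' Computes incremental cost, incremental QALYs and the ICER (or a dominance
#' label) of the risk-prediction strategy against standard care from two
#' strategy results on matched cohorts.
#'
#' @param sc,rp [run_strategy()] results for the standard-care and
#'   risk-prediction arms.
#' @return A list of class `ce_result` with `delta_cost`, `delta_qalys`,
#'   `icer` (number or `NA`), and `label` (one of `"ICER"`, `"RP dominant"`,
#'   `"RP dominated"`, `"undefined, compare costs"`).
#' @export
icer <- function(sc, rp) {
  dc <- rp$mean_cost - sc$mean_cost
  dq <- rp$mean_qalys - sc$mean_qalys
  if (dq == 0) {
    out <- list(delta_cost = dc, delta_qalys = dq, icer = NA_real_,
                label = "undefined, compare costs")
  } else if (dc <= 0 && dq > 0) {
    out <- list(delta_cost = dc, delta_qalys = dq, icer = NA_real_,
                label = "RP dominant")
  } else if (dc >= 0 && dq < 0) {
    out <- list(delta_cost = dc, delta_qalys = dq, icer = NA_real_,
                label = "RP dominated")
  } else {
    out <- list(delta_cost = dc, delta_qalys = dq, icer = dc / dq,
                label = "ICER")
  }
  class(out) <- "ce_result"
  out
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> RP vs SC\n")
  cat(sprintf("  incremental cost:  %.1f\n", x$delta_cost))
  cat(sprintf("  incremental QALYs: %.4f\n", x$delta_qalys))
  if (x$label == "ICER") cat(sprintf("  ICER: %.0f per QALY\n", x$icer))
  else cat(sprintf("  %s\n", x$label))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA replicates with
#' positive net monetary benefit \eqn{\lambda \Delta Q - \Delta C > 0}.
#'
#' @param delta_cost,delta_qalys Per-replicate incremental costs and QALYs.
#' @param lambda Vector of willingness-to-pay values.
#' @return Data frame with columns `lambda` and `probability`.
#' @export
ceac <- function(delta_cost, delta_qalys, lambda = seq(0, 50000, by = 2500)) {
  stopifnot(length(delta_cost) == length(delta_qalys))
  prob <- vapply(lambda,
                 function(l) mean(l * delta_qalys - delta_cost > 0),
                 numeric(1))
  data.frame(lambda = lambda, probability = prob)
}

#' One-way sensitivity analysis
#'
#' Re-runs both strategies on the same cohort with matched per-patient seeds
#' for a set of single-parameter perturbations and reports the ICER of each
#' scenario next to the unperturbed baseline. Each scenario perturbs exactly
#' one parameter; supported kinds are `"rp_threshold"` (absolute value),
#' `"pga_cost_mult"`, `"primary_full_cost_mult"`, `"secondary_full_cost_mult"`
#' (multipliers on the respective unit cost) and `"adherence"` (absolute
#' value).
#'
#' @param scenarios A data frame with columns `name`, `kind`, `value`.
#' @param params Baseline [model_params()].
#' @param n Patients per run (the sensitivity analyses use a reduced cohort).
#' @param seed Master seed (cohort and per-patient substreams).
#' @param cohort_spec_base Optional [cohort_spec()] template.
#' @return Data frame with one row per scenario (baseline first): name, kind,
#'   value, delta_cost, delta_qalys, icer, label.
#' @export
one_way_sa <- function(scenarios, params = model_params(), n = 10000,
                       seed = 1L, cohort_spec_base = NULL) {
  kinds <- c("rp_threshold", "pga_cost_mult", "primary_full_cost_mult",
             "secondary_full_cost_mult", "adherence")
  if (!all(c("name", "kind", "value") %in% names(scenarios))) {
    stop("scenarios needs columns name, kind, value", call. = FALSE)
  }
  bad <- !scenarios$kind %in% kinds
  if (any(bad)) {
    stop("unknown scenario kind: ", scenarios$kind[bad][1], call. = FALSE)
  }
  spec <- if (is.null(cohort_spec_base)) cohort_spec(n = n, seed = seed)
          else { cohort_spec_base$n <- n; cohort_spec_base$seed <- seed; cohort_spec_base }
  coh <- sample_cohort(spec)
  run_one <- function(p) {
    sc <- run_strategy(coh, "sc", p, master_seed = seed)
    rp <- run_strategy(coh, "rp", p, master_seed = seed)
    icer(sc, rp)
  }
  base <- run_one(params)
  rows <- list(data.frame(name = "baseline", kind = "baseline", value = NA_real_,
                          delta_cost = base$delta_cost,
                          delta_qalys = base$delta_qalys,
                          icer = ifelse(is.na(base$icer), NA_real_, base$icer),
                          label = base$label))
  for (i in seq_len(nrow(scenarios))) {
    p <- perturb_params(params, scenarios$kind[i], scenarios$value[i])
    ce <- run_one(p)
    rows[[i + 1L]] <- data.frame(name = scenarios$name[i],
                                 kind = scenarios$kind[i],
                                 value = scenarios$value[i],
                                 delta_cost = ce$delta_cost,
                                 delta_qalys = ce$delta_qalys,
                                 icer = ifelse(is.na(ce$icer), NA_real_, ce$icer),
                                 label = ce$label)
  }
  do.call(rbind, rows)
}

#' Perturb one model parameter
#'
#' Helper behind [one_way_sa()]: returns a copy of `params` with exactly one
#' parameter changed.
#'
#' @param params [model_params()].
#' @param kind Scenario kind (see [one_way_sa()]).
#' @param value New value or multiplier.
#' @return Modified `model_params`.
#' @export
perturb_params <- function(params, kind, value) {
  p <- params
  switch(kind,
    rp_threshold = { p$rp_threshold <- value },
    pga_cost_mult = {
      med <- p$lines$code %in% c(LINE_PGA, LINE_PGA_BB)
      p$lines$annual_cost[med] <- p$lines$annual_cost[med] * value
    },
    primary_full_cost_mult = {
      p$schedule$cost_primary_full <- p$schedule$cost_primary_full * value
    },
    secondary_full_cost_mult = {
      p$schedule$cost_secondary_full <- p$schedule$cost_secondary_full * value
    },
    adherence = { p$adherence <- value },
    stop("unknown scenario kind: ", kind, call. = FALSE))
  p
}

# moment-matched second-order distributions ---------------------------------

#' Moment-matched Beta and Gamma draws
#'
#' Standard health-economics parameterizations for probabilistic sensitivity
#' analysis: `rbeta_mm` draws from a Beta with given mean and sd (utilities),
#' `rgamma_mm` from a Gamma with given mean and sd (unit costs).
#'
#' @param n Number of draws.
#' @param mean,sd Target moments (`mean` in (0,1) for the Beta).
#' @return Numeric vector.
#' @export
rbeta_mm <- function(n, mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  v <- sd^2
  if (v >= mean * (1 - mean)) stop("sd too large for a Beta", call. = FALSE)
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' @rdname rbeta_mm
#' @export
rgamma_mm <- function(n, mean, sd) {
  stopifnot(mean > 0, sd > 0)
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Draw one second-order parameter set
#'
#' Draws a replicate's parameter set for the probabilistic sensitivity
#' analysis: treatment-effect means from normals truncated at zero (sd from
#' the effectiveness table), stage utilities from moment-matched Betas
#' (re-sorted to preserve the severity ordering), and unit costs from
#' moment-matched Gammas with sd equal to `cost_cv` times the mean.
#'
#' @param params Baseline [model_params()].
#' @param utility_sd Absolute sd of the utility distributions.
#' @param cost_cv Coefficient of variation of the unit-cost distributions.
#' @return A `model_params` copy with perturbed values.
#' @export
psa_draw <- function(params, utility_sd = 0.04, cost_cv = 0.2) {
  p <- params
  act <- p$lines$code > 0
  m <- stats::rnorm(sum(act), p$lines$effect_mean[act], p$lines$effect_sd[act])
  p$lines$effect_mean[act] <- pmin(pmax(m, 0), 0.9)
  u0 <- p$econ$utilities
  u <- vapply(u0, function(m) rbeta_mm(1, m, utility_sd), numeric(1))
  p$econ$utilities <- stats::setNames(sort(u, decreasing = TRUE), names(u0))
  for (f in c("cost_primary_iop", "cost_primary_full", "cost_secondary_iop",
              "cost_secondary_full")) {
    m0 <- p$schedule[[f]]
    p$schedule[[f]] <- rgamma_mm(1, m0, cost_cv * m0)
  }
  ann <- p$lines$annual_cost > 0
  p$lines$annual_cost[ann] <- vapply(p$lines$annual_cost[ann],
                                     function(m) rgamma_mm(1, m, cost_cv * m),
                                     numeric(1))
  one <- p$lines$oneoff_cost > 0
  p$lines$oneoff_cost[one] <- vapply(p$lines$oneoff_cost[one],
                                     function(m) rgamma_mm(1, m, cost_cv * m),
                                     numeric(1))
  p
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_reps` replicates: each draws one second-order parameter set via
#' [psa_draw()], generates a fresh cohort, simulates both strategies with
#' common random numbers, and records the incremental cost and QALYs. Returns
#' the replicate scatter, the CEAC over a willingness-to-pay grid, and the
#' probability of cost-effectiveness at the base threshold.
#'
#' @param n_patients Patients per replicate.
#' @param n_reps Number of replicates (second-order draws).
#' @param params Baseline [model_params()].
#' @param seed Master seed.
#' @param lambda Willingness-to-pay grid for the CEAC.
#' @param utility_sd,cost_cv Passed to [psa_draw()].
#' @param cohort_spec_base Optional [cohort_spec()] template.
#' @return An object of class `psa_result`: `scatter` (data frame of
#'   `delta_cost`, `delta_qalys`), `ceac`, and `prob_ce_at_wtp`.
#' @export
run_psa <- function(n_patients = 2000, n_reps = 100, params = model_params(),
                    seed = 1L, lambda = seq(0, 50000, by = 2500),
                    utility_sd = 0.04, cost_cv = 0.2,
                    cohort_spec_base = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  dc <- numeric(n_reps); dq <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- as.integer((as.numeric(seed) + r * 1000003) %% 2147483647)
    set.seed(rep_seed)
    p <- psa_draw(params, utility_sd = utility_sd, cost_cv = cost_cv)
    spec <- if (is.null(cohort_spec_base)) cohort_spec(n = n_patients, seed = rep_seed)
            else { cohort_spec_base$n <- n_patients; cohort_spec_base$seed <- rep_seed; cohort_spec_base }
    coh <- sample_cohort(spec)
    sc <- run_strategy(coh, "sc", p, master_seed = rep_seed)
    rp <- run_strategy(coh, "rp", p, master_seed = rep_seed)
    dc[r] <- rp$mean_cost - sc$mean_cost
    dq[r] <- rp$mean_qalys - sc$mean_qalys
  }
  cc <- ceac(dc, dq, lambda)
  wtp <- params$econ$wtp
  out <- list(scatter = data.frame(delta_cost = dc, delta_qalys = dq),
              ceac = cc,
              prob_ce_at_wtp = mean(wtp * dq - dc > 0),
              wtp = wtp, n_patients = n_patients, n_reps = n_reps)
  class(out) <- "psa_result"
  out
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d replicates x %d patients\n", x$n_reps, x$n_patients))
  cat(sprintf("  mean incremental cost:  %.1f\n", mean(x$scatter$delta_cost)))
  cat(sprintf("  mean incremental QALYs: %.4f\n", mean(x$scatter$delta_qalys)))
  cat(sprintf("  P(cost-effective at %.0f/QALY) = %.2f\n", x$wtp, x$prob_ce_at_wtp))
  invisible(x)
}
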