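# Discounting, cost streams, utility/QALY streams, and aggregation into
# arm-level and incremental cost-effectiveness results.

#' Discount a value to present value
#'
#' `value / (1 + rate)^t`, continuous in `t`; streams are discounted at
#' cycle start, anchored to programme start (year 0 = first screening round).
#'
#' @param value EUR or QALY amount (vectorised).
#' @param t time in years (vectorised).
#' @param rate annual discount rate, >= 0.
#' @return discounted value.
#' @export
discount <- function(value, t, rate) {
  stopifnot(all(rate >= 0), all(t >= 0))
  value / (1 + rate)^t
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost incremental cost (EUR).
#' @param delta_effect incremental effect (QALYs or LYs); must be non-zero.
#' @return EUR per unit effect, rounded to whole EUR.
#' @export
icer <- function(delta_cost, delta_effect) {
  if (any(delta_effect == 0))
    stop("undefined ICER: zero incremental effect (report dominance instead)")
  round(delta_cost / delta_effect)
}

#' Net monetary benefit
#'
#' `wtp * delta_q - delta_c`.
#'
#' @param wtp willingness-to-pay threshold (EUR per QALY).
#' @param delta_q incremental QALYs.
#' @param delta_c incremental costs (EUR).
#' @return EUR.
#' @export
nmb <- function(wtp, delta_q, delta_c) wtp * delta_q - delta_c

# --- billing schedules -----------------------------------------------------

# Per-cycle first-line treatment amounts (excluding the one-time
# first-3-months entry cost): a cost density of rest_of_year1 over
# [0.25, 1) and year2 over [1, 2), integrated over each cycle.  At
# dt = 0.25 this reproduces the published schedule exactly (rest/3 in
# cycles 1-3, year2/4 in cycles 4-7).
first_line_cycle_costs <- function(cs_stage, n_cycles, dt) {
  dens <- function(t) {
    ifelse(t < 0.25, 0,
    ifelse(t < 1,    cs_stage$rest_of_year1 / 0.75,
    ifelse(t < 2,    cs_stage$year2, 0)))
  }
  t0 <- (seq_len(n_cycles) - 1) * dt
  # midpoint rule is exact for the piecewise-constant density when cycle
  # boundaries align with phase boundaries
  dens(t0 + dt / 2) * dt
}

# Cycle indices (1-based) at which an aftercare visit is billed: every six
# months through year two after diagnosis, annually thereafter.
followup_cycles <- function(n_cycles, dt) {
  horizon_t <- n_cycles * dt
  vt <- seq(0.5, 2, by = 0.5)
  if (horizon_t > 3) vt <- c(vt, seq(3, ceiling(horizon_t), by = 1))
  idx <- floor(vt / dt) + 1
  idx[vt < horizon_t & idx <= n_cycles]
}

#' Per-cycle treatment costs for one diagnosed stratum
#'
#' Cycle 0 bills the first-3-months cost per person entering; cycles 1-3 the
#' remainder of the first treatment year (split equally) and cycles 4-7 the
#' second treatment year, both per alive pre-progression person-cycle;
#' aftercare visits (chest CT plus specialist consult) are billed per alive
#' pre-progression person every six months through year two, annually
#' thereafter.  Second-line treatment is a one-time cost per progression
#' event; end-of-life care a one-time cost per lung cancer death.
#'
#' @param trace an `lcs_trace` for the stratum.
#' @param stage stage label `"I"`..`"IV"`.
#' @param cs the `costs` block of an `lcs_parameters` object.
#' @return numeric vector of undiscounted EUR per cycle.
#' @export
treatment_cost_stream <- function(trace, stage, cs) {
  n_cycles <- nrow(trace$occupancy) - 1
  if (n_cycles < 1) return(numeric(0))
  dt <- trace$cycle_length
  st <- cs$stage[[stage]]
  pre <- trace$occupancy[seq_len(n_cycles), "pre"]
  cost <- first_line_cycle_costs(st, n_cycles, dt) * pre
  # the first-3-months block is billed per person entering at diagnosis
  cost[1] <- cost[1] + st$first_3_months * trace$n
  fu <- followup_cycles(n_cycles, dt)
  cost[fu] <- cost[fu] + (cs$followup_ct + cs$followup_consult) * pre[fu]
  cost <- cost + st$second_line * trace$prog_events +
    cs$end_of_life * trace$lc_deaths
  cost
}

#' Per-cycle QALYs for one stratum
#'
#' Pre-progression occupancy times the stage's pre-progression utility plus
#' post-progression occupancy times the post-progression utility, per cycle.
#' Missed individuals (never diagnosed) instead accrue the age-specific
#' population utility while alive.
#'
#' @param trace an `lcs_trace`.
#' @param u the `utilities` block of an `lcs_parameters` object.
#' @param stage `"I"`..`"IV"`, or `"missed"`.
#' @return numeric vector of undiscounted QALYs per cycle.
#' @export
qaly_stream <- function(trace, u, stage) {
  n_cycles <- nrow(trace$occupancy) - 1
  if (n_cycles < 1) return(numeric(0))
  dt <- trace$cycle_length
  pre <- trace$occupancy[seq_len(n_cycles), "pre"]
  post <- trace$occupancy[seq_len(n_cycles), "post"]
  if (identical(stage, "missed")) {
    ages <- trace$entry_age + (seq_len(n_cycles) - 1) * dt
    (pre + post) * population_utility(u, ages) * dt
  } else {
    (pre * u$pre_progression[[stage]] + post * u$post_progression[[stage]]) * dt
  }
}

population_utility <- function(u, ages) {
  tab <- u$population_utility_by_age
  a <- pmin(pmax(floor(ages), min(tab$age)), max(tab$age))
  tab$utility[match(a, tab$age)]
}

#' Discounted programme costs from the diagnosis ledger
#'
#' Recruitment: one invitation letter per person aged 50-74 plus one GP
#' consult per participant, at programme start (year 0, undiscounted).
#' Screening: a CT scan per screen, discounted at the round year.
#' Diagnostic: work-up of true and false screen-positives at the
#' screen-detected tariff, clinical presenters at the clinical tariff, and a
#' repeat low-dose CT for indeterminate scans, discounted at the event year.
#'
#' @param ledger an `lcs_ledger`.
#' @param cs the `costs` block of an `lcs_parameters` object.
#' @param settings the `settings` block (discount rate for costs, horizon).
#' @return named vector `c(recruitment, screening, diagnostic)` in EUR, plus
#'   attribute `no_screening_diagnostic` (the no-screening arm's clinical
#'   work-up total).
#' @export
screening_program_costs <- function(ledger, cs, settings) {
  rc <- settings$discount_rate_costs
  recruitment <- ledger$recruitment$letters * cs$invitation_letter +
    ledger$recruitment$gp_consults * cs$gp_consult
  r <- ledger$rounds
  screening <- sum(discount(r$screens * cs$ct_scan, r$year, rc))
  d <- ledger$diagnoses
  within_h <- d$year < settings$horizon
  diag_of <- function(arm) {
    dd <- d[d$arm == arm & within_h, ]
    tariff <- ifelse(dd$mode == "screen", cs$diag_screen_detected,
              ifelse(dd$mode == "clinical", cs$diag_clinical, 0))
    sum(discount(dd$mass * tariff, dd$year, rc))
  }
  diagnostic <- diag_of("screening") +
    sum(discount(r$false_positives * cs$diag_screen_detected, r$year, rc)) +
    sum(discount(r$indeterminates * cs$followup_ct, r$year, rc))
  out <- c(recruitment = recruitment, screening = screening,
           diagnostic = diagnostic)
  attr(out, "no_screening_diagnostic") <- diag_of("no_screening")
  out
}
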