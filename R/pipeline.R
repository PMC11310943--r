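# End-to-end model run: decision tree -> Markov cohort engine -> discounted
# economic aggregation.  The engine is vectorised across diagnosis-year
# strata so that probabilistic sensitivity analysis (1000 model evaluations)
# stays cheap.

#' Run the full cost-effectiveness model
#'
#' Simulates both arms of the decision tree, propagates every diagnosed
#' stratum (arm x stage x detection mode x diagnosis year) through the
#' Markov engine, accrues discounted life years, QALYs and costs by category,
#' and returns arm-level plus incremental results.
#'
#' @param p an `lcs_parameters` object.
#' @param som an `lcs_screen_model` (defaults to the shipped calibrated one).
#' @param lt an `lcs_life_table`.
#' @return an `lcs_result` (see [aggregate_economics()]).
#' @export
run_model <- function(p, som = make_screening_outcomes(), lt = make_life_table()) {
  ledger <- simulate_arms(p, som, lt)
  streams <- compute_streams(p, ledger, lt)
  aggregate_economics(ledger, streams, p)
}

# Scale late-stage first-line costs and survival for the immunotherapy
# utilisation scenario.  The cost share of immunotherapy in late-stage
# first-line treatment is taken as 0.3 and the survival gain per unit
# uplift as 0.1; both apply to stages III and IV in both arms.
IMMUNO_COST_SHARE <- 0.3
IMMUNO_SURV_GAIN <- 0.1

apply_special_flags <- function(p) {
  u <- p$special_flags$immunotherapy_uplift %||% 0
  if (u > 0) {
    for (s in c("III", "IV")) {
      for (f in c("first_3_months", "rest_of_year1", "year2")) {
        p$costs$stage[[s]][[f]] <- p$costs$stage[[s]][[f]] * (1 + IMMUNO_COST_SHARE * u)
      }
    }
  }
  p
}

model_curves <- function(p) {
  cv <- default_curves(p$survival)
  u <- p$special_flags$immunotherapy_uplift %||% 0
  if (u > 0) {
    for (s in c("III", "IV")) {
      cv$os[[s]]$params[["rate"]] <- cv$os[[s]]$params[["rate"]] / (1 + IMMUNO_SURV_GAIN * u)
    }
  }
  cv
}

# Discounted per-unit-mass outcomes for every (stage, diagnosis year)
# stratum, shared across arms and detection modes.
compute_streams <- function(p, ledger, lt) {
  p <- apply_special_flags(p)
  s <- p$settings
  dt <- s$cycle_length
  accrual <- s$accrual_horizon %||% s$horizon
  horizon <- s$horizon
  entry_age0 <- ledger$entry_age
  rc <- s$discount_rate_costs
  rh <- s$discount_rate_health
  bg <- p$background_mortality_multiplier
  cv <- model_curves(p)
  # Death hazards for the pre- and post-progression states both come from
  # the stratum's own OS curve (progression switches utility and triggers
  # second-line costs, not the death hazard), so total survival reproduces
  # the fitted OS curve; set to "stage_iv" to make post-progression
  # patients of any stage die at the stage-IV rate instead.
  post_mode <- s$post_progression_mortality %||% "stage_os"
  half <- isTRUE(s$half_cycle_correction)

  d <- ledger$diagnoses
  d <- d[d$mass > 0, , drop = FALSE]
  strata <- unique(d[c("stage", "year")])
  strata <- strata[strata$year < horizon, , drop = FALSE]

  out <- list()
  for (stg in unique(strata$stage)) {
    years <- sort(strata$year[strata$stage == stg])
    if (length(years) == 0) next
    n_cycles <- as.integer(round((horizon - min(years)) / dt))
    is_missed <- identical(stg, "missed")
    eff_stage <- if (is_missed) p$survival$missed_behaves_as else stg
    os <- cv$os[[eff_stage]]
    dpfs <- if (is_missed) NULL else cv$dpfs[[stg]]
    post_os <- if (post_mode == "stage_iv") cv$os[["IV"]] else os
    blk <- run_stage_block(os, dpfs, post_os, lt,
                           entry_ages = entry_age0 + years,
                           n_cycles = n_cycles, dt = dt, bg_mult = bg)
    ns <- length(years)
    K <- matrix(rep(seq_len(n_cycles), each = ns), nrow = ns)   # cycle index
    t_rel <- (K - 1) * dt
    t_cal <- years + t_rel                                      # calendar time
    live_mask <- (t_rel < (horizon - years)) * (t_cal < accrual)
    dc <- (1 + rc)^(-t_cal) * live_mask
    dh <- (1 + rh)^(-t_cal) * live_mask
    pre <- blk$pre[, seq_len(n_cycles), drop = FALSE]
    post <- blk$post[, seq_len(n_cycles), drop = FALSE]
    if (half) {
      pre <- (pre + blk$pre[, seq_len(n_cycles) + 1, drop = FALSE]) / 2
      post <- (post + blk$post[, seq_len(n_cycles) + 1, drop = FALSE]) / 2
    }
    ev_prog <- blk$prog_events[, seq_len(n_cycles) + 1, drop = FALSE]
    ev_lc <- blk$lc_deaths[, seq_len(n_cycles) + 1, drop = FALSE]
    alive <- pre + post

    ly <- rowSums(alive * dt * dh)
    if (is_missed) {
      ages <- entry_age0 + t_cal
      pu <- matrix(population_utility(p$utilities, ages), nrow = ns)
      qaly <- rowSums(alive * pu * dt * dh)
      treat <- numeric(ns); eol <- numeric(ns)
    } else {
      qaly <- rowSums((pre * p$utilities$pre_progression[[stg]] +
                       post * p$utilities$post_progression[[stg]]) * dt * dh)
      st <- p$costs$stage[[stg]]
      flc <- first_line_cycle_costs(st, n_cycles, dt)
      cost_cycle <- sweep(pre, 2, flc, "*")
      cost_cycle[, 1] <- cost_cycle[, 1] + st$first_3_months
      fu <- followup_cycles(n_cycles, dt)
      cost_cycle[, fu] <- cost_cycle[, fu, drop = FALSE] +
        (p$costs$followup_ct + p$costs$followup_consult) * pre[, fu, drop = FALSE]
      cost_cycle <- cost_cycle + st$second_line * ev_prog
      treat <- rowSums(cost_cycle * dc)
      eol <- rowSums(p$costs$end_of_life * ev_lc * dc)
    }
    lc_deaths <- rowSums(ev_lc * live_mask)

    # Patients are booked from diagnosis (missed individuals from presumed
    # presentation) only; pre-diagnosis person-time is booked in neither
    # arm, mirroring the published accounting.  The residual lead-time
    # asymmetry is discussed in the methods vignette.
    out[[stg]] <- data.frame(
      stage = stg, year = years, ly = ly, qaly = qaly,
      ly_patient = ly, qaly_patient = qaly,
      treatment = treat, end_of_life = eol, lc_deaths = lc_deaths)
  }
  per_unit <- do.call(rbind, out)
  if (is.null(per_unit))
    per_unit <- data.frame(stage = character(), year = numeric(), ly = numeric(),
                           qaly = numeric(), ly_patient = numeric(),
                           qaly_patient = numeric(), treatment = numeric(),
                           end_of_life = numeric(), lc_deaths = numeric())

  # cancer-free block (identical across arms)
  n_cycles <- as.integer(round(horizon / dt))
  t0 <- (seq_len(n_cycles) - 1) * dt
  h <- life_table_hazard(lt, entry_age0 + t0) * bg
  alive <- cumprod(c(1, exp(-h * dt)))[seq_len(n_cycles)]
  if (half) alive <- (alive + c(alive[-1], alive[n_cycles] * exp(-h[n_cycles] * dt))) / 2
  keep <- t0 < accrual
  dh0 <- (1 + rh)^(-t0) * keep
  cf_ly <- sum(alive * dt * dh0)
  cf_qaly <- sum(alive * population_utility(p$utilities, entry_age0 + t0) * dt * dh0)

  list(per_unit = per_unit, cancer_free = c(ly = cf_ly, qaly = cf_qaly),
       params_effective = p)
}

#' Aggregate ledger and streams into an economic result
#'
#' Produces discounted per-arm life years, QALYs and costs split into
#' recruitment, screening, diagnostic, treatment by stage and end-of-life
#' categories, plus incremental outcomes (delta costs, delta QALYs, delta
#' LYs, ICER per QALY and per LY, and net monetary benefit at the configured
#' willingness-to-pay).
#'
#' @param ledger an `lcs_ledger` from [simulate_arms()].
#' @param streams per-unit outcome streams from the Markov engine (built
#'   internally by [run_model()]).
#' @param p the `lcs_parameters` object of the run.
#' @return an `lcs_result`.
#' @export
aggregate_economics <- function(ledger, streams, p) {
  pe <- streams$params_effective
  s <- pe$settings
  prog <- screening_program_costs(ledger, pe$costs, s)
  per_unit <- streams$per_unit
  d <- ledger$diagnoses
  d$key <- paste(d$stage, d$year)
  per_unit$key <- paste(per_unit$stage, per_unit$year)
  idx <- match(d$key, per_unit$key)

  arm_totals <- function(arm) {
    sel <- d$arm == arm
    m <- d$mass[sel]
    u <- per_unit[idx[sel], ]
    u[is.na(u$ly), c("ly", "qaly", "ly_patient", "qaly_patient",
                     "treatment", "end_of_life", "lc_deaths")] <- 0
    agg <- function(v) tapply(m * v, d$stage[sel], sum)
    stages_here <- sort(unique(d$stage[sel]))
    list(
      ly_by_stage = agg(u$ly), qaly_by_stage = agg(u$qaly),
      ly_patient_by_stage = agg(u$ly_patient),
      qaly_patient_by_stage = agg(u$qaly_patient),
      treatment_by_stage = agg(u$treatment),
      end_of_life = sum(m * u$end_of_life),
      lc_deaths_by_stage = agg(u$lc_deaths),
      diagnosed_by_stage = tapply(m, d$stage[sel], sum))
  }
  scr <- arm_totals("screening")
  nos <- arm_totals("no_screening")

  cf <- streams$cancer_free * ledger$cancer_free_mass
  flags <- pe$special_flags
  cess <- (flags$smoking_cessation_cost %||% 0) * ledger$participants
  fp_du <- flags$fp_disutility %||% 0
  r <- ledger$rounds
  accrual <- s$accrual_horizon %||% s$horizon
  rkeep <- r$year < accrual
  fp_loss <- sum(discount((r$false_positives + r$indeterminates)[rkeep] * fp_du,
                          r$year[rkeep], s$discount_rate_health))

  arm_result <- function(tot, screening_arm) {
    costs <- list(
      recruitment = if (screening_arm) unname(prog[["recruitment"]]) + cess else 0,
      screening = if (screening_arm) unname(prog[["screening"]]) else 0,
      diagnostic = if (screening_arm) unname(prog[["diagnostic"]])
                   else attr(prog, "no_screening_diagnostic"),
      treatment_by_stage = tot$treatment_by_stage,
      end_of_life = tot$end_of_life)
    total_cost <- costs$recruitment + costs$screening + costs$diagnostic +
      sum(tot$treatment_by_stage, na.rm = TRUE) + costs$end_of_life
    qaly <- sum(tot$qaly_by_stage, na.rm = TRUE) + cf[["qaly"]] -
      if (screening_arm) fp_loss else 0
    list(
      ly = sum(tot$ly_by_stage, na.rm = TRUE) + cf[["ly"]],
      qaly = qaly,
      ly_by_stage = tot$ly_by_stage, qaly_by_stage = tot$qaly_by_stage,
      ly_patient_by_stage = tot$ly_patient_by_stage,
      qaly_patient_by_stage = tot$qaly_patient_by_stage,
      ly_cancer_free = cf[["ly"]], qaly_cancer_free = cf[["qaly"]],
      diagnosed_by_stage = tot$diagnosed_by_stage,
      lc_deaths_by_stage = tot$lc_deaths_by_stage,
      costs = costs, total_cost = total_cost)
  }
  a_scr <- arm_result(scr, TRUE)
  a_nos <- arm_result(nos, FALSE)

  delta_c <- a_scr$total_cost - a_nos$total_cost
  delta_q <- a_scr$qaly - a_nos$qaly
  delta_l <- a_scr$ly - a_nos$ly
  res <- list(
    screening = a_scr, no_screening = a_nos,
    incremental = list(delta_cost = delta_c, delta_qaly = delta_q,
                       delta_ly = delta_l),
    icer_qaly = if (delta_q != 0) delta_c / delta_q else NA_real_,
    icer_ly = if (delta_l != 0) delta_c / delta_l else NA_real_,
    nmb = nmb(s$wtp, delta_q, delta_c),
    wtp = s$wtp, ledger = ledger)
  structure(res, class = "lcs_result")
}

#' @export
print.lcs_result <- function(x, ...) {
  cat("Lung cancer screening cost-effectiveness result\n")
  cat(sprintf("  incremental costs : EUR %s\n",
              format(round(x$incremental$delta_cost), big.mark = ",")))
  cat(sprintf("  incremental QALYs : %s\n",
              format(round(x$incremental$delta_qaly), big.mark = ",")))
  cat(sprintf("  incremental LYs   : %s\n",
              format(round(x$incremental$delta_ly), big.mark = ",")))
  cat(sprintf("  ICER per QALY     : EUR %s\n",
              format(round(x$icer_qaly), big.mark = ",")))
  cat(sprintf("  ICER per LY       : EUR %s\n",
              format(round(x$icer_ly), big.mark = ",")))
  cat(sprintf("  NMB at EUR %s/QALY: EUR %s\n",
              format(x$wtp, big.mark = ","),
              format(round(x$nmb), big.mark = ",")))
  invisible(x)
}
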