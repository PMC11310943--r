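# The decision tree: eligibility, participation, annual screening rounds,
# detection pathway assignment, stage allocation, missed individuals, and the
# diagnosis ledger feeding the Markov engine.
#
# Person mass is continuous throughout; integers appear only at the
# reporting boundary.

#' Eligible population from demography
#'
#' `aged = round(total * frac_aged_50_74)`;
#' `eligible = round(aged * smoking_rate)`.
#'
#' @param d the `demography` block of an `lcs_parameters` object.
#' @return named numeric vector `c(aged_50_74, eligible)`.
#' @export
eligible_population <- function(d) {
  aged <- round(d$total_population * d$frac_aged_50_74)
  eligible <- round(aged * d$smoking_rate)
  c(aged_50_74 = aged, eligible = eligible)
}

#' Number of screening participants
#'
#' `floor(eligible * uptake)` (floor matches the published participant
#' count).
#'
#' @param eligible eligible individual count.
#' @param uptake uptake fraction in `[0, 1]`.
#' @return participant count.
#' @export
participants <- function(eligible, uptake) {
  stopifnot(uptake >= 0, uptake <= 1)
  floor(eligible * uptake)
}

#' Allocate a diagnosed mass across clinical stages
#'
#' @param n person-mass to allocate.
#' @param dist 4-vector of stage fractions summing to 1.
#' @param rounded if `TRUE`, round to the nearest integer (the reporting
#'   convention); the unrounded mass is what flows through the model.
#' @return named vector of per-stage counts.
#' @export
allocate_clinical_stages <- function(n, dist, rounded = FALSE) {
  stopifnot(abs(sum(dist) - 1) < 1e-9)
  out <- setNames(n * as.numeric(dist), STAGES)
  if (rounded) round(out) else out
}

#' Simulate both arms of the decision tree
#'
#' Both arms share one incident-cancer process: cancers arise in the
#' participant cohort at an annual rate of
#' `annual_incidence_eligible * risk_concentration`, with the at-risk mass
#' depleted by prior diagnosis and background mortality over the lifetime
#' horizon.  In the screening arm, a pre-clinical cancer is screen-detected
#' at each attended annual round with `detection_prob_per_round` (staged by
#' the screen-detected stage distribution) until its pre-clinical sojourn
#' (`clinical_delay_years`) elapses, after which it presents clinically;
#' because participants remain under programme surveillance, every
#' screening-arm cancer is eventually diagnosed.  In the no-screening arm
#' `clinical_detection_fraction` of cancers present clinically after the
#' sojourn (staged by the clinical stage distribution) and the remainder are
#' never diagnosed ("missed individuals", a no-screening-arm concept by
#' definition).  Screens, false positives, indeterminate scans, invitation
#' letters and GP consults are logged per round.
#'
#' @param p an `lcs_parameters` object.
#' @param som an `lcs_screen_model`.
#' @param lt life table used to deplete the at-risk mass.
#' @return an `lcs_ledger`: `diagnoses` (arm, stage, mode, year, mass),
#'   `rounds` (screens, false positives, indeterminates per round),
#'   recruitment tallies and cohort masses.
#' @export
simulate_arms <- function(p, som, lt = make_life_table()) {
  s <- p$settings
  if (s$horizon < s$n_rounds)
    stop("configuration error: settings.horizon shorter than settings.n_rounds")
  ep <- eligible_population(p$demography)
  P <- ep[["eligible"]] * s$uptake
  a <- s$adherence
  d <- som$detection_prob_per_round
  delay <- som$clinical_delay_years
  cdf <- som$clinical_detection_fraction
  clin_dist <- p$epidemiology$clinical_stage_distribution
  scr_dist <- som$screen_stage_distribution
  rate <- p$epidemiology$annual_incidence_eligible * p$epidemiology$risk_concentration
  horizon <- s$horizon
  entry_age <- p$demography$mean_entry_age
  last_round <- s$n_rounds - 1

  years <- 0:(horizon - 1)
  atrisk <- numeric(horizon + 1)
  atrisk[1] <- P
  new_cancer <- numeric(horizon)
  for (y in years) {
    new_cancer[y + 1] <- atrisk[y + 1] * rate
    q_bg <- 1 - exp(-life_table_hazard(lt, entry_age + y) *
                      p$background_mortality_multiplier)
    atrisk[y + 2] <- (atrisk[y + 1] - new_cancer[y + 1]) * (1 - q_bg)
  }

  rows <- list()
  add <- function(arm, mode, year, mass, dist) {
    if (mass <= 0) return(invisible())
    alloc <- allocate_clinical_stages(mass, dist)
    rows[[length(rows) + 1]] <<- data.frame(
      arm = arm, stage = STAGES, mode = mode, year = year,
      mass = as.numeric(alloc))
  }
  preclin <- numeric(s$n_rounds)  # undetected pre-clinical mass present at each round

  for (y in years) {
    m <- new_cancer[y + 1]
    if (m <= 0) next
    # --- screening arm ---
    resid <- m
    opp <- intersect(seq(y, y + delay - 1), 0:last_round)
    for (r in opp) {
      preclin[r + 1] <- preclin[r + 1] + resid
      det <- resid * a * d
      add("screening", "screen", r, det, scr_dist)
      resid <- resid - det
    }
    add("screening", "clinical", y + delay, resid, clin_dist)
    # --- no-screening arm ---
    add("no_screening", "clinical", y + delay, m * cdf, clin_dist)
    if (m * (1 - cdf) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        arm = "no_screening", stage = "missed", mode = "missed",
        year = y + delay, mass = m * (1 - cdf))
    }
  }
  diagnoses <- do.call(rbind, rows)
  if (is.null(diagnoses) || nrow(diagnoses) == 0) {
    diagnoses <- data.frame(arm = character(), stage = character(),
                            mode = character(), year = numeric(),
                            mass = numeric())
  } else {
    diagnoses <- stats::aggregate(mass ~ arm + stage + mode + year,
                                  data = diagnoses, FUN = sum)
  }

  round_ids <- 0:last_round
  # screens: adherent share of the cancer-free at-risk mass plus attending
  # undetected pre-clinical carriers
  screens <- a * (atrisk[round_ids + 1] + preclin)
  rounds <- data.frame(
    round = round_ids, year = round_ids, screens = screens,
    false_positives = screens * som$false_positive_rate,
    indeterminates = screens * som$indeterminate_rate)

  structure(list(
    diagnoses = diagnoses, rounds = rounds,
    recruitment = list(letters = if (P > 0) ep[["aged_50_74"]] else 0,
                       gp_consults = P),
    eligible = ep[["eligible"]], aged_50_74 = ep[["aged_50_74"]],
    participants = P, pool_by_year = new_cancer,
    pool_total = sum(new_cancer),
    cancer_free_mass = ep[["eligible"]] - sum(new_cancer),
    entry_age = entry_age),
    class = "lcs_ledger")
}

#' Incremental QALYs gained per screening-arm lung cancer patient
#'
#' @param delta_qaly incremental QALYs of screening versus no screening.
#' @param screen_arm_diagnoses total screening-arm diagnosed count.
#' @return the ratio, reported to 2 decimals.
#' @export
qalys_per_patient <- function(delta_qaly, screen_arm_diagnoses) {
  stopifnot(screen_arm_diagnoses > 0)
  round(delta_qaly / screen_arm_diagnoses, 2)
}

#' Export a diagnosis ledger as tidy CSV
#' @param ledger an `lcs_ledger`.
#' @param path output CSV path.
#' @export
write_ledger <- function(ledger, path) {
  df <- ledger$diagnoses
  names(df)[names(df) == "mode"] <- "detection_mode"
  write.csv(df[order(df$arm, df$year, df$stage), ], path, row.names = FALSE)
  invisible(path)
}

#' Arm-by-stage diagnosed totals from a ledger
#' @param ledger an `lcs_ledger`.
#' @param rounded round person counts to integers (the reporting convention).
#' @return data frame with columns `arm`, `stage`, `mass`.
#' @export
ledger_stage_table <- function(ledger, rounded = TRUE) {
  d <- ledger$diagnoses
  out <- stats::aggregate(mass ~ arm + stage, data = d, FUN = sum)
  if (rounded) out$mass <- round(out$mass)
  out
}
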