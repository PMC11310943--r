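# Synthetic stand-ins for inputs that are only available in restricted
# appendices: screening performance, the national life table, age-specific
# population utilities, and noisy survival anchors for fit-recovery tests.

# Frozen output of calibrate_screening_outcomes(table1_fixture()); see that
# function for the derivation.  Regenerate with:
#   calibrate_screening_outcomes(table1_fixture())
.default_screen_model <- list(
  screen_stage_distribution = c(I = 0.62982681, II = 0.06723742,
                                III = 0.17341019, IV = 0.12952558),
  detection_prob_per_round = 0.90,
  false_positive_rate = 0.013,
  indeterminate_rate = 0.020,
  clinical_detection_fraction = 0.666,
  clinical_delay_years = 2
)

#' Synthetic screening-outcome model
#'
#' The per-round performance of the screening programme: the stage
#' distribution of screen-detected cancers, the probability that a prevalent
#' pre-clinical cancer is detected at an attended screen, per-screen
#' false-positive and indeterminate rates, the fraction of cancers that ever
#' present clinically in the absence of screening, and the pre-clinical
#' sojourn time before symptomatic presentation.
#'
#' Called with no arguments this returns the shipped frozen model, calibrated
#' (see [calibrate_screening_outcomes()]) so that a full base-case run
#' reproduces the published screening-arm stage shares of roughly
#' 51/7/20/22 percent and a screening/no-screening diagnosis ratio of about
#' 1.5 (clinical detection fraction 0.666).
#'
#' @param seed optional integer; when given, rates are jittered
#'   reproducibly (+/- 5 percent) around the frozen model, for stress tests.
#' @param calibration optional 4-vector of target screening-arm stage shares;
#'   when given, the screen-detected stage distribution is set to these
#'   shares directly (the degenerate short-cut used in unit tests; full
#'   end-to-end calibration lives in [calibrate_screening_outcomes()]).
#' @return an object of class `lcs_screen_model`.
#' @export
make_screening_outcomes <- function(seed = NULL, calibration = NULL) {
  m <- .default_screen_model
  if (!is.null(calibration)) {
    stopifnot(length(calibration) == 4)
    if (abs(sum(calibration) - 1) > 1e-9)
      stop("calibration shares must sum to 1")
    m$screen_stage_distribution <- setNames(as.numeric(calibration), STAGES)
  }
  if (!is.null(seed)) {
    set.seed(seed)
    jitter <- function(x) x * runif(length(x), 0.95, 1.05)
    m$detection_prob_per_round <- min(1, jitter(m$detection_prob_per_round))
    m$false_positive_rate <- min(1, jitter(m$false_positive_rate))
    m$indeterminate_rate <- min(1, jitter(m$indeterminate_rate))
    s <- jitter(m$screen_stage_distribution)
    m$screen_stage_distribution <- s / sum(s)
  }
  structure(m, class = "lcs_screen_model")
}

#' Calibrate the screen-detected stage distribution
#'
#' Solves for the stage distribution of screen-detected cancers such that the
#' mixed screening-arm stage shares (screen-detected plus interval/clinical
#' presenters) hit the target shares.  Because the fraction of the
#' screening-arm cancer mass that is screen-detected does not depend on the
#' stage distribution itself, the mixing equation
#' `target = f_screen * s + (1 - f_screen) * clinical` is linear in `s` and
#' one pass is exact; the solution is clipped at zero and renormalised.
#'
#' @param p an `lcs_parameters` object (the base case to calibrate against).
#' @param targets screening-arm stage shares to reproduce.
#' @param clinical_detection_fraction share of cancers ever presenting
#'   clinically without screening.
#' @return a calibrated `lcs_screen_model`.
#' @export
calibrate_screening_outcomes <- function(p = table1_fixture(),
                                         targets = c(0.51, 0.07, 0.20, 0.22),
                                         clinical_detection_fraction = 0.666) {
  stopifnot(abs(sum(targets) - 1) < 1e-6)
  m <- make_screening_outcomes()
  m$clinical_detection_fraction <- clinical_detection_fraction
  led <- simulate_arms(p, m)
  d <- led$diagnoses
  scr <- d[d$arm == "screening", ]
  f_screen <- sum(scr$mass[scr$mode == "screen"]) / sum(scr$mass)
  clin <- p$epidemiology$clinical_stage_distribution
  s <- (targets - (1 - f_screen) * clin) / f_screen
  s <- pmax(s, 0)
  s <- s / sum(s)
  m$screen_stage_distribution <- setNames(as.numeric(s), STAGES)
  m
}

#' Gompertz-Makeham life table
#'
#' Annual death probabilities `q(age) = 1 - exp(-(c + a * exp(b * age)))`,
#' capped at 1 and forced to 1 at `max_age`.  The defaults approximate a
#' western-European national life table.
#'
#' @param a Makeham-Gompertz level (default 5e-5).
#' @param b Gompertz slope per year of age (default 0.095).
#' @param c age-independent baseline hazard (default 5e-4).
#' @param max_age closing age of the table (default 108).
#' @return an object of class `lcs_life_table`: data frame with columns
#'   `age` and `q`.
#' @export
make_life_table <- function(a = 5e-5, b = 0.095, c = 5e-4, max_age = 108) {
  if (a < 0 || c < 0 || max_age < 1)
    stop("invalid life table parameters: a, c must be >= 0 and max_age >= 1")
  age <- 0:max_age
  q <- 1 - exp(-(c + a * exp(b * age)))
  q <- pmin(q, 1)
  q[length(q)] <- 1
  if (any(q < 0 | q > 1 | is.na(q)))
    stop("invalid life table parameters: q outside [0, 1]")
  structure(data.frame(age = age, q = q), class = c("lcs_life_table", "data.frame"))
}

#' Read or write a life table as a two-column CSV (age, q)
#' @param path CSV file path.
#' @return an `lcs_life_table`.
#' @export
read_life_table <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("age", "q") %in% names(df)))
  if (any(df$q < 0 | df$q > 1)) stop("life table q values must be in [0, 1]")
  if (df$q[nrow(df)] != 1) stop("life table must close with q = 1 at max age")
  structure(df[c("age", "q")], class = c("lcs_life_table", "data.frame"))
}

#' @rdname read_life_table
#' @param lt an `lcs_life_table`.
#' @export
write_life_table <- function(lt, path) {
  write.csv(as.data.frame(lt)[c("age", "q")], path, row.names = FALSE)
  invisible(path)
}

#' Synthetic age-specific population utilities
#'
#' Emulates EQ-5D-5L population norms with a linear decline:
#' `utility(age) = max(0, u50 - slope * (age - 50))`.
#'
#' @param u50 utility at age 50 (default 0.89).
#' @param slope per-year decrement (default 0.003).
#' @param max_age last tabulated age.
#' @return data frame with columns `age` and `utility`.
#' @export
make_population_utilities <- function(u50 = 0.89, slope = 0.003, max_age = 108) {
  stopifnot(u50 > 0, u50 <= 1, slope >= 0)
  age <- 18:max_age
  utility <- pmax(0, u50 - slope * pmax(age - 50, 0))
  data.frame(age = age, utility = utility)
}

#' Binomially perturbed survival anchors
#'
#' Produces noisy Kaplan-Meier-like survival observations around a true
#' parametric curve, for fit-recovery tests: at each time the observed
#' survival is `Binomial(n_at_risk, S(t)) / n_at_risk`.
#'
#' @param curve an `lcs_curve` (see [fit_curve()]).
#' @param times increasing vector of times (years).
#' @param n_at_risk number at risk (sampling denominator).
#' @param seed RNG seed (draws are deterministic per seed).
#' @return data frame with columns `time` and `survival`.
#' @export
make_km_anchors <- function(curve, times, n_at_risk, seed = 1) {
  stopifnot(all(diff(times) > 0), n_at_risk > 0)
  set.seed(seed)
  s_true <- vapply(times, function(t) survival_at(curve, t), numeric(1))
  obs <- rbinom(length(times), n_at_risk, s_true) / n_at_risk
  data.frame(time = times, survival = obs)
}
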