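# Stage-stratified cohort state-transition engine at 3-month cycles.
# States: pre-progression, post-progression, dead of lung cancer, dead of
# other causes.  A vectorised multi-stratum runner drives the pipeline; the
# per-stratum run_cohort() and a microsimulation oracle back the tests.

TRACE_STATES <- c("pre", "post", "dead_lc", "dead_other")

new_trace <- function(stage, n, entry_age, entry_year, cycle_length,
                      occupancy, prog_events, lc_deaths, other_deaths) {
  tr <- structure(list(stage = stage, n = n, entry_age = entry_age,
                       entry_year = entry_year, cycle_length = cycle_length,
                       occupancy = occupancy, prog_events = prog_events,
                       lc_deaths = lc_deaths, other_deaths = other_deaths),
                  class = "lcs_trace")
  assert_trace(tr)
  tr
}

assert_trace <- function(tr) {
  occ <- tr$occupancy
  if (any(occ < -1e-9)) stop("trace invariant violated: negative occupancy")
  tot <- rowSums(occ)
  if (any(abs(tot - tr$n) > 1e-6 * max(tr$n, 1)))
    stop("trace invariant violated: person-mass not conserved")
  for (s in c("dead_lc", "dead_other"))
    if (any(diff(occ[, s]) < -1e-9))
      stop("trace invariant violated: absorbing state decreased")
  invisible(tr)
}

#' Run one cohort stratum through the Markov model
#'
#' Propagates a person-mass (all starting in the pre-progression state at
#' diagnosis) through three-month cycles until the horizon or extinction of
#' the living mass.  Transition probabilities come from [cycle_matrix()]:
#' disease mortality from the stratum's OS curve, progression from the D/PFS
#' excess hazard, background mortality from the life table at the stratum's
#' current age, and post-progression mortality from `post_os`.
#'
#' @param stage stage label (metadata).
#' @param n person-mass entering at diagnosis.
#' @param entry_age age at diagnosis (years).
#' @param entry_year calendar year of diagnosis relative to programme start.
#' @param curves list with `os`, `dpfs` (may be `NULL`) and optional
#'   `post_os` (`lcs_curve` objects).
#' @param lt an `lcs_life_table`.
#' @param settings the `settings` block of an `lcs_parameters` object
#'   (`cycle_length`, `horizon` are used).
#' @param bg_mult background mortality multiplier.
#' @param n_years years to simulate (default: `settings$horizon`).
#' @return an `lcs_trace`: occupancy per cycle start (rows `0..n_cycles`),
#'   plus per-cycle transition-event counts for event-triggered costs.
#' @export
run_cohort <- function(stage, n, entry_age, entry_year, curves, lt, settings,
                       bg_mult = 1, n_years = settings$horizon) {
  dt <- settings$cycle_length
  n_cycles <- max(0L, as.integer(round(n_years / dt)))
  occ <- matrix(0, nrow = n_cycles + 1, ncol = 4,
                dimnames = list(NULL, TRACE_STATES))
  occ[1, "pre"] <- n
  prog <- lc <- oth <- numeric(n_cycles)
  post_os <- curves$post_os %||% curves$os
  state <- c(pre = n, post = 0, dead_lc = 0, dead_other = 0)
  for (k in seq_len(n_cycles)) {
    if (state[["pre"]] + state[["post"]] < 1e-9) {
      occ[(k + 1):(n_cycles + 1), ] <- matrix(state, nrow = n_cycles + 1 - k,
                                              ncol = 4, byrow = TRUE)
      break
    }
    t <- (k - 1) * dt
    m <- cycle_matrix(curves$os, curves$dpfs, lt, entry_age + t, t, dt,
                      bg_mult = bg_mult, post_os = post_os)
    sh <- attr(m, "lc_share")
    die_pre <- state[["pre"]] * m["pre", "dead"]
    die_post <- state[["post"]] * m["post", "dead"]
    prog[k] <- state[["pre"]] * m["pre", "post"]
    lc[k] <- die_pre * sh[["pre"]] + die_post * sh[["post"]]
    oth[k] <- die_pre + die_post - lc[k]
    state <- c(
      pre = state[["pre"]] * m["pre", "pre"],
      post = state[["post"]] * m["post", "post"] + prog[k],
      dead_lc = state[["dead_lc"]] + lc[k],
      dead_other = state[["dead_other"]] + oth[k])
    occ[k + 1, ] <- state
  }
  new_trace(stage, n, entry_age, entry_year, dt, occ, prog, lc, oth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorised engine: traces for all diagnosis years of one stage at once.
# Returns per-unit-mass occupancy/event matrices of dim (n_strata, n_cycles).
run_stage_block <- function(os, dpfs, post_os, lt, entry_ages, n_cycles, dt,
                            bg_mult = 1) {
  ns <- length(entry_ages)
  t_grid <- (seq_len(n_cycles) - 1) * dt
  h_os <- interval_hazard_vec(os, t_grid, dt)
  h_dpfs <- if (is.null(dpfs)) h_os else interval_hazard_vec(dpfs, t_grid, dt)
  h_prog_t <- pmax(h_dpfs - h_os, 0)
  if (any(h_dpfs - h_os < -1e-9))
    stop(sprintf("numerical-consistency error: D/PFS hazard below OS hazard (stage %s)",
                 os$stage))
  h_post <- interval_hazard_vec(post_os, t_grid, dt)
  pre <- post <- dead_lc <- dead_oth <- prog_ev <- lc_ev <- oth_ev <-
    matrix(0, nrow = ns, ncol = n_cycles + 1)
  pre[, 1] <- 1
  s_pre <- rep(1, ns); s_post <- rep(0, ns)
  s_dlc <- rep(0, ns); s_doth <- rep(0, ns)
  for (k in seq_len(n_cycles)) {
    age <- entry_ages + (k - 1) * dt
    h_bg <- life_table_hazard(lt, age) * bg_mult
    h_die_pre <- h_os[k] + h_bg
    p_die_pre <- 1 - exp(-h_die_pre * dt)
    p_prog <- exp(-h_die_pre * dt) * (1 - exp(-h_prog_t[k] * dt))
    h_die_post <- h_post[k] + h_bg
    p_die_post <- 1 - exp(-h_die_post * dt)
    sh_pre <- ifelse(h_die_pre > 0, h_os[k] / h_die_pre, 0)
    sh_post <- ifelse(h_die_post > 0, h_post[k] / h_die_post, 0)
    die_pre <- s_pre * p_die_pre
    die_post <- s_post * p_die_post
    new_prog <- s_pre * p_prog
    new_lc <- die_pre * sh_pre + die_post * sh_post
    new_oth <- die_pre + die_post - new_lc
    s_pre <- s_pre * (1 - p_die_pre - p_prog)
    s_post <- s_post * (1 - p_die_post) + new_prog
    s_dlc <- s_dlc + new_lc
    s_doth <- s_doth + new_oth
    pre[, k + 1] <- s_pre; post[, k + 1] <- s_post
    dead_lc[, k + 1] <- s_dlc; dead_oth[, k + 1] <- s_doth
    prog_ev[, k + 1] <- new_prog; lc_ev[, k + 1] <- new_lc
    oth_ev[, k + 1] <- new_oth
  }
  list(pre = pre, post = post, dead_lc = dead_lc, dead_other = dead_oth,
       prog_events = prog_ev, lc_deaths = lc_ev, other_deaths = oth_ev)
}

interval_hazard_vec <- function(c, t_grid, dt) {
  H0 <- cum_hazard_at(c, t_grid)
  H1 <- cum_hazard_at(c, t_grid + dt)
  (H1 - H0) / dt
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates `n_individuals` one by one with the same per-cycle transition
#' matrices as [run_cohort()]; used to validate the deterministic cohort
#' propagation against Monte-Carlo counts.
#'
#' @inheritParams run_cohort
#' @param n_individuals number of simulated persons.
#' @param seed RNG seed (traces are deterministic per seed).
#' @return an `lcs_trace` of simulated counts.
#' @export
microsim_oracle <- function(stage, n_individuals, entry_age, entry_year, curves,
                            lt, settings, bg_mult = 1, seed = 1,
                            n_years = settings$horizon) {
  stopifnot(n_individuals >= 1)
  set.seed(seed)
  dt <- settings$cycle_length
  n_cycles <- as.integer(round(n_years / dt))
  post_os <- curves$post_os %||% curves$os
  state <- rep(1L, n_individuals)  # 1 pre, 2 post, 3 dead_lc, 4 dead_other
  occ <- matrix(0, nrow = n_cycles + 1, ncol = 4,
                dimnames = list(NULL, TRACE_STATES))
  occ[1, ] <- tabulate(state, 4)
  prog <- lc <- oth <- numeric(n_cycles)
  for (k in seq_len(n_cycles)) {
    t <- (k - 1) * dt
    alive <- state <= 2L
    if (!any(alive)) { occ[(k + 1):(n_cycles + 1), ] <-
      matrix(tabulate(state, 4), nrow = n_cycles + 1 - k, ncol = 4, byrow = TRUE)
      break }
    m <- cycle_matrix(curves$os, curves$dpfs, lt, entry_age + t, t, dt,
                      bg_mult = bg_mult, post_os = post_os)
    sh <- attr(m, "lc_share")
    u <- runif(n_individuals)
    is_pre <- state == 1L
    is_post <- state == 2L
    p_die_pre <- m["pre", "dead"]; p_prog <- m["pre", "post"]
    p_die_post <- m["post", "dead"]
    # pre: [0, p_die) dead, [p_die, p_die+p_prog) progress
    died_pre <- is_pre & u < p_die_pre
    progressed <- is_pre & !died_pre & u < p_die_pre + p_prog
    died_post <- is_post & u < p_die_post
    u2 <- runif(n_individuals)
    lc_pre <- died_pre & u2 < sh[["pre"]]
    lc_post <- died_post & u2 < sh[["post"]]
    state[progressed] <- 2L
    state[died_pre | died_post] <- 4L
    state[lc_pre | lc_post] <- 3L
    prog[k] <- sum(progressed)
    lc[k] <- sum(lc_pre | lc_post)
    oth[k] <- sum(died_pre | died_post) - lc[k]
    occ[k + 1, ] <- tabulate(state, 4)
  }
  new_trace(stage, n_individuals, entry_age, entry_year, dt, occ, prog, lc, oth)
}

#' Undiscounted life years per cycle from a trace
#'
#' Alive occupancy at each cycle start times the cycle length; no half-cycle
#' correction by default (second-order at three-month cycles).
#'
#' @param t an `lcs_trace`.
#' @param cycle_length cycle length in years (defaults to the trace's own).
#' @param half_cycle if `TRUE`, average adjacent cycle-start occupancies.
#' @return numeric vector of life years accrued in each cycle.
#' @export
trace_person_time <- function(t, cycle_length = t$cycle_length,
                              half_cycle = FALSE) {
  alive <- t$occupancy[, "pre"] + t$occupancy[, "post"]
  nc <- nrow(t$occupancy) - 1
  if (nc < 1) return(numeric(0))
  a <- alive[seq_len(nc)]
  if (half_cycle) a <- (a + alive[seq_len(nc) + 1]) / 2
  a * cycle_length
}
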