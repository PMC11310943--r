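settings_for <- function(horizon = 42, dt = 0.25) {
  s <- base_params()$settings
  s$horizon <- horizon
  s$cycle_length <- dt
  s
}

stage_curves <- function(stage) {
  cv <- default_curves(base_params()$survival)
  list(os = cv$os[[stage]], dpfs = cv$dpfs[[stage]])
}

test_that("degenerate cohorts behave trivially", {
  cvs <- stage_curves("IV")
  tr0 <- run_cohort("IV", 0, 58, 0, cvs, make_life_table(), settings_for(5))
  expect_true(all(tr0$occupancy == 0))
  static <- run_cohort("I", 100, 58, 0, list(os = exp_curve(0), dpfs = exp_curve(0)),
                       zero_lt(), settings_for(5))
  expect_true(all(static$occupancy[, "pre"] == 100))
  expect_true(all(static$prog_events == 0))
})

test_that("the chain reproduces the OS anchor with background mortality off", {
  cvs <- stage_curves("IV")
  tr <- run_cohort("IV", 1, 58, 0, cvs, zero_lt(), settings_for(5))
  alive5 <- sum(tr$occupancy[nrow(tr$occupancy), c("pre", "post")])
  expect_gt(alive5, 0.0591 * 0.93)
  expect_lt(alive5, 0.0591 * 1.07)
  expect_equal(unname(tr$occupancy[nrow(tr$occupancy), "dead_lc"]), 1 - 0.0591,
               tolerance = 1e-3)
})

test_that("trace invariants hold on base-case strata", {
  lt <- make_life_table()
  for (s in c("I", "III", "IV")) {
    tr <- run_cohort(s, 1000, 62, 4, stage_curves(s), lt, settings_for(30))
    occ <- tr$occupancy
    expect_true(all(abs(rowSums(occ) - 1000) < 1e-6))
    expect_true(all(diff(occ[, "dead_lc"]) > -1e-9))
    expect_true(all(diff(occ[, "dead_other"]) > -1e-9))
    expect_true(all(occ >= -1e-9))
  }
})

test_that("person-time follows the geometric series under constant survival", {
  # per-cycle survival s = 0.9 via an exponential with rate -log(0.9)/dt and
  # no progression; total LY = n * dt / (1 - s) by direct geometric summation
  # of start-of-cycle occupancy (the convention used throughout)
  dt <- 0.25
  rate <- -log(0.9) / dt
  tr <- run_cohort("I", 50, 58, 0, list(os = exp_curve(rate), dpfs = exp_curve(rate)),
                   zero_lt(), settings_for(80, dt))
  expect_equal(sum(trace_person_time(tr)), 50 * dt / (1 - 0.9), tolerance = 1e-3)
  # 100 persons alive exactly 4 cycles then all dead: 100 life years
  occ <- rbind(matrix(rep(c(100, 0, 0, 0), 4), nrow = 4, byrow = TRUE),
               c(0, 0, 100, 0))
  colnames(occ) <- c("pre", "post", "dead_lc", "dead_other")
  tr2 <- manual_trace(occ, lc = c(0, 0, 0, 100))
  expect_equal(sum(trace_person_time(tr2)), 100)
  expect_length(trace_person_time(manual_trace(occ * 0)), 4)
  expect_equal(sum(trace_person_time(manual_trace(occ * 0))), 0)
})

test_that("microsimulation oracle agrees with the cohort engine", {
  lt <- make_life_table()
  cases <- list(list(stage = "I", n = 1e5, bg = 1),
                list(stage = "IV", n = 2e4, bg = 1),
                list(stage = "III", n = 2e4, bg = 2))
  for (cs in cases) {
    cvs <- stage_curves(cs$stage)
    st <- settings_for(20)
    det <- run_cohort(cs$stage, cs$n, 58, 0, cvs, lt, st, bg_mult = cs$bg)
    sim <- microsim_oracle(cs$stage, cs$n, 58, 0, cvs, lt, st,
                           bg_mult = cs$bg, seed = 42)
    for (state in c("pre", "post", "dead_lc", "dead_other")) {
      p <- det$occupancy[, state] / cs$n
      se <- sqrt(pmax(p * (1 - p), 1e-12) * cs$n)
      diff <- abs(sim$occupancy[, state] - det$occupancy[, state])
      # 4 SEs: ~1000 simultaneous per-cycle comparisons across the cases
      expect_true(all(diff <= 4 * se + 4), info = paste(cs$stage, state))
    }
  }
})

test_that("microsimulation is deterministic per seed and respects zero hazards", {
  cvs <- list(os = exp_curve(0), dpfs = exp_curve(0))
  s1 <- microsim_oracle("I", 500, 58, 0, cvs, zero_lt(), settings_for(5), seed = 9)
  expect_true(all(s1$occupancy[, "pre"] == 500))
  cvs2 <- stage_curves("II")
  a <- microsim_oracle("II", 300, 58, 0, cvs2, make_life_table(), settings_for(10), seed = 4)
  b <- microsim_oracle("II", 300, 58, 0, cvs2, make_life_table(), settings_for(10), seed = 4)
  expect_identical(a$occupancy, b$occupancy)
})

test_that("halving the cycle length changes total life years by < 2%", {
  # discretisation stability is judged with the second-order (half-cycle)
  # accumulator; the first-order rectangle rule carries an O(cycle) offset
  # of ~3% for the fast stage-IV hazard that halving only halves
  lt <- make_life_table()
  for (s in c("I", "IV")) {
    t1 <- run_cohort(s, 1, 58, 0, stage_curves(s), lt, settings_for(42, 0.25))
    t2 <- run_cohort(s, 1, 58, 0, stage_curves(s), lt, settings_for(42, 0.125))
    ly1 <- sum(trace_person_time(t1, half_cycle = TRUE))
    ly2 <- sum(trace_person_time(t2, half_cycle = TRUE))
    expect_lt(abs(ly1 - ly2) / ly1, 0.02)
  }
  # the rectangle rule itself is stable for slow hazards
  s1 <- sum(trace_person_time(run_cohort("I", 1, 58, 0, stage_curves("I"), lt,
                                         settings_for(42, 0.25))))
  s2 <- sum(trace_person_time(run_cohort("I", 1, 58, 0, stage_curves("I"), lt,
                                         settings_for(42, 0.125))))
  expect_lt(abs(s1 - s2) / s1, 0.02)
})

test_that("the vectorised engine matches run_cohort stratum by stratum", {
  lt <- make_life_table()
  cvs <- stage_curves("III")
  st <- settings_for(12)
  blk <- lcsmodel:::run_stage_block(cvs$os, cvs$dpfs, cvs$os, lt,
                                    entry_ages = c(58, 65), n_cycles = 48,
                                    dt = 0.25)
  for (i in 1:2) {
    tr <- run_cohort("III", 1, c(58, 65)[i], 0, cvs, lt, st)
    expect_equal(blk$pre[i, ], unname(tr$occupancy[, "pre"]), tolerance = 1e-12)
    expect_equal(blk$post[i, ], unname(tr$occupancy[, "post"]), tolerance = 1e-12)
    expect_equal(blk$lc_deaths[i, -1], unname(tr$lc_deaths), tolerance = 1e-12)
    expect_equal(blk$prog_events[i, -1], unname(tr$prog_events), tolerance = 1e-12)
  }
})
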