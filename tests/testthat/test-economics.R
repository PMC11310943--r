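test_that("discounting follows 1/(1+r)^t", {
  expect_equal(discount(100, 1, 0.05), 100 / 1.05)
  expect_equal(round(discount(100, 1, 0.05), 3), 95.238)
  expect_equal(discount(7, 13.7, 0), 7)
  expect_equal(discount(100, 0, 0.05), 100)
})

test_that("icer and nmb reproduce the published worked examples", {
  expect_equal(icer(1382091070, 56122), 24627)
  expect_equal(icer(1382091070, 84049), 16444)
  expect_equal(icer(0, 5), 0)
  expect_error(icer(10, 0), "undefined ICER")
  # scale invariance
  expect_equal(icer(3 * 1382091070, 3 * 56122), icer(1382091070, 56122))
  expect_equal(nmb(50000, 56122, 1382091070), 50000 * 56122 - 1382091070)
  # the published NMB (1,424,012,194) uses unrounded incrementals; the
  # rounded-inputs identity must agree within 1e-5 relative
  expect_lt(abs(nmb(50000, 56122, 1382091070) - 1424012194) / 1424012194, 1e-5)
  expect_equal(nmb(123, 0, 0), 0)
  expect_equal(nmb(0, 10, 77), -77)
})

test_that("treatment stream bills the published schedule", {
  cs <- base_params()$costs
  # one stage-I person, progression-free for exactly one year, then gone
  occ <- rbind(matrix(rep(c(1, 0, 0, 0), 4), nrow = 4, byrow = TRUE),
               c(0, 0, 0, 1))
  colnames(occ) <- c("pre", "post", "dead_lc", "dead_other")
  tr <- manual_trace(occ, oth = c(0, 0, 0, 1))
  stream <- treatment_cost_stream(tr, "I", cs)
  expect_equal(stream[1], 8564)
  expect_equal(sum(stream[2:4]), 1956 + 368)  # + one aftercare visit at 6 months
  expect_equal(sum(stream), 8564 + 1956 + (280 + 88))
  # person dying of lung cancer in cycle 0
  occ2 <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  colnames(occ2) <- colnames(occ)
  tr2 <- manual_trace(occ2, lc = 1)
  expect_equal(sum(treatment_cost_stream(tr2, "I", cs)), 8564 + 7466)
  # second-line on progression events
  occ3 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  colnames(occ3) <- colnames(occ)
  tr3 <- manual_trace(occ3, prog = 1, stage = "III")
  expect_equal(unname(treatment_cost_stream(tr3, "III", cs)[1]), 16606 + 24795)
  # zero-person trace
  expect_equal(sum(treatment_cost_stream(manual_trace(occ * 0), "I", cs)), 0)
})

test_that("qaly stream applies stage utilities and population utilities", {
  u <- base_params()$utilities
  occ_pre <- rbind(matrix(rep(c(1, 0, 0, 0), 4), nrow = 4, byrow = TRUE),
                   c(1, 0, 0, 0))
  colnames(occ_pre) <- c("pre", "post", "dead_lc", "dead_other")
  expect_equal(sum(qaly_stream(manual_trace(occ_pre), u, "I")), 0.78)
  occ_post <- occ_pre[, c(2, 1, 3, 4)]
  colnames(occ_post) <- colnames(occ_pre)
  for (s in c("I", "IV")) {
    expect_equal(sum(qaly_stream(manual_trace(occ_post, stage = s), u, s)), 0.69)
  }
  u1 <- u
  u1$population_utility_by_age$utility[] <- 1
  expect_equal(sum(qaly_stream(manual_trace(occ_pre), u1, "missed")), 1)
})

test_that("programme costs follow the ledger arithmetic", {
  cs <- base_params()$costs
  st <- base_params()$settings
  st$discount_rate_costs <- 0
  led <- structure(list(
    diagnoses = data.frame(arm = character(), stage = character(),
                           mode = character(), year = numeric(), mass = numeric()),
    rounds = data.frame(round = 0, year = 0, screens = 1000,
                        false_positives = 0, indeterminates = 0),
    recruitment = list(letters = 500, gp_consults = 0)), class = "lcs_ledger")
  pc <- screening_program_costs(led, cs, st)
  expect_equal(pc[["screening"]], 280 * 1000)
  expect_equal(pc[["recruitment"]], 500 * 3)  # letters only, no participants
  expect_equal(pc[["diagnostic"]], 0)
})

test_that("totals decrease monotonically in the discount rate, equal raw sums at 0", {
  at_rate <- function(r) {
    p <- ps_set(ps_set(base_params(), "settings.discount_rate_costs", r),
                "settings.discount_rate_health", r)
    run_model(p, base_som(), base_lt())
  }
  r0 <- at_rate(0); r3 <- at_rate(0.03); r5 <- base_result()
  for (f in c("total_cost", "qaly", "ly")) {
    expect_gt(r0$screening[[f]], r3$screening[[f]])
    expect_gt(r3$screening[[f]], r5$screening[[f]])
  }
  # at rate 0 the screening cost equals the undiscounted scan bill exactly
  led <- r0$ledger
  expect_equal(r0$screening$costs$screening, sum(led$rounds$screens) * 280,
               tolerance = 1e-9)
})

test_that("cost categories add up to the arm totals", {
  for (arm in list(base_result()$screening, base_result()$no_screening)) {
    total <- arm$costs$recruitment + arm$costs$screening + arm$costs$diagnostic +
      sum(arm$costs$treatment_by_stage, na.rm = TRUE) + arm$costs$end_of_life
    expect_equal(total, arm$total_cost, tolerance = 1)
  }
})

test_that("NMB is positive iff the ICER is below willingness-to-pay", {
  r <- base_result()
  expect_true(r$incremental$delta_qaly > 0)
  expect_equal(r$nmb > 0, r$icer_qaly < r$wtp)
})
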