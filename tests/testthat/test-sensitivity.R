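psa_of <- function(dc, dq) {
  structure(list(draws = data.frame(delta_cost = dc, delta_qaly = dq),
                 seed = 0, n_draws = length(dc)), class = "lcs_psa")
}

test_that("probabilistic ICER is the ratio of means", {
  expect_equal(probabilistic_icer(psa_of(c(100, 300), c(1, 1))), 200)
  expect_equal(round(probabilistic_icer(psa_of(rep(1382091070, 3), rep(56122, 3)))),
               24627)
  expect_equal(probabilistic_icer(psa_of(c(100, 300), c(1, 2)),
                                  method = "mean_of_ratios"), 125)
  expect_error(probabilistic_icer(psa_of(c(1, -1), c(1, -1))), "undefined")
})

test_that("CEAC counts draws with positive net benefit", {
  s <- psa_of(c(100, 300, 500), c(2, 2, 2))
  expect_equal(ceac(s, 150)$prob_cost_effective, 1 / 3)
  expect_equal(ceac(s, 0)$prob_cost_effective, 0)      # no negative-cost draws
  expect_equal(ceac(s, 1e9)$prob_cost_effective, 1)
  # monotone nondecreasing in lambda when all delta-Q > 0
  set.seed(2)
  s2 <- psa_of(rnorm(200, 1000, 400), runif(200, 0.1, 2))
  pr <- ceac(s2, seq(0, 20000, by = 500))$prob_cost_effective
  expect_true(all(diff(pr) >= 0))
})

test_that("moment matching reproduces the target mean and flags impossible cases", {
  set.seed(1)
  g <- lcsmodel:::draw_gamma(1000, 280, 56, "x")
  expect_lt(abs(mean(g) - 280), 3 * 56 / sqrt(1000))
  b <- lcsmodel:::draw_beta(1000, 0.78, 0.05, "x")
  expect_lt(abs(mean(b) - 0.78), 3 * 0.05 / sqrt(1000))
  expect_error(lcsmodel:::draw_beta(10, 0.5, 0.6, "utilities.x"), "utilities.x")
})

test_that("degenerate PSA reproduces the deterministic result bit for bit", {
  p <- base_params()
  for (nm in names(p$distributions)) p$distributions[[nm]]$se <- 0
  s <- sample_psa(p, 3, seed = 99, som = base_som(), lt = base_lt())
  det <- run_model(p, base_som(), base_lt())
  expect_identical(unique(s$draws$delta_cost), det$incremental$delta_cost)
  expect_identical(unique(s$draws$delta_qaly), det$incremental$delta_qaly)
})

test_that("PSA draws are reproducible per seed", {
  a <- sample_psa(base_params(), 3, seed = 7, som = base_som(), lt = base_lt())
  b <- sample_psa(base_params(), 3, seed = 7, som = base_som(), lt = base_lt())
  expect_identical(a$draws, b$draws)
  expect_identical(a$params, b$params)
})

test_that("tornado entries are symmetric and analytic for a pure cost lever", {
  tor <- base_tornado()
  r <- base_result()
  row <- tor[tor$parameter == "costs.ct_scan", ]
  # CT cost enters delta-C linearly through the screening bill, delta-Q fixed
  S <- r$screening$costs$screening
  dq <- r$incremental$delta_qaly
  expect_equal(row$icer_low, (r$incremental$delta_cost - 0.2 * S) / dq,
               tolerance = 1e-6)
  expect_equal(row$icer_high, (r$incremental$delta_cost + 0.2 * S) / dq,
               tolerance = 1e-6)
  expect_equal(row$icer_high - r$icer_qaly, r$icer_qaly - row$icer_low,
               tolerance = 1e-6)
  expect_true(all(diff(tor$span) <= 1e-9))  # sorted descending
  expect_error(one_way(base_params(), "no.such.path"), "no.such.path")
})

test_that("scenario runner matches the base case and published directions", {
  p <- base_params()
  tab <- run_scenarios(p, list(scenario("empty"),
                               scenario("ct82", list(`costs.ct_scan` = 82)),
                               scenario("du15", fp_disutility = 0.015),
                               scenario("du50", fp_disutility = 0.05),
                               scenario("disc0",
                                        list(`settings.discount_rate_costs` = 0,
                                             `settings.discount_rate_health` = 0))),
                       som = base_som(), lt = base_lt())
  r <- base_result()
  expect_equal(tab$icer[1], r$icer_qaly, tolerance = 1e-9)
  expect_lt(tab$icer[tab$name == "ct82"], r$icer_qaly)
  # disutility lowers delta-QALY and raises the ICER, monotonically
  expect_lt(tab$delta_qaly[tab$name == "du15"], tab$delta_qaly[1])
  expect_lt(tab$delta_qaly[tab$name == "du50"], tab$delta_qaly[tab$name == "du15"])
  expect_gt(tab$icer[tab$name == "du50"], tab$icer[tab$name == "du15"])
  # zero discounting: QALYs accrue later than costs, so the ICER falls
  expect_lt(tab$icer[tab$name == "disc0"], r$icer_qaly)
})

test_that("the built-in scenario battery runs and is internally consistent", {
  sc <- table3_scenarios()
  expect_gt(length(sc), 25)
  sub <- run_scenarios(base_params(),
                       sc[c("base_case", "uptake_0.154", "rounds_3",
                            "immunotherapy_uplift_0.5", "background_mortality_x2")],
                       som = base_som(), lt = base_lt())
  expect_true(all(is.finite(sub$icer)))
  expect_lt(sub$delta_cost[sub$name == "uptake_0.154"], sub$delta_cost[1])
  expect_lt(sub$delta_cost[sub$name == "rounds_3"], sub$delta_cost[1])
  # higher immunotherapy utilisation narrows the incremental treatment bill
  expect_lt(sub$delta_cost[sub$name == "immunotherapy_uplift_0.5"], sub$delta_cost[1])
})
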