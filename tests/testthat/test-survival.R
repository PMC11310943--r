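test_that("single-anchor exponential fits have the closed-form rate", {
  # lambda = -log(S)/t, computed independently
  cases <- list(list(5, 0.0591), list(5, 0.7863), list(1, 0.4013))
  for (cs in cases) {
    fit <- fit_curve(data.frame(time = cs[[1]], survival = cs[[2]]),
                     family = "exponential")
    expect_equal(fit$params[["rate"]], -log(cs[[2]]) / cs[[1]], tolerance = 1e-12)
  }
  # printed-precision anchors: -log(0.0591)/5 = 0.5657049, the published
  # 0.565718 reflects an unrounded survival input (2.3e-5 relative apart)
  expect_equal(fit_curve(data.frame(time = 5, survival = 0.0591),
                         "exponential")$params[["rate"]], 0.565718,
               tolerance = 1e-4)
  expect_equal(fit_curve(data.frame(time = 5, survival = 0.7863),
                         "exponential")$params[["rate"]], 0.0480838,
               tolerance = 1e-4)
  # auto with a single anchor must choose exponential
  expect_equal(fit_curve(data.frame(time = 5, survival = 0.5))$family,
               "exponential")
  expect_error(fit_curve(data.frame(time = 5, survival = 0.5), "weibull"),
               "single anchor")
  expect_error(fit_curve(data.frame(time = 5, survival = 0)), "in \\(0, 1\\)")
  expect_error(fit_curve(data.frame(time = 5, survival = 1)), "in \\(0, 1\\)")
})

test_that("anchors exactly on a Weibull are interpolated exactly", {
  t <- c(1, 2, 4)
  s <- exp(-(t / 4)^1.5)
  fit <- fit_curve(data.frame(time = t, survival = s), family = "weibull")
  expect_equal(fit$params[["shape"]], 1.5, tolerance = 1e-6)
  expect_equal(fit$params[["scale"]], 4, tolerance = 1e-6)
  auto <- fit_curve(data.frame(time = t, survival = s))
  expect_equal(survival_at(auto, 3), exp(-(3 / 4)^1.5), tolerance = 1e-6)
})

test_that("survival_at follows each family's closed form", {
  expect_equal(survival_at(exp_curve(0.565718), 0), 1)
  expect_equal(survival_at(exp_curve(0.565718), 5), 0.0591, tolerance = 1e-4)
  expect_equal(survival_at(exp_curve(0.565718), 1), exp(-0.565718))
  expect_error(survival_at(exp_curve(1), -1), ">= 0")
  ll <- lcsmodel:::new_curve("loglogistic", c(scale = 2, shape = 3))
  expect_equal(survival_at(ll, 2), 0.5)
  ln <- lcsmodel:::new_curve("lognormal", c(meanlog = log(2), sdlog = 1))
  expect_equal(survival_at(ln, 2), 0.5)
  gz <- lcsmodel:::new_curve("gompertz", c(rate = 0.1, shape = 0.2))
  expect_equal(survival_at(gz, 3), exp(-(0.1 / 0.2) * (exp(0.2 * 3) - 1)))
})

test_that("prob_to_cycle is the constant-hazard conversion and is additive", {
  expect_equal(prob_to_cycle(0, 0.25), 0)
  expect_equal(prob_to_cycle(1, 0.25), 1)
  p_annual <- 1 - exp(-0.565718)   # stage IV one-year death probability
  expect_equal(prob_to_cycle(p_annual, 0.25), 1 - exp(-0.565718 / 4),
               tolerance = 1e-12)
  expect_equal(round(prob_to_cycle(p_annual, 0.25), 5), 0.13188)
  # compounding four quarterly cycles reproduces the annual probability
  for (p in c(0.05, 0.4321, 0.9)) {
    pc <- prob_to_cycle(p, 0.25)
    expect_equal(1 - (1 - pc)^4, p, tolerance = 1e-12)
  }
})

test_that("life_table_hazard converts q to a rate with capped boundary", {
  lt <- make_life_table()
  expect_equal(life_table_hazard(zero_lt(), 60), 0)
  q58 <- lt$q[lt$age == 58]
  expect_equal(life_table_hazard(lt, 58), -log(1 - q58))
  expect_equal(life_table_hazard(lt, 58.9), -log(1 - q58))  # floor(age)
  expect_equal(life_table_hazard(lt, 108), 50)   # q = 1 capped
  expect_equal(life_table_hazard(lt, 500), 50)   # beyond table: closing hazard
})

test_that("cycle_matrix matches the two-state competing-risk closed form", {
  lam <- 0.565718
  mu <- -log(0.4013)
  m <- cycle_matrix(exp_curve(lam), exp_curve(mu, "DPFS"), zero_lt(),
                    age = 60, t = 0, cycle = 0.25)
  # oracle: survive death over the cycle, then progress via excess hazard
  expect_equal(m["pre", "post"], exp(-lam * 0.25) * (1 - exp(-(mu - lam) * 0.25)),
               tolerance = 1e-12)
  expect_equal(m["pre", "dead"], 1 - exp(-lam * 0.25), tolerance = 1e-12)
  expect_equal(rowSums(m), c(pre = 1, post = 1, dead = 1), tolerance = 1e-12)
  expect_equal(m["dead", c("pre", "post")], c(pre = 0, post = 0))  # absorbing
})

test_that("background mortality enters additively and scales with bg_mult", {
  s_one <- exp_curve(0)  # disease-free: S == 1
  lt <- make_life_table()
  h <- life_table_hazard(lt, 70)
  m1 <- cycle_matrix(s_one, s_one, lt, age = 70, t = 0, cycle = 0.25, bg_mult = 1)
  m2 <- cycle_matrix(s_one, s_one, lt, age = 70, t = 0, cycle = 0.25, bg_mult = 2)
  expect_equal(m1["pre", "dead"], 1 - exp(-h * 0.25), tolerance = 1e-12)
  expect_equal(m2["pre", "dead"], 1 - exp(-2 * h * 0.25), tolerance = 1e-12)
  expect_equal(attr(m1, "lc_share")[["pre"]], 0)  # no disease hazard
  m0 <- cycle_matrix(s_one, s_one, zero_lt(), age = 70, t = 0, cycle = 0.25)
  expect_equal(matrix(as.numeric(m0), 3), diag(3), tolerance = 1e-12)
})

test_that("OS dominates D/PFS on a dense grid for every default stage pair", {
  cv <- default_curves(base_params()$survival)
  grid <- seq(0.01, 42, by = 0.1)
  for (s in c("I", "II", "III", "IV")) {
    expect_true(all(survival_at(cv$os[[s]], grid) >=
                    survival_at(cv$dpfs[[s]], grid) - 1e-12))
  }
})
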