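# One-way (tornado) sensitivity analysis, probabilistic sensitivity
# analysis, the cost-effectiveness acceptability curve, and the scenario
# runner.

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the full model with each parameter at `(1 - delta)` and
#' `(1 + delta)` times its base value (probabilities capped at 1; members of
#' a Dirichlet group are perturbed individually with the remaining shares
#' renormalised proportionally) and reports the ICER at both ends, sorted by
#' span for tornado plotting.
#'
#' @param p an `lcs_parameters` object.
#' @param param_paths dotted paths to vary; the default is every non-fixed
#'   cost and utility parameter in `p$distributions`.  Demographic and
#'   epidemiological parameters scale both arms jointly (they resize the
#'   modelled population rather than change the intervention) and are
#'   explored through scenarios; pass their paths explicitly to include
#'   them in the tornado.
#' @param delta relative perturbation (default 0.2).
#' @param som,lt screening-outcome model and life table held fixed.
#' @return data frame (class `lcs_tornado`) with columns `parameter`,
#'   `icer_low`, `icer_high`, `span`, sorted by span descending.
#' @export
one_way <- function(p, param_paths = NULL, delta = 0.2,
                    som = make_screening_outcomes(), lt = make_life_table()) {
  stopifnot(delta > 0, delta < 1)
  if (is.null(param_paths)) {
    kinds <- vapply(p$distributions, `[[`, character(1), "kind")
    param_paths <- names(p$distributions)[kinds != "fixed"]
    param_paths <- grep("^(costs|utilities)\\.", param_paths, value = TRUE)
  }
  run_at <- function(path, mult) {
    base <- tryCatch(ps_get(p, path),
                     error = function(e) stop("one_way: ", conditionMessage(e),
                                              call. = FALSE))
    val <- base * mult
    ds <- p$distributions[[path]]
    if (!is.null(ds) && ds$kind %in% c("beta", "dirichlet_group")) val <- min(val, 1)
    p2 <- ps_set(p, path, val)
    if (!is.null(ds) && ds$kind == "dirichlet_group") {
      # renormalise the sibling shares proportionally
      parts <- split_path(path)
      vec_path <- paste(parts[-length(parts)], collapse = ".")
      vec <- ps_get(p2, vec_path)
      k <- parts[length(parts)]
      others <- setdiff(names(vec), k)
      vec[others] <- vec[others] * (1 - vec[[k]]) / sum(vec[others])
      p2 <- ps_set(p2, vec_path, vec)
    }
    r <- run_model(p2, som, lt)
    r$icer_qaly
  }
  rows <- lapply(param_paths, function(path) {
    lo <- run_at(path, 1 - delta)
    hi <- run_at(path, 1 + delta)
    data.frame(parameter = path, icer_low = lo, icer_high = hi,
               span = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  class(out) <- c("lcs_tornado", "data.frame")
  out
}

# moment-matched draws
draw_beta <- function(n, m, se, path) {
  if (se == 0) return(rep(m, n))
  v <- se^2
  if (v >= m * (1 - m))
    stop("cannot parameterise beta from (mean, se) for ", path)
  a <- m * (m * (1 - m) / v - 1)
  rbeta(n, a, a * (1 - m) / m)
}
draw_gamma <- function(n, m, se, path) {
  if (se == 0) return(rep(m, n))
  shape <- (m / se)^2
  rgamma(n, shape = shape, rate = shape / m)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter vectors (beta and gamma moment-matched to
#' `(mean, se)`; Dirichlet groups drawn jointly with concentrations
#' `100 * share`; fixed parameters untouched), reruns the full model per
#' draw, and records incremental costs and QALYs.
#'
#' @param p an `lcs_parameters` object.
#' @param n number of draws (>= 1).
#' @param seed RNG seed; draws are reproducible per seed.
#' @param som,lt held fixed across draws.
#' @return an `lcs_psa`: list with `draws` (data frame `delta_cost`,
#'   `delta_qaly`), `params` (matrix of sampled values), `seed`, `n_draws`.
#' @export
sample_psa <- function(p, n, seed = 1,
                       som = make_screening_outcomes(), lt = make_life_table()) {
  stopifnot(n >= 1)
  set.seed(seed)
  kinds <- vapply(p$distributions, `[[`, character(1), "kind")
  paths <- names(p$distributions)[kinds != "fixed"]
  groups <- split(paths[kinds[paths] == "dirichlet_group"],
                  vapply(paths[kinds[paths] == "dirichlet_group"],
                         function(pp) p$distributions[[pp]]$group_id, character(1)))
  singles <- paths[kinds[paths] != "dirichlet_group"]

  samples <- matrix(NA_real_, nrow = n, ncol = length(paths),
                    dimnames = list(NULL, paths))
  for (path in singles) {
    ds <- p$distributions[[path]]
    samples[, path] <- switch(ds$kind,
      beta = draw_beta(n, ds$mean, ds$se, path),
      gamma = draw_gamma(n, ds$mean, ds$se, path),
      stop("distribution kind not samplable: ", ds$kind, " for ", path))
  }
  for (g in names(groups)) {
    members <- groups[[g]]
    conc <- vapply(members, function(pp) 100 * p$distributions[[pp]]$mean,
                   numeric(1))
    degenerate <- all(vapply(members, function(pp) {
      se <- p$distributions[[pp]]$se; !is.null(se) && se == 0
    }, logical(1)))
    if (degenerate) {
      g_draws <- matrix(rep(conc / sum(conc), each = n), nrow = n)
    } else {
      g_draws <- vapply(conc, function(a) rgamma(n, shape = a, rate = 1),
                        numeric(n))
      g_draws <- matrix(g_draws, nrow = n)
      g_draws <- g_draws / rowSums(g_draws)
    }
    samples[, members] <- g_draws
  }

  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    pi <- p
    for (path in colnames(samples))
      pi <- ps_set(pi, path, unname(samples[i, path]))
    r <- run_model(pi, som, lt)
    dc[i] <- r$incremental$delta_cost
    dq[i] <- r$incremental$delta_qaly
  }
  structure(list(draws = data.frame(delta_cost = dc, delta_qaly = dq),
                 params = samples, seed = seed, n_draws = n),
            class = "lcs_psa")
}

#' Probabilistic ICER from PSA draws
#'
#' Ratio of means `mean(delta_cost) / mean(delta_qaly)` by default (the
#' standard estimator in cost-effectiveness analysis); `"mean_of_ratios"` is
#' available as an option.
#'
#' @param s an `lcs_psa`.
#' @param method `"ratio_of_means"` or `"mean_of_ratios"`.
#' @return EUR per QALY.
#' @export
probabilistic_icer <- function(s, method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  if (method == "ratio_of_means") {
    mq <- mean(s$draws$delta_qaly)
    if (mq == 0) stop("undefined probabilistic ICER: mean incremental QALYs is 0")
    mean(s$draws$delta_cost) / mq
  } else {
    mean(s$draws$delta_cost / s$draws$delta_qaly)
  }
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit.
#'
#' @param s an `lcs_psa`.
#' @param wtp_grid nonempty vector of EUR/QALY thresholds.
#' @return data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(s, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1)
  prob <- vapply(wtp_grid, function(l)
    mean(l * s$draws$delta_qaly - s$draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' Run a list of scenarios
#'
#' One full pipeline run per scenario, identical to the base case except for
#' the scenario's overrides and special flags.
#'
#' @param p an `lcs_parameters` object.
#' @param scenarios list of `lcs_scenario` objects.
#' @param som,lt held fixed across scenarios.
#' @return data frame with one row per scenario: per-arm total costs and
#'   QALYs, incrementals, and ICER per QALY.
#' @export
run_scenarios <- function(p, scenarios,
                          som = make_screening_outcomes(), lt = make_life_table()) {
  rows <- lapply(scenarios, function(sc) {
    r <- tryCatch(run_model(apply_scenario(p, sc), som, lt),
                  error = function(e) stop("scenario '", sc$name, "': ",
                                           conditionMessage(e), call. = FALSE))
    data.frame(
      name = sc$name,
      cost_screening = r$screening$total_cost,
      qaly_screening = r$screening$qaly,
      cost_no_screening = r$no_screening$total_cost,
      qaly_no_screening = r$no_screening$qaly,
      delta_cost = r$incremental$delta_cost,
      delta_qaly = r$incremental$delta_qaly,
      icer = r$icer_qaly)
  })
  do.call(rbind, rows)
}

#' The built-in scenario battery
#'
#' Time horizons, discount rates, screening rounds, uptake, adherence,
#' smoking rates, CT scan prices, smoking-cessation programme costs,
#' immunotherapy utilisation uplifts, false-positive disutilities, a
#' stage-I utility increase, and doubled background mortality.
#'
#' @return named list of `lcs_scenario` objects.
#' @export
table3_scenarios <- function() {
  sc <- list(scenario("base_case"))
  for (h in c(10, 20, 30))
    sc <- c(sc, list(scenario(sprintf("time_horizon_%dy", h),
                              list(`settings.accrual_horizon` = h))))
  for (r in c(0, 0.03, 0.10))
    sc <- c(sc, list(scenario(sprintf("discount_%g", r),
                              list(`settings.discount_rate_costs` = r,
                                   `settings.discount_rate_health` = r))))
  for (k in c(3, 5, 10, 15))
    sc <- c(sc, list(scenario(sprintf("rounds_%d", k),
                              list(`settings.n_rounds` = k))))
  for (u in c(0.154, 0.168, 0.41))
    sc <- c(sc, list(scenario(sprintf("uptake_%g", u),
                              list(`settings.uptake` = u))))
  for (a in c(0.3, 0.5, 0.7))
    sc <- c(sc, list(scenario(sprintf("adherence_%g", a),
                              list(`settings.adherence` = a))))
  for (sm in c(0.15, 0.10, 0.05))
    sc <- c(sc, list(scenario(sprintf("smoking_rate_%g", sm),
                              list(`demography.smoking_rate` = sm))))
  for (ct in c(82, 103, 175))
    sc <- c(sc, list(scenario(sprintf("ct_cost_%d", ct),
                              list(`costs.ct_scan` = ct))))
  for (cc in c(300, 400))
    sc <- c(sc, list(scenario(sprintf("cessation_%d", cc),
                              smoking_cessation_cost = cc)))
  for (iu in c(0.1, 0.2, 0.5, 1.0))
    sc <- c(sc, list(scenario(sprintf("immunotherapy_uplift_%g", iu),
                              immunotherapy_uplift = iu)))
  for (du in c(0.015, 0.03, 0.05))
    sc <- c(sc, list(scenario(sprintf("fp_disutility_%g", du),
                              fp_disutility = du)))
  sc <- c(sc, list(scenario("stage1_utility_up20",
                            list(`utilities.pre_progression.I` = 0.936))))
  sc <- c(sc, list(scenario("background_mortality_x2",
                            list(background_mortality_multiplier = 2))))
  names(sc) <- vapply(sc, `[[`, character(1), "name")
  sc
}
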