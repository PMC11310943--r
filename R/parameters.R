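#' @importFrom stats optim rbinom rbeta rgamma runif setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

STAGES <- c("I", "II", "III", "IV")

#' Distribution specification for a model parameter
#'
#' Describes how a single parameter is varied in probabilistic sensitivity
#' analysis.  `beta` and `gamma` distributions are moment-matched to
#' `(mean, se)`; members of a `dirichlet_group` are drawn jointly and
#' renormalised; `fixed` parameters are never varied.
#'
#' @param kind one of `"fixed"`, `"beta"`, `"gamma"`, `"dirichlet_group"`.
#' @param mean central (base-case) value.
#' @param se standard error; defaults to `0.2 * mean` for beta/gamma
#'   (matching the +/-20 percent span used in one-way sensitivity analysis).
#' @param group_id identifier tying the members of a dirichlet group together.
#' @return an object of class `lcs_dist`.
#' @export
distribution_spec <- function(kind = c("fixed", "beta", "gamma", "dirichlet_group"),
                              mean, se = NULL, group_id = NULL) {
  kind <- match.arg(kind)
  if (is.null(se) && kind %in% c("beta", "gamma")) se <- 0.2 * mean
  structure(list(kind = kind, mean = mean, se = se, group_id = group_id),
            class = "lcs_dist")
}

#' Base-case parameter set for the Austrian screening programme
#'
#' Returns the full base-case configuration: demography (total population
#' 8,978,929; 32.22 percent aged 50-74; smoking rate 20.76 percent; mean entry
#' age 58), epidemiology (0.45 percent annual lung cancer incidence in the
#' eligible population, clinical stage distribution 16.3/7.8/27.7/48.2
#' percent), programme settings (17 annual rounds, 50 percent uptake, 100
#' percent adherence, 3-month Markov cycles, 42-year lifetime horizon,
#' 5 percent discount rates, EUR 50,000 willingness-to-pay), the unit-cost
#' schedule, health-state utilities, stage-wise survival anchors (5-year OS
#' and 1-year disease/progression-free survival), and the PSA distribution
#' tags for every non-fixed parameter.
#'
#' @return a validated `lcs_parameters` object.
#' @export
table1_fixture <- function() {
  stage_costs <- list(
    I   = list(first_3_months = 8564,  rest_of_year1 = 1956,  year2 = 736,
               second_line = 32085),
    II  = list(first_3_months = 8215,  rest_of_year1 = 2588,  year2 = 736,
               second_line = 32085),
    III = list(first_3_months = 16606, rest_of_year1 = 41502, year2 = 13598,
               second_line = 24795),
    IV  = list(first_3_months = 12529, rest_of_year1 = 25442, year2 = 2517,
               second_line = 24795)
  )
  p <- list(
    demography = list(
      total_population = 8978929,
      frac_aged_50_74  = 0.3222,
      smoking_rate     = 0.2076,
      mean_entry_age   = 58
    ),
    epidemiology = list(
      annual_incidence_eligible = 0.0045,
      # The screened cohort is the high-risk subset of the eligible
      # population; its incidence exceeds the eligible-population average.
      # 2.0 reproduces the scale of published diagnosis totals.
      risk_concentration = 2.0,
      clinical_stage_distribution = c(I = 0.163, II = 0.078,
                                      III = 0.277, IV = 0.482)
    ),
    settings = list(
      uptake = 0.50, adherence = 1.0, n_rounds = 17,
      cycle_length = 0.25, horizon = 42, accrual_horizon = 42, wtp = 50000,
      discount_rate_costs = 0.05, discount_rate_health = 0.05,
      half_cycle_correction = FALSE
    ),
    costs = list(
      stage = stage_costs,
      invitation_letter = 3, gp_consult = 22, ct_scan = 280,
      diag_screen_detected = 803, diag_clinical = 1093,
      followup_ct = 280, followup_consult = 88,
      end_of_life = 7466
    ),
    utilities = list(
      pre_progression  = c(I = 0.78, II = 0.78, III = 0.69, IV = 0.69),
      post_progression = c(I = 0.69, II = 0.69, III = 0.69, IV = 0.69),
      population_utility_by_age = make_population_utilities()
    ),
    survival = list(
      os_5yr   = c(I = 0.7863, II = 0.5490, III = 0.2924, IV = 0.0591),
      dpfs_1yr = c(I = 0.8780, II = 0.8780, III = 0.4181, IV = 0.4013),
      missed_behaves_as = "II"
    ),
    background_mortality_multiplier = 1,
    special_flags = list(fp_disutility = 0, smoking_cessation_cost = 0,
                         immunotherapy_uplift = 0),
    distributions = list()
  )
  d <- list()
  d[["settings.uptake"]] <- distribution_spec("beta", 0.50)
  d[["demography.total_population"]] <- distribution_spec("gamma", 8978929)
  d[["demography.frac_aged_50_74"]] <- distribution_spec("beta", 0.3222)
  d[["demography.smoking_rate"]] <- distribution_spec("beta", 0.2076)
  d[["epidemiology.annual_incidence_eligible"]] <- distribution_spec("gamma", 0.0045)
  for (s in STAGES) {
    d[[paste0("epidemiology.clinical_stage_distribution.", s)]] <-
      distribution_spec("dirichlet_group",
                        p$epidemiology$clinical_stage_distribution[[s]],
                        group_id = "clinical_stage")
    for (f in names(stage_costs[[s]])) {
      d[[paste0("costs.stage.", s, ".", f)]] <-
        distribution_spec("gamma", stage_costs[[s]][[f]])
    }
    d[[paste0("utilities.pre_progression.", s)]] <-
      distribution_spec("beta", p$utilities$pre_progression[[s]])
    d[[paste0("utilities.post_progression.", s)]] <-
      distribution_spec("beta", p$utilities$post_progression[[s]])
  }
  for (f in c("invitation_letter", "gp_consult", "ct_scan",
              "diag_screen_detected", "diag_clinical",
              "followup_ct", "followup_consult", "end_of_life")) {
    d[[paste0("costs.", f)]] <- distribution_spec("gamma", p$costs[[f]])
  }
  # Whole-life-table uncertainty is exposed through a single hazard
  # multiplier (gamma, mean 1).
  d[["background_mortality_multiplier"]] <- distribution_spec("gamma", 1)
  p$distributions <- d
  p <- structure(p, class = "lcs_parameters")
  v <- validate_parameters(p)
  if (length(v) > 0) stop("table1_fixture does not validate: ",
                          paste(v, collapse = "; "))
  p
}

# --- dotted-path addressing ------------------------------------------------

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Get a parameter by dotted path
#' @param p an `lcs_parameters` object (or any nested list).
#' @param path dotted identifier, e.g. `"costs.stage.IV.first_3_months"`.
#' @return the value at `path`.
#' @export
ps_get <- function(p, path) {
  parts <- split_path(path)
  cur <- p
  for (k in parts) {
    if (is.list(cur)) {
      if (!k %in% names(cur)) stop("unknown parameter path: ", path)
      cur <- cur[[k]]
    } else {
      if (!k %in% names(cur)) stop("unknown parameter path: ", path)
      cur <- cur[[k]]
    }
  }
  cur
}

#' Set a parameter by dotted path (non-destructive)
#' @inheritParams ps_get
#' @param value replacement value.
#' @return a modified copy of `p`.
#' @export
ps_set <- function(p, path, value) {
  parts <- split_path(path)
  set_rec <- function(node, parts, value) {
    k <- parts[[1]]
    if (!k %in% names(node)) stop("unknown parameter path: ", path)
    if (length(parts) == 1) {
      node[[k]] <- value
    } else {
      node[[k]] <- set_rec(node[[k]], parts[-1], value)
    }
    node
  }
  out <- set_rec(unclass(p), parts, value)
  class(out) <- class(p)
  out
}

# --- validation ------------------------------------------------------------

#' Validate a parameter set
#'
#' Checks every structural invariant and returns descriptions of all
#' violations (an empty character vector means the set is valid).  Violations
#' are returned, not raised, so callers can report them all at once.
#'
#' @param p an `lcs_parameters` object.
#' @return character vector of violation messages, each naming the parameter
#'   path and the violated rule.
#' @export
validate_parameters <- function(p) {
  v <- character()
  bad <- function(path, rule) sprintf("%s: %s", path, rule)
  frac_in <- function(path, x, lo = 0, hi = 1) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < lo) || any(x > hi))
      v[[length(v) + 1]] <<- bad(path, sprintf("must be in [%g, %g]", lo, hi))
  }
  frac_in("demography.frac_aged_50_74", p$demography$frac_aged_50_74)
  frac_in("demography.smoking_rate", p$demography$smoking_rate)
  if (p$demography$total_population <= 0)
    v[[length(v) + 1]] <- bad("demography.total_population", "must be > 0")
  if (p$demography$mean_entry_age < 50 || p$demography$mean_entry_age > 74)
    v[[length(v) + 1]] <- bad("demography.mean_entry_age", "must be in [50, 74]")

  inc <- p$epidemiology$annual_incidence_eligible
  if (inc <= 0 || inc >= 0.05)
    v[[length(v) + 1]] <- bad("epidemiology.annual_incidence_eligible",
                              "must be in (0, 0.05)")
  sd <- p$epidemiology$clinical_stage_distribution
  if (abs(sum(sd) - 1) > 1e-9)
    v[[length(v) + 1]] <- bad("epidemiology.clinical_stage_distribution",
                              "stage fractions must sum to 1")
  if (any(sd < 0)) v[[length(v) + 1]] <- bad("epidemiology.clinical_stage_distribution",
                                             "stage fractions must be >= 0")

  s <- p$settings
  frac_in("settings.uptake", s$uptake)
  frac_in("settings.adherence", s$adherence)
  if (s$n_rounds < 1) v[[length(v) + 1]] <- bad("settings.n_rounds", "must be >= 1")
  if (s$cycle_length <= 0) v[[length(v) + 1]] <- bad("settings.cycle_length", "must be > 0")
  if (s$horizon < s$n_rounds)
    v[[length(v) + 1]] <- bad("settings.horizon", "must be >= n_rounds")
  if (!is.null(s$accrual_horizon) &&
      (s$accrual_horizon <= 0 || s$accrual_horizon > s$horizon))
    v[[length(v) + 1]] <- bad("settings.accrual_horizon", "must be in (0, horizon]")
  frac_in("settings.discount_rate_costs", s$discount_rate_costs, 0, 0.2)
  frac_in("settings.discount_rate_health", s$discount_rate_health, 0, 0.2)

  flat_costs <- unlist(p$costs)
  if (any(flat_costs < 0))
    v[[length(v) + 1]] <- bad("costs", "all unit costs must be >= 0")

  u <- p$utilities
  frac_in("utilities.pre_progression", u$pre_progression)
  frac_in("utilities.post_progression", u$post_progression)
  if (any(u$post_progression > u$pre_progression + 1e-12))
    v[[length(v) + 1]] <- bad("utilities", "post-progression utility must not exceed pre-progression")
  frac_in("utilities.population_utility_by_age.utility",
          u$population_utility_by_age$utility)

  sv <- p$survival
  for (nm in c("os_5yr", "dpfs_1yr")) {
    x <- sv[[nm]]
    if (any(x <= 0) || any(x >= 1))
      v[[length(v) + 1]] <- bad(paste0("survival.", nm), "fractions must be in (0, 1)")
  }
  if (!sv$missed_behaves_as %in% STAGES)
    v[[length(v) + 1]] <- bad("survival.missed_behaves_as", "must be a stage I-IV")

  if (p$background_mortality_multiplier <= 0)
    v[[length(v) + 1]] <- bad("background_mortality_multiplier", "must be > 0")

  # distribution invariants
  groups <- list()
  for (path in names(p$distributions)) {
    ds <- p$distributions[[path]]
    if (ds$kind == "beta" && (ds$mean < 0 || ds$mean > 1))
      v[[length(v) + 1]] <- bad(path, "beta mean must be in [0, 1]")
    if (ds$kind == "gamma" && ds$mean <= 0)
      v[[length(v) + 1]] <- bad(path, "gamma mean must be > 0")
    if (ds$kind == "dirichlet_group")
      groups[[ds$group_id]] <- c(groups[[ds$group_id]], ds$mean)
  }
  for (g in names(groups)) {
    if (abs(sum(groups[[g]]) - 1) > 1e-9)
      v[[length(v) + 1]] <- bad(paste0("distributions[dirichlet:", g, "]"),
                                "group means must sum to 1")
  }
  v
}

# --- config I/O ------------------------------------------------------------

#' Load a parameter configuration
#'
#' Reads a YAML mapping mirroring the parameter tree (see
#' `inst/extdata/table1_austria_2022.yaml` for the full schema).  Any key left
#' out takes its base-case default from [table1_fixture()].  The result is
#' validated; all violations are reported together.
#'
#' @param source path to a YAML file, or a YAML string.
#' @return a validated `lcs_parameters` object.
#' @export
load_parameters <- function(source) {
  raw <- tryCatch(
    if (length(source) == 1 && file.exists(source)) yaml::read_yaml(source)
    else yaml::yaml.load(source),
    error = function(e) stop("configuration parse failure: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!is.list(raw)) stop("configuration parse failure: top level must be a mapping")
  p <- table1_fixture()
  known <- c("demography", "epidemiology", "settings", "costs", "utilities",
             "survival", "background_mortality_multiplier", "special_flags",
             "distributions")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "))
  merged <- unclass(p)
  for (k in setdiff(names(raw), "distributions")) {
    if (k %in% c("background_mortality_multiplier")) {
      merged[[k]] <- raw[[k]]
    } else {
      merged[[k]] <- merge_section(merged[[k]], raw[[k]], k)
    }
  }
  if (!is.null(raw$distributions)) {
    for (path in names(raw$distributions)) {
      ds <- raw$distributions[[path]]
      merged$distributions[[path]] <-
        distribution_spec(ds$kind, ds$mean, ds$se, ds$group_id)
    }
  }
  out <- structure(merged, class = "lcs_parameters")
  # utility table may arrive as a plain list of two arrays
  put <- out$utilities$population_utility_by_age
  if (!is.data.frame(put)) {
    out$utilities$population_utility_by_age <-
      data.frame(age = unlist(put$age), utility = unlist(put$utility))
  }
  # named numeric vectors may arrive as lists
  for (f in c("pre_progression", "post_progression"))
    out$utilities[[f]] <- unlist(out$utilities[[f]])
  for (f in c("os_5yr", "dpfs_1yr"))
    out$survival[[f]] <- unlist(out$survival[[f]])
  out$epidemiology$clinical_stage_distribution <-
    unlist(out$epidemiology$clinical_stage_distribution)
  viol <- validate_parameters(out)
  if (length(viol) > 0)
    stop("configuration validation error:\n  ", paste(viol, collapse = "\n  "))
  out
}

merge_section <- function(base, new, keypath) {
  if (is.null(new)) return(base)
  if (!is.list(new)) return(new)
  for (k in names(new)) {
    if (!k %in% names(base))
      stop("configuration error: unknown key: ", keypath, ".", k)
    base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
      merge_section(base[[k]], new[[k]], paste0(keypath, ".", k))
    else if (is.numeric(base[[k]]) && length(base[[k]]) > 1 && !is.null(names(base[[k]])))
      unlist(modifyList(as.list(base[[k]]), as.list(new[[k]])))
    else new[[k]]
  }
  base
}

#' Serialise a parameter set to YAML
#' @param p an `lcs_parameters` object.
#' @param path optional file path; if `NULL` the YAML text is returned.
#' @return `path` (invisibly) or YAML text.
#' @export
save_parameters <- function(p, path = NULL) {
  x <- unclass(p)
  x$utilities$population_utility_by_age <-
    list(age = x$utilities$population_utility_by_age$age,
         utility = x$utilities$population_utility_by_age$utility)
  x$distributions <- lapply(x$distributions, unclass)
  txt <- yaml::as.yaml(x, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

# --- scenarios -------------------------------------------------------------

#' Define a scenario
#'
#' A scenario is a named set of parameter overrides plus optional special
#' flags that downstream modules interpret (a one-off QALY decrement per
#' false-positive or indeterminate screen, a per-participant smoking
#' cessation programme cost, and an immunotherapy utilisation uplift that
#' scales late-stage first-line costs in both arms and improves late-stage
#' survival).
#'
#' @param name scenario label.
#' @param overrides named list mapping dotted parameter paths to values.
#' @param fp_disutility one-off utility decrement (applied for one year) per
#'   false-positive or indeterminate screen.
#' @param smoking_cessation_cost EUR per participant at programme entry.
#' @param immunotherapy_uplift fractional increase in immunotherapy
#'   utilisation for stage III-IV patients.
#' @return an object of class `lcs_scenario`.
#' @export
scenario <- function(name, overrides = list(), fp_disutility = NULL,
                     smoking_cessation_cost = NULL, immunotherapy_uplift = NULL) {
  structure(list(name = name, overrides = overrides,
                 special_flags = list(
                   fp_disutility = fp_disutility,
                   smoking_cessation_cost = smoking_cessation_cost,
                   immunotherapy_uplift = immunotherapy_uplift)),
            class = "lcs_scenario")
}

#' Apply a scenario to a parameter set
#'
#' Returns a new parameter set with the overrides applied; the input is not
#' modified.  Unknown override paths raise an error naming the path.
#'
#' @param p an `lcs_parameters` object.
#' @param s an `lcs_scenario`.
#' @return a modified `lcs_parameters` object.
#' @export
apply_scenario <- function(p, s) {
  stopifnot(inherits(s, "lcs_scenario"))
  out <- p
  for (path in names(s$overrides)) {
    out <- tryCatch(ps_set(out, path, s$overrides[[path]]),
                    error = function(e) stop("scenario '", s$name, "': ",
                                             conditionMessage(e), call. = FALSE))
  }
  for (f in names(s$special_flags)) {
    if (!is.null(s$special_flags[[f]])) out$special_flags[[f]] <- s$special_flags[[f]]
  }
  out
}
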