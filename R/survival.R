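# Parametric survival curves from summary anchors, lifetime extrapolation,
# and conversion to per-cycle transition probabilities blended additively
# with background mortality.

CURVE_FAMILIES <- c("exponential", "weibull", "lognormal", "loglogistic", "gompertz")

new_curve <- function(family, params, endpoint = "OS", stage = NA_character_) {
  structure(list(family = family, params = params,
                 endpoint = endpoint, stage = stage),
            class = "lcs_curve")
}

#' Evaluate a fitted survival curve
#'
#' @param c an `lcs_curve`.
#' @param t time in years (vectorised), `t >= 0`.
#' @return survival probability `S(t)`.
#' @export
survival_at <- function(c, t) {
  if (any(t < 0)) stop("t must be >= 0")
  p <- c$params
  switch(c$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = exp(-(t / p[["scale"]])^p[["shape"]]),
    lognormal   = 1 - stats::pnorm((log(pmax(t, .Machine$double.xmin)) - p[["meanlog"]]) / p[["sdlog"]]) * (t > 0),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    gompertz    = exp(-(p[["rate"]] / p[["shape"]]) * (exp(p[["shape"]] * t) - 1)),
    stop("unknown curve family: ", c$family)
  )
}

cum_hazard_at <- function(c, t) {
  s <- survival_at(c, t)
  -log(pmax(s, 1e-300))
}

# interval hazard rate (per year) over [t, t + dt]
interval_hazard <- function(c, t, dt) {
  (cum_hazard_at(c, t + dt) - cum_hazard_at(c, t)) / dt
}

#' Fit a parametric survival curve to summary anchors
#'
#' With a single anchor only the exponential is identifiable and the rate has
#' the closed form `lambda = -log(S) / t`.  With two or more anchors the fit
#' is least squares on the log-cumulative-hazard scale,
#' `log H(t) = log(-log S(t))`, where the exponential and Weibull are linear
#' (and therefore interpolate exactly when the anchor count equals the
#' parameter count) and the remaining families are fitted numerically.
#' `family = "auto"` picks the family with minimal AIC among families with at
#' most `length(anchors) - 1` free parameters.
#'
#' @param anchors data frame with columns `time` (> 0) and `survival`
#'   (in (0, 1)), or a list of `(time, survival)` pairs.
#' @param family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, or `"auto"`.
#' @param endpoint `"OS"` or `"DPFS"` (metadata only).
#' @param stage stage label (metadata only).
#' @return an `lcs_curve`.
#' @export
fit_curve <- function(anchors, family = "auto", endpoint = "OS", stage = NA_character_) {
  if (is.list(anchors) && !is.data.frame(anchors))
    anchors <- do.call(rbind, lapply(anchors, function(a)
      data.frame(time = a[[1]], survival = a[[2]])))
  stopifnot(nrow(anchors) >= 1)
  if (any(anchors$time <= 0)) stop("anchor times must be > 0")
  if (any(anchors$survival <= 0 | anchors$survival >= 1))
    stop("anchor survival values must be in (0, 1)")
  t <- anchors$time
  logH <- log(-log(anchors$survival))
  n <- nrow(anchors)

  fit_one <- function(fam) {
    k <- if (fam == "exponential") 1 else 2
    if (k > max(n, 1)) return(NULL)
    if (fam == "exponential") {
      rate <- exp(mean(logH - log(t)))
      pred <- log(rate) + log(t)
      params <- c(rate = rate)
    } else if (n < 2) {
      return(NULL)
    } else if (fam == "weibull") {
      co <- stats::lm.fit(cbind(1, log(t)), logH)$coefficients
      shape <- co[[2]]
      if (shape <= 0) return(NULL)
      params <- c(shape = shape, scale = exp(-co[[1]] / shape))
      pred <- co[[1]] + shape * log(t)
    } else {
      start <- switch(fam,
        lognormal   = c(mean(log(t)), 1),
        loglogistic = c(log(stats::median(t)), 1),  # log(scale), log(shape)
        gompertz    = c(log(exp(mean(logH - log(t)))), 0.1))
      obj <- function(par) {
        cv <- switch(fam,
          lognormal   = new_curve(fam, c(meanlog = par[1], sdlog = exp(par[2]))),
          loglogistic = new_curve(fam, c(scale = exp(par[1]), shape = exp(par[2]))),
          gompertz    = new_curve(fam, c(rate = exp(par[1]), shape = abs(par[2]) + 1e-8)))
        sum((log(pmax(cum_hazard_at(cv, t), 1e-300)) - logH)^2)
      }
      op <- tryCatch(stats::optim(start, obj, method = "Nelder-Mead",
                                  control = list(maxit = 2000)),
                     error = function(e) NULL)
      if (is.null(op)) return(NULL)
      par <- op$par
      params <- switch(fam,
        lognormal   = c(meanlog = par[1], sdlog = exp(par[2])),
        loglogistic = c(scale = exp(par[1]), shape = exp(par[2])),
        gompertz    = c(rate = exp(par[1]), shape = abs(par[2]) + 1e-8))
      pred <- log(pmax(cum_hazard_at(new_curve(fam, params), t), 1e-300))
    }
    rss <- sum((pred - logH)^2)
    aic <- n * log(max(rss, 1e-300) / n) + 2 * k
    list(curve = new_curve(fam, params, endpoint, stage), aic = aic)
  }

  if (family == "auto") {
    fams <- if (n == 1) "exponential" else CURVE_FAMILIES
    fits <- Filter(Negate(is.null), lapply(fams, fit_one))
    if (length(fits) == 0) stop("no family could be fitted")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
    return(best$curve)
  }
  family <- match.arg(family, CURVE_FAMILIES)
  if (n == 1 && family != "exponential")
    stop("with a single anchor the family must be exponential")
  f <- fit_one(family)
  if (is.null(f)) stop("could not fit family ", family)
  f$curve
}

#' Build the default stage-wise OS and D/PFS curves from survival anchors
#'
#' Each stage's overall survival is an exponential through its 5-year OS
#' anchor and each stage's disease/progression-free survival an exponential
#' through its 1-year D/PFS anchor (the only identifiable family with one
#' anchor per endpoint).
#'
#' @param sv the `survival` section of an `lcs_parameters` object.
#' @return list with elements `os` and `dpfs`, each a named list of
#'   `lcs_curve` objects by stage.
#' @export
default_curves <- function(sv) {
  os <- lapply(STAGES, function(s)
    fit_curve(data.frame(time = 5, survival = sv$os_5yr[[s]]),
              family = "exponential", endpoint = "OS", stage = s))
  dpfs <- lapply(STAGES, function(s)
    fit_curve(data.frame(time = 1, survival = sv$dpfs_1yr[[s]]),
              family = "exponential", endpoint = "DPFS", stage = s))
  list(os = setNames(os, STAGES), dpfs = setNames(dpfs, STAGES))
}

#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p_annual)^cycle` with the cycle
#' length in years.
#'
#' @param p_annual probability per year, in `[0, 1]`.
#' @param cycle cycle length in years, > 0.
#' @return per-cycle probability.
#' @export
prob_to_cycle <- function(p_annual, cycle) {
  stopifnot(all(p_annual >= 0 & p_annual <= 1), cycle > 0)
  1 - (1 - p_annual)^cycle
}

# hazard cap used where q = 1 would give an infinite rate
.HAZARD_CAP <- 50

#' Annual background mortality hazard from a life table
#'
#' `-log(1 - q(floor(age)))`, capped at 50 per year where `q = 1`; ages
#' beyond the table return the closing hazard.
#'
#' @param lt an `lcs_life_table`.
#' @param age age in years (vectorised).
#' @return hazard rate per year.
#' @export
life_table_hazard <- function(lt, age) {
  a <- pmin(pmax(floor(age), min(lt$age)), max(lt$age))
  q <- lt$q[match(a, lt$age)]
  h <- -log(1 - q)
  h[!is.finite(h)] <- .HAZARD_CAP
  pmin(h, .HAZARD_CAP)
}

#' One-cycle transition matrix for a diagnosed stratum
#'
#' States are (pre-progression, post-progression, dead).  Over the cycle
#' `[t, t + cycle]` since diagnosis, death from either living state combines
#' the disease hazard from the stratum's OS curve with the `bg_mult`-scaled
#' background hazard additively; the cause-of-death split is proportional to
#' the two hazard components.  The pre-to-post transition uses the excess
#' hazard of the D/PFS curve over the OS curve (the alive-with-progression
#' mass `S_OS - S_DPFS`), clipped at zero.  Post-progression patients use
#' `post_os` (by default the stage-IV OS curve) as their disease hazard.
#'
#' @param os OS curve of the stratum.
#' @param dpfs D/PFS curve of the stratum, or `NULL` for strata that never
#'   progress (e.g. missed individuals).
#' @param lt life table for background mortality.
#' @param age current age in years.
#' @param t time since diagnosis in years.
#' @param cycle cycle length in years.
#' @param bg_mult background-mortality hazard multiplier.
#' @param post_os OS curve governing post-progression mortality (defaults to
#'   `os`).
#' @return a 3x3 transition matrix with attribute `lc_share`, the fraction of
#'   each living state's death probability attributed to lung cancer.
#' @export
cycle_matrix <- function(os, dpfs, lt, age, t, cycle, bg_mult = 1, post_os = os) {
  stopifnot(t >= 0, cycle > 0)
  h_os <- interval_hazard(os, t, cycle)
  h_bg <- life_table_hazard(lt, age) * bg_mult
  h_dpfs <- if (is.null(dpfs)) h_os else interval_hazard(dpfs, t, cycle)
  h_prog <- h_dpfs - h_os
  if (h_prog < -1e-9)
    stop(sprintf("numerical-consistency error: D/PFS hazard below OS hazard (stage %s, t = %.3f)",
                 os$stage, t))
  h_prog <- max(h_prog, 0)
  h_die_pre <- h_os + h_bg
  p_die_pre <- 1 - exp(-h_die_pre * cycle)
  p_prog <- exp(-h_die_pre * cycle) * (1 - exp(-h_prog * cycle))
  h_post <- interval_hazard(post_os, t, cycle)
  h_die_post <- h_post + h_bg
  p_die_post <- 1 - exp(-h_die_post * cycle)
  m <- matrix(c(
    1 - p_die_pre - p_prog, p_prog,         p_die_pre,
    0,                      1 - p_die_post, p_die_post,
    0,                      0,              1), byrow = TRUE, nrow = 3,
    dimnames = list(c("pre", "post", "dead"), c("pre", "post", "dead")))
  attr(m, "lc_share") <- c(
    pre  = if (h_die_pre > 0) h_os / h_die_pre else 0,
    post = if (h_die_post > 0) h_post / h_die_post else 0)
  m
}
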