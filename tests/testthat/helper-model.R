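# Shared fixtures; expensive objects are computed once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

base_params <- function() cached("params", table1_fixture())
base_lt <- function() cached("lt", make_life_table())
base_som <- function() cached("som", make_screening_outcomes())
base_result <- function()
  cached("result", run_model(base_params(), base_som(), base_lt()))
base_tornado <- function()
  cached("tornado", one_way(base_params(), som = base_som(), lt = base_lt()))

# a life table with no background mortality (q = 0 below max age)
zero_lt <- function() {
  lt <- make_life_table(a = 0, b = 0.1, c = 0, max_age = 200)
  lt
}

exp_curve <- function(rate, endpoint = "OS", stage = "IV")
  lcsmodel:::new_curve("exponential", c(rate = rate), endpoint, stage)

# hand-built trace: occupancy row per cycle start
manual_trace <- function(occ, prog = NULL, lc = NULL, oth = NULL,
                         stage = "I", dt = 0.25) {
  nc <- nrow(occ) - 1
  lcsmodel:::new_trace(stage, sum(occ[1, ]), 58, 0, dt, occ,
                       prog %||% numeric(nc), lc %||% numeric(nc),
                       oth %||% numeric(nc))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
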