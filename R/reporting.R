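# Report writers (base-case results table, scenario table) and the
# command-line entry point.

report_round <- function(x) round(unname(x))

#' Write the base-case results table
#'
#' A CSV shaped like the published base-case table: lung cancer diagnoses by
#' stage and arm, late-stage diagnoses averted, lung cancer deaths, life
#' years, QALYs, costs by category, ICER and NMB.  Persons and EUR are
#' rounded to integers; every cell is a direct restatement of an
#' `lcs_result` or ledger field (the only report-side arithmetic is the
#' stated roundings and the averted-stage difference).
#'
#' @param r an `lcs_result`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_table2 <- function(r, path) {
  g <- function(x, s) { v <- x[s]; if (is.na(v)) 0 else unname(v) }
  scr <- r$screening; nos <- r$no_screening
  rows <- list()
  add <- function(item, s = NA, n = NA, inc = NA)
    rows[[length(rows) + 1]] <<- data.frame(item = item, screening = s,
                                            no_screening = n, incremental = inc)
  dsc <- scr$diagnosed_by_stage; dns <- nos$diagnosed_by_stage
  add("diagnoses_total", report_round(sum(dsc)), report_round(sum(dns[STAGES], na.rm = TRUE)),
      report_round(sum(dsc) - sum(dns[STAGES], na.rm = TRUE)))
  for (s in STAGES)
    add(paste0("diagnoses_stage_", s), report_round(g(dsc, s)), report_round(g(dns, s)),
        report_round(g(dsc, s) - g(dns, s)))
  add("missed_individuals", NA, report_round(g(dns, "missed")))
  averted <- (g(dns, "IV") - g(dsc, "IV")) + (g(dns, "III") - g(dsc, "III"))
  add("stage_III_IV_averted", report_round(averted))
  ksc <- scr$lc_deaths_by_stage; kns <- nos$lc_deaths_by_stage
  add("lc_deaths_total", report_round(sum(ksc)), report_round(sum(kns)),
      report_round(sum(ksc) - sum(kns)))
  add("ly_total", report_round(scr$ly), report_round(nos$ly),
      report_round(scr$ly - nos$ly))
  add("qaly_total", report_round(scr$qaly), report_round(nos$qaly),
      report_round(scr$qaly - nos$qaly))
  cc <- function(arm, cat) unname(arm$costs[[cat]])
  for (cat in c("recruitment", "screening", "diagnostic"))
    add(paste0("cost_", cat), report_round(cc(scr, cat)), report_round(cc(nos, cat)),
        report_round(cc(scr, cat) - cc(nos, cat)))
  tsc <- scr$costs$treatment_by_stage; tns <- nos$costs$treatment_by_stage
  add("cost_treatment_total", report_round(sum(tsc, na.rm = TRUE)),
      report_round(sum(tns, na.rm = TRUE)),
      report_round(sum(tsc, na.rm = TRUE) - sum(tns, na.rm = TRUE)))
  for (s in STAGES)
    add(paste0("cost_treatment_stage_", s), report_round(g(tsc, s)),
        report_round(g(tns, s)), report_round(g(tsc, s) - g(tns, s)))
  add("cost_end_of_life", report_round(scr$costs$end_of_life),
      report_round(nos$costs$end_of_life),
      report_round(scr$costs$end_of_life - nos$costs$end_of_life))
  add("cost_total", report_round(scr$total_cost), report_round(nos$total_cost),
      report_round(scr$total_cost - nos$total_cost))
  if (r$incremental$delta_qaly == 0) {
    add("icer_per_qaly", "identical/dominated")
  } else {
    add("icer_per_qaly", report_round(r$icer_qaly))
  }
  add("icer_per_ly", if (r$incremental$delta_ly == 0) "identical/dominated"
      else report_round(r$icer_ly))
  add("nmb", report_round(r$nmb))
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config_path) {
  if (is.null(config_path)) return("builtin-base-case")
  unname(tools::md5sum(config_path))
}

#' Run the base case and write reports
#'
#' Loads the configuration (or uses the built-in base case), runs the model,
#' and writes a results-table CSV, a JSON result, and a run manifest to
#' `out_dir`.
#'
#' @param config_path YAML configuration path, or `NULL` for the base case.
#' @param out_dir output directory (created if needed).
#' @param som,lt screening-outcome model and life table.
#' @return the `lcs_result`, invisibly.
#' @export
run_base_case <- function(config_path = NULL, out_dir = ".",
                          som = make_screening_outcomes(), lt = make_life_table()) {
  p <- if (is.null(config_path)) table1_fixture() else load_parameters(config_path)
  r <- run_model(p, som, lt)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table2(r, file.path(out_dir, "table2.csv"))
  res_json <- list(
    screening = list(ly = r$screening$ly, qaly = r$screening$qaly,
                     total_cost = r$screening$total_cost,
                     costs = r$screening$costs),
    no_screening = list(ly = r$no_screening$ly, qaly = r$no_screening$qaly,
                        total_cost = r$no_screening$total_cost,
                        costs = r$no_screening$costs),
    incremental = r$incremental,
    icer_qaly = r$icer_qaly, icer_ly = r$icer_ly, nmb = r$nmb,
    schema_version = "1")
  jsonlite::write_json(res_json, file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config_hash = config_hash(config_path),
                   package_version = as.character(utils::packageVersion("lcsmodel")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   scenario = "base_case")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(r)
}

#' Command-line interface
#'
#' Subcommands: `base` (base-case run and reports), `osa` (tornado CSV),
#' `psa` (cost-effectiveness-plane scatter CSV), `ceac` (CEAC CSV),
#' `scenarios` (scenario table CSV).  Flags: `--config`, `--seed`,
#' `--n-draws`, `--wtp-grid` (comma-separated), `--out-dir`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process's).
#' @return exit status 0 invisibly; stops with a message on error.
#' @export
lcs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop("usage: lcsmodel <base|osa|psa|ceac|scenarios> [options]")
  cmd <- args[[1]]
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-draws", type = "integer", default = 1000L,
                          dest = "n_draws"),
    optparse::make_option("--wtp-grid", type = "character",
                          default = "0,10000,20000,30000,40000,50000,75000,100000",
                          dest = "wtp_grid"),
    optparse::make_option("--out-dir", type = "character", default = ".",
                          dest = "out_dir"))), args = args[-1])
  dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- if (is.null(opts$config)) table1_fixture() else load_parameters(opts$config)
  log_line <- function(...) message(sprintf(...))
  log_line("lcsmodel %s | command=%s seed=%d config=%s",
           as.character(utils::packageVersion("lcsmodel")), cmd, opts$seed,
           config_hash(opts$config))
  switch(cmd,
    base = run_base_case(opts$config, opts$out_dir),
    osa = {
      tor <- one_way(p)
      write.csv(tor, file.path(opts$out_dir, "tornado.csv"), row.names = FALSE)
    },
    psa = {
      s <- sample_psa(p, opts$n_draws, seed = opts$seed)
      write.csv(s$draws, file.path(opts$out_dir, "ce_plane.csv"),
                row.names = FALSE)
      log_line("probabilistic ICER: %.0f", probabilistic_icer(s))
    },
    ceac = {
      s <- sample_psa(p, opts$n_draws, seed = opts$seed)
      grid <- as.numeric(strsplit(opts$wtp_grid, ",")[[1]])
      write.csv(ceac(s, grid), file.path(opts$out_dir, "ceac.csv"),
                row.names = FALSE)
    },
    scenarios = {
      tab <- run_scenarios(p, table3_scenarios())
      write.csv(tab, file.path(opts$out_dir, "scenarios.csv"),
                row.names = FALSE)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
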