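# End-to-end runner: simulate or read a cohort, then produce the cohort
# summary, the concordance/tetrachoric table, the biometric model grid,
# cumulative incidence and concordance curves, and age-resolved
# component curves, from a single configuration.  All artifacts are
# plain text (TSV + JSON); a run is deterministic given config + seed.

.report_schema_version <- "1.0"

#' Default run configuration
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param scenario A `sim_params` object used when `input` is `NULL`
#'   (default: [default_scenario()]).
#' @param models Model names fitted in each sex mode.
#' @param sex_modes Sex modes for the model grid.
#' @param age_grid Ages for the CIF / concordance / heritability curves.
#' @param n_boot Bootstrap replicates for concordance bands.
#' @param weight_cap Cap for [ipc_weights()].
#' @param seed Integer master seed (mandatory; drives simulation and all
#'   bootstraps).
#' @param verbose Log progress to stderr.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, scenario = NULL,
                       models = c("sat", "ACE", "AE", "CE", "E"),
                       sex_modes = c("adjusted", "stratified_F",
                                     "stratified_M"),
                       age_grid = seq(40, 100, by = 5),
                       n_boot = 50, weight_cap = 20, seed = 1L,
                       verbose = FALSE) {
  if (is.null(scenario)) scenario <- default_scenario(seed = seed)
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(input = input, scenario = scenario, models = models,
                 sex_modes = sex_modes, age_grid = age_grid,
                 n_boot = n_boot, weight_cap = weight_cap,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' The file mirrors the [run_config()] arguments; `scenario` is a nested
#' object of [simulation_params()] arguments.  An annotated example
#' ships in `inst/extdata/example_config.json`.
#'
#' @param path JSON file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  drop_meta <- function(x) x[!startsWith(names(x), "_")]
  cfg <- drop_meta(cfg)
  scen <- NULL
  if (!is.null(cfg$scenario))
    scen <- do.call(simulation_params, drop_meta(as.list(cfg$scenario)))
  args <- cfg[setdiff(names(cfg), "scenario")]
  do.call(run_config, c(args, list(scenario = scen)))
}

.log <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort and emits: a cohort composition
#' summary; the pair-count/tetrachoric table on both-alive-at-entry
#' pairs; the biometric model grid per sex mode with LR/AIC comparisons;
#' sex-specific cumulative incidence of the endpoint and of death;
#' proband-wise concordance curves per zygosity class; and age-resolved
#' variance components for the best sex-adjusted model.  When `out_dir`
#' is given, each table is written as TSV, the whole bundle as
#' `report.json`, and the configuration is echoed back.
#'
#' Per-stratum failures are isolated: a stratum whose fit fails is
#' reported as an error entry without aborting the run.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return The report bundle, invisibly a named list.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  t0 <- Sys.time()

  if (!is.null(config$input)) {
    .log(v, "reading cohort from ", config$input)
    cohort <- read_cohort(config$input)
  } else {
    .log(v, "simulating cohort (seed ", config$scenario$seed, ")")
    cohort <- simulate_cohort(config$scenario)
  }

  asm <- assemble_pairs(cohort)
  pairs <- asm$pairs
  .log(v, nrow(cohort), " records, ", nrow(pairs), " pairs, ",
       nrow(asm$orphans), " orphans")

  summary_tbl <- do.call(rbind, lapply(split(cohort, cohort$zygosity),
    function(d) data.frame(
      zygosity = d$zygosity[1], n_twins = nrow(d),
      n_female = sum(d$sex == "F"), n_event = sum(d$status == "EVENT"),
      n_death = sum(d$status == "DEATH"),
      mean_entry_age = mean(d$entry_age), stringsAsFactors = FALSE)))
  rownames(summary_tbl) <- NULL

  conc_tbl <- tryCatch(concordance_table(pairs), error = function(e) {
    .log(v, "concordance table failed: ", conditionMessage(e)); NULL })

  weights <- ipc_weights(cohort, cap = config$weight_cap)
  .log(v, "IPC weights: ", attr(weights, "n_capped"), " capped")

  grid <- list()
  for (sm in config$sex_modes) {
    for (m in config$models) {
      key <- paste(sm, m, sep = ".")
      grid[[key]] <- tryCatch(
        fit_model(model_spec(m, sm), pairs, weights),
        error = function(e) {
          .log(v, "fit ", key, " failed: ", conditionMessage(e))
          list(error = conditionMessage(e))
        })
    }
  }
  grid_tbl <- do.call(rbind, lapply(names(grid), function(key) {
    f <- grid[[key]]
    if (!inherits(f, "biometric_fit"))
      return(data.frame(fit = key, model = NA_character_,
                        sex_mode = NA_character_, prev_F = NA_real_,
                        prev_M = NA_real_, rho_MZ = NA_real_,
                        rho_DZ = NA_real_, cwc_MZ = NA_real_,
                        cwc_DZ = NA_real_, H = NA_real_, A = NA_real_,
                        D = NA_real_, C = NA_real_, E = NA_real_,
                        logLik = NA_real_, AIC = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(fit = key, model = f$spec$model, sex_mode = f$spec$sex_mode,
               prev_F = f$prevalence[["F"]], prev_M = f$prevalence[["M"]],
               rho_MZ = f$rho_MZ, rho_DZ = f$rho_DZ,
               cwc_MZ = f$casewise[["MZ"]], cwc_DZ = f$casewise[["DZ"]],
               H = f$H, A = f$components[["A"]], D = f$components[["D"]],
               C = f$components[["C"]], E = f$components[["E"]],
               logLik = f$logLik, AIC = f$AIC, stringsAsFactors = FALSE)
  }))
  comparisons <- lapply(stats::setNames(config$sex_modes, config$sex_modes),
    function(sm) {
      fits <- grid[paste(sm, config$models, sep = ".")]
      names(fits) <- config$models
      fits <- Filter(function(f) inherits(f, "biometric_fit"), fits)
      if (length(fits) >= 2) compare_models(fits) else NULL
    })

  cif <- list()
  for (s in c("F", "M")) {
    rec <- cohort[cohort$sex == s, , drop = FALSE]
    cif[[s]] <- list(event = aalen_johansen(rec, "EVENT"),
                     death = aalen_johansen(rec, "DEATH"))
  }

  set.seed(config$seed + 1L)
  conc_curves <- lapply(list(MZ = "MZ", DZ = c("DZ_SS", "DZ_OS")),
    function(z) tryCatch(
      concordance_function(select_stratum(pairs, zygosity = z),
                           config$age_grid, weights,
                           n_boot = config$n_boot),
      error = function(e) NULL))

  best_adj <- grid_tbl[grid_tbl$sex_mode == "adjusted" &
                         grid_tbl$model != "sat", , drop = FALSE]
  herit_age <- NULL
  if (nrow(best_adj)) {
    best_model <- best_adj$model[which.min(best_adj$AIC)]
    .log(v, "age-resolved components for ", best_model)
    herit_age <- tryCatch(
      heritability_by_age(pairs, model_spec(best_model, "adjusted"),
                          config$age_grid, weights),
      error = function(e) NULL)
  }

  report <- list(
    schema_version = .report_schema_version,
    config = list(seed = config$seed, models = config$models,
                  sex_modes = config$sex_modes,
                  age_grid = config$age_grid, n_boot = config$n_boot,
                  weight_cap = config$weight_cap,
                  scenario = if (is.null(config$input))
                    unclass(config$scenario) else NULL,
                  input = config$input),
    cohort_summary = summary_tbl,
    concordance_table = conc_tbl,
    model_grid = grid_tbl,
    comparisons = lapply(comparisons, function(x)
      if (is.null(x)) NULL else list(tests = x$tests, aic = x$aic)),
    cif = lapply(cif, function(x) lapply(x, as.data.frame)),
    concordance_curves = conc_curves,
    heritability_by_age = herit_age,
    n_capped_weights = attr(weights, "n_capped"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, name) if (!is.null(df))
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    wtsv(summary_tbl, "cohort_summary.tsv")
    wtsv(conc_tbl, "concordance_table.tsv")
    wtsv(grid_tbl, "model_grid.tsv")
    wtsv(herit_age, "heritability_by_age.tsv")
    for (s in names(cif)) {
      wtsv(as.data.frame(cif[[s]]$event), paste0("cif_event_", s, ".tsv"))
      wtsv(as.data.frame(cif[[s]]$death), paste0("cif_death_", s, ".tsv"))
    }
    for (z in names(conc_curves))
      wtsv(conc_curves[[z]], paste0("concordance_", z, ".tsv"))
    # elapsed time varies between runs; keep the JSON deterministic
    json_report <- report
    json_report$elapsed_sec <- NULL
    jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Parses `--config PATH --seed INT --out DIR --verbose` and runs
#' [run_pipeline()].  Intended for
#' `Rscript -e 'twinrisk::twinrisk_cli()' -- --seed 1 --out results`.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return The report bundle, invisibly.
#' @export
twinrisk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the CLI requires the 'optparse' package")
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON run configuration"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "twinrisk_out"),
    optparse::make_option("--verbose", action = "store_true",
                          default = FALSE)))
  opt <- optparse::parse_args(parser, args = args)
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
         else run_config(seed = opt$seed, verbose = opt$verbose)
  cfg$seed <- as.integer(opt$seed)
  cfg$scenario$seed <- as.integer(opt$seed)
  cfg$verbose <- opt$verbose
  run_pipeline(cfg, out_dir = opt$out)
}
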