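# Run orchestration, manifest and file emission -----------------------------

#' Run a full analysis and emit its output files
#'
#' High-level driver behind the command-line interface. Each command writes
#' its tabular outputs as CSV into `out_dir` together with a JSON run
#' manifest (package version, timestamp, seed, MD5 of the resolved
#' parameter set, and the file inventory), so deterministic commands re-run
#' from the same manifest reproduce their outputs bit-identically.
#'
#' Commands: `"base-case"` (comparison row plus both cohort traces),
#' `"scenarios"` (the scenario table), `"dsa"` (tornado table),
#' `"psa"` (samples and acceptability curve), `"validate-oracle"`
#' (cohort-versus-microsimulation report).
#'
#' @param command one of the commands above.
#' @param params `NULL` for defaults, or a config path / named list passed to
#'   [load_parameters()].
#' @param out_dir output directory, created if missing.
#' @param entry_age,exit_age scenario ages (base case 40-59).
#' @param perspective `"payer"` or `"societal"`; a societal run requires the
#'   user-supplied indirect-cost block (see [societal_block()]).
#' @param iterations PSA iterations.
#' @param n_patients microsimulation size for `"validate-oracle"`.
#' @param seed RNG seed for the stochastic commands.
#' @param wtp,discount optional overrides of the willingness-to-pay and
#'   discount rate.
#' @param quiet suppress console summaries.
#' @return invisibly, a list with the computed objects and the manifest.
#' @export
run_analysis <- function(command = c("base-case", "scenarios", "dsa", "psa",
                                     "validate-oracle"),
                         params = NULL, out_dir = ".",
                         entry_age = 40, exit_age = 59,
                         perspective = c("payer", "societal"),
                         iterations = 10000, n_patients = 50000, seed = 1,
                         wtp = NULL, discount = NULL, quiet = FALSE) {
  command <- match.arg(command)
  perspective <- match.arg(perspective)
  ps <- load_parameters(params)
  if (!is.null(discount)) ps <- set_parameter(ps, "discount_rate", discount)
  if (!is.null(wtp)) ps <- set_parameter(ps, "wtp", wtp)
  validate_parameters(ps)
  if (perspective == "societal" &&
      (is.null(ps$societal$indirect_cost_biblind) ||
       is.null(ps$societal$visits_per_state)))
    stop("societal perspective requires indirect_cost_biblind and ",
         "visits_per_state; supply them via the parameter config",
         call. = FALSE)
  sc <- scenario_config(entry_age, exit_age, perspective = perspective)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }
  out <- list(parameters = ps, scenario = sc)

  if (command == "base-case") {
    lpi <- run_cohort(ps, "lpi", sc)
    obs <- run_cohort(ps, "observation", sc)
    cea <- compare_arms(lpi, obs, ps$values$wtp, ps$values$jpy_per_gbp)
    emit("cea.csv", function(f) cea_table(cea, f))
    emit("trace_lpi.csv", function(f) trace_table(lpi, f))
    emit("trace_observation.csv", function(f) trace_table(obs, f))
    if (!quiet) print(cea)
    out$cea <- cea
  } else if (command == "scenarios") {
    sweep <- scenario_sweep(ps, wtp = ps$values$wtp)
    emit("scenarios.csv", function(f)
      utils::write.csv(sweep, f, row.names = FALSE))
    if (!quiet) print(sweep[, c("scenario", "delta_cost", "delta_qaly",
                                "icer_jpy")])
    out$sweep <- sweep
  } else if (command == "dsa") {
    torn <- tornado(ps, sc, top_k = 12, wtp = ps$values$wtp)
    base <- compare_arms(run_cohort(ps, "lpi", sc),
                         run_cohort(ps, "observation", sc),
                         ps$values$wtp, ps$values$jpy_per_gbp)
    emit("tornado.csv", function(f) tornado_csv(attr(torn, "full"), f))
    if (!quiet) {
      cat("Top one-way excursions by ICER span:\n")
      print(torn[, c("parameter", "icer_low", "icer_high", "span")])
    }
    out$tornado <- torn
    out$base_cea <- base
  } else if (command == "psa") {
    psa <- run_psa(ps, sc, n_iterations = iterations, seed = seed,
                   wtp = ps$values$wtp)
    curve <- ceac(psa)
    emit("psa_samples.csv", function(f) psa_csv(psa, f))
    emit("ceac.csv", function(f) ceac_csv(curve, f))
    if (!quiet) print(psa)
    out$psa <- psa
    out$ceac <- curve
  } else if (command == "validate-oracle") {
    rep <- validate_oracle(ps, sc, n_patients = n_patients, seed = seed)
    emit("oracle_validation.csv", function(f)
      utils::write.csv(rep, f, row.names = FALSE))
    if (!quiet) print(rep)
    out$validation <- rep
  }

  emit("parameters.csv", function(f) parameters_table(ps, f))
  pfile <- emit("parameters.json", function(f) write_parameters(ps, f))
  manifest <- list(
    package = "lpicea",
    version = as.character(utils::packageVersion("lpicea")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    command = command, seed = seed,
    scenario = sc$label, perspective = perspective,
    parameter_md5 = unname(tools::md5sum(pfile)),
    files = c(files, "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
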