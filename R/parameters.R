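#' @keywords internal
"_PACKAGE"

# Parameter registry --------------------------------------------------------
#
# One row per model input. `type` drives the deterministic sensitivity range
# (+/-30% probabilities, +/-8% utilities, +/-20% costs; discount rate 0-4%)
# and the probabilistic distribution family (beta with SD = 10% of the mean
# for probabilities, beta with SD = 5% for utilities, gamma with SD = 10%
# for costs; structural constants are held fixed).
.param_registry <- function() {
  row <- function(name, value, type, family, sd_frac, label) {
    data.frame(name = name, value = value, type = type,
               psa_family = family, psa_sd_frac = sd_frac,
               label = label, stringsAsFactors = FALSE)
  }
  reg <- rbind(
    row("p_pacs_pac_lpi",      0.0117,  "probability", "beta",  0.10, "PACS to PAC, LPI arm"),
    row("p_pacs_pac_obs",      0.0218,  "probability", "beta",  0.10, "PACS to PAC, observation arm"),
    row("p_pac_pacg_lpi",      0.00146, "probability", "beta",  0.10, "PAC to PACG, LPI arm"),
    row("p_pac_pacg_obs",      0.0034,  "probability", "beta",  0.10, "PAC to PACG, observation arm"),
    row("p_pacg_uniblind",     0.0046,  "probability", "beta",  0.10, "PACG to unilateral blindness"),
    row("p_uni_biblind",       0.0387,  "probability", "beta",  0.10, "Unilateral to bilateral blindness"),
    row("p_pacs_aacc_obs",     0.00097, "probability", "beta",  0.10, "PACS to AACC, observation arm"),
    row("p_aacc_pacs_lpiopen", 1.0,     "probability", "fixed", NA,   "AACC to PACS (LPI open)"),
    row("p_pacg_trab_40_49",   0.0088,  "probability", "beta",  0.10, "PACG to trabeculectomy, age 40-49"),
    row("p_pacg_trab_50_59",   0.0063,  "probability", "beta",  0.10, "PACG to trabeculectomy, age 50+"),
    row("u_pacs",              1.0,     "utility",     "fixed", NA,   "Utility, PACS"),
    row("u_pac",               1.0,     "utility",     "fixed", NA,   "Utility, PAC"),
    row("u_aacc",              0.99,    "utility",     "fixed", NA,   "Utility, AACC year"),
    row("u_pacg",              0.75,    "utility",     "beta",  0.05, "Utility, PACG"),
    row("u_trab",              0.74,    "utility",     "beta",  0.05, "Utility, trabeculectomy year"),
    row("u_uniblind",          0.47,    "utility",     "beta",  0.05, "Utility, unilateral blindness"),
    row("u_biblind",           0.26,    "utility",     "beta",  0.05, "Utility, bilateral blindness"),
    row("trab_utility_loss",   0.007,   "constant",    "fixed", NA,   "Utility loss attributed to glaucoma surgery"),
    row("c_pacs_lpi_y1",       98393,   "cost",        "gamma", 0.10, "PACS first year, LPI arm"),
    row("c_pacs_obs_y1",       19560,   "cost",        "gamma", 0.10, "PACS first year, observation arm"),
    row("c_pacs_lpi_follow",   23780,   "cost",        "gamma", 0.10, "PACS follow-up, LPI arm / post-AACC"),
    row("c_pacs_obs_follow",   22180,   "cost",        "gamma", 0.10, "PACS follow-up, observation arm"),
    row("c_pac_y1",            171259,  "cost",        "gamma", 0.10, "PAC first year (incl. lens extraction)"),
    row("c_pac_follow",        23780,   "cost",        "gamma", 0.10, "PAC follow-up"),
    row("c_pacg_40_49",        48545,   "cost",        "gamma", 0.10, "PACG annual, age 40-49"),
    row("c_pacg_50_59",        47553,   "cost",        "gamma", 0.10, "PACG annual, age 50+"),
    row("c_uniblind_40_49",    46645,   "cost",        "gamma", 0.10, "Unilateral blindness annual, age 40-49"),
    row("c_uniblind_50_59",    45653,   "cost",        "gamma", 0.10, "Unilateral blindness annual, age 50+"),
    row("c_biblind_40_49",     44745,   "cost",        "gamma", 0.10, "Bilateral blindness annual, age 40-49"),
    row("c_biblind_50_59",     43753,   "cost",        "gamma", 0.10, "Bilateral blindness annual, age 50+"),
    row("c_aacc",              107167,  "cost",        "gamma", 0.10, "AACC year (emergency LPI)"),
    row("c_trab",              697008,  "cost",        "gamma", 0.10, "Trabeculectomy (one-time)"),
    row("discount_rate",       0.02,    "rate",        "fixed", NA,   "Annual discount rate"),
    row("wtp",                 5e6,     "constant",    "fixed", NA,   "Willingness-to-pay, JPY/QALY"),
    row("jpy_per_gbp",         160,     "constant",    "fixed", NA,   "Exchange rate, JPY per pound sterling")
  )
  # deterministic one-way ranges by parameter class
  lo <- hi <- rep(NA_real_, nrow(reg))
  vary <- reg$psa_family != "fixed"
  frac <- c(probability = 0.30, utility = 0.08, cost = 0.20)[reg$type]
  lo[vary] <- reg$value[vary] * (1 - frac[vary])
  hi[vary] <- reg$value[vary] * (1 + frac[vary])
  dr <- reg$name == "discount_rate"
  lo[dr] <- 0; hi[dr] <- 0.04
  reg$dsa_low <- lo
  reg$dsa_high <- hi
  reg
}

#' Default model parameters
#'
#' Returns the complete input set of the two-arm angle-closure Markov model:
#' annual transition probabilities, state utilities, state costs in Japanese
#' Yen (with 40-49 / 50+ age brackets where the inputs differ by age), the
#' annual discount rate, the willingness-to-pay threshold and the JPY/GBP
#' exchange rate. Every varied parameter carries its one-way sensitivity
#' range and its probabilistic distribution specification.
#'
#' @param societal optional list of societal-perspective inputs; see
#'   [societal_block()]. The payer-perspective model ignores it.
#' @return An object of class `lpi_params`: a list with elements `values`
#'   (named list of numbers), `meta` (data frame with one row per parameter:
#'   `name`, `value`, `type`, `dsa_low`, `dsa_high`, `psa_family`,
#'   `psa_sd_frac`, `label`) and `societal`.
#' @examples
#' ps <- default_parameters()
#' ps$values$p_pacs_pac_lpi   # 0.0117
#' @export
default_parameters <- function(societal = societal_block()) {
  meta <- .param_registry()
  ps <- structure(
    list(values = as.list(stats::setNames(meta$value, meta$name)),
         meta = meta, societal = societal),
    class = "lpi_params")
  validate_parameters(ps)
  ps
}

#' Societal-perspective cost block
#'
#' The societal analysis needs indirect costs that are not part of the payer
#' data set; only the travel cost per visit and the fraction of indirect
#' costs attributed to unilateral blindness ship as defaults. The annual
#' indirect cost of bilateral blindness and the visit schedule per state must
#' be supplied by the user before a societal run is possible.
#'
#' @param indirect_cost_biblind annual indirect cost (JPY) of bilateral
#'   blindness (disability pension, care, lost salary); no default.
#' @param uniblind_fraction fraction of the bilateral indirect cost incurred
#'   by unilateral blindness.
#' @param travel_cost_per_visit travel cost in JPY per clinic visit.
#' @param visits_per_state named numeric vector of annual visit counts per
#'   model state; no default.
#' @export
societal_block <- function(indirect_cost_biblind = NULL,
                           uniblind_fraction = 0.30,
                           travel_cost_per_visit = 4547,
                           visits_per_state = NULL) {
  list(indirect_cost_biblind = indirect_cost_biblind,
       uniblind_fraction = uniblind_fraction,
       travel_cost_per_visit = travel_cost_per_visit,
       visits_per_state = visits_per_state)
}

#' Validate a parameter set
#'
#' Checks the structural invariants: probabilities and utilities in \[0, 1\],
#' non-negative costs and discount rate, per-state exit probabilities summing
#' to at most one, and one-way ranges bracketing the default value.
#'
#' @param ps an `lpi_params` object.
#' @return `ps`, invisibly; errors name the violated invariant.
#' @export
validate_parameters <- function(ps) {
  stopifnot(inherits(ps, "lpi_params"))
  v <- ps$values
  m <- ps$meta
  num <- vapply(v[m$name], function(x) is.numeric(x) && length(x) == 1, logical(1))
  if (!all(num))
    stop("non-scalar parameter value: ", paste(m$name[!num], collapse = ", "))
  val <- unlist(v[m$name])
  bad <- function(cond, what) {
    if (any(cond))
      stop("parameter out of range (", what, "): ",
           paste(m$name[cond], collapse = ", "), call. = FALSE)
  }
  prob <- m$type == "probability"
  util <- m$type == "utility"
  bad(prob & (val < 0 | val > 1), "probability must be in [0, 1]")
  bad(util & (val < 0 | val > 1), "utility must be in [0, 1]")
  bad(m$type == "cost" & val < 0, "cost must be >= 0")
  if (v$discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  if (v$jpy_per_gbp <= 0) stop("jpy_per_gbp must be > 0", call. = FALSE)
  # exit-probability mass per state, worst case (observation-arm PACS rows)
  exits <- c(
    pacs_obs = v$p_pacs_pac_obs + v$p_pacs_aacc_obs,
    pacs_lpi = v$p_pacs_pac_lpi,
    pac_obs  = v$p_pac_pacg_obs, pac_lpi = v$p_pac_pacg_lpi,
    pacg     = v$p_pacg_uniblind, uni = v$p_uni_biblind)
  if (any(exits > 1))
    stop("exit probabilities exceed 1 for state row: ",
         paste(names(exits)[exits > 1], collapse = ", "), call. = FALSE)
  varied <- !is.na(m$dsa_low)
  dv <- val[varied]
  if (any(m$dsa_low[varied] > dv | dv > m$dsa_high[varied]))
    stop("dsa range does not bracket default value", call. = FALSE)
  invisible(ps)
}

#' Age-bracket parameter lookup
#'
#' Trabeculectomy probability and the PACG/blindness annual costs are
#' tabulated for ages 40-49 and 50-59. Brackets are half-open: the 40-49
#' value applies to attained ages in \[40, 50) and the 50-59 value to all
#' ages 50 and above, so lifetime scenarios reuse the older bracket beyond
#' age 59.
#'
#' @param ps an `lpi_params` object.
#' @param family one of `"trab_prob"`, `"pacg_cost"`, `"uniblind_cost"`,
#'   `"biblind_cost"`.
#' @param age attained age in years (>= 40); vectorised.
#' @return the bracketed value(s).
#' @examples
#' ps <- default_parameters()
#' age_bracket_value(ps, "trab_prob", 45)  # 0.0088
#' age_bracket_value(ps, "pacg_cost", 50)  # 47553: age 50 is the upper bracket
#' @export
age_bracket_value <- function(ps, family = c("trab_prob", "pacg_cost",
                                             "uniblind_cost", "biblind_cost"),
                              age) {
  family <- match.arg(family)
  if (any(age < 40)) stop("age must be >= 40", call. = FALSE)
  v <- ps$values
  pair <- switch(family,
    trab_prob     = c(v$p_pacg_trab_40_49, v$p_pacg_trab_50_59),
    pacg_cost     = c(v$c_pacg_40_49, v$c_pacg_50_59),
    uniblind_cost = c(v$c_uniblind_40_49, v$c_uniblind_50_59),
    biblind_cost  = c(v$c_biblind_40_49, v$c_biblind_50_59))
  ifelse(age < 50, pair[1], pair[2])
}

#' Load parameters from a config document
#'
#' Merges user overrides into the default set. The source may be a named
#' list, or a path to a YAML or JSON document whose top level maps parameter
#' names to numbers (an optional `societal` block is passed through).
#'
#' @param config_source named list, or path to a `.yaml`/`.yml`/`.json` file;
#'   `NULL` or an empty list returns the defaults.
#' @param quiet suppress the per-override messages.
#' @return a validated `lpi_params` object.
#' @examples
#' ps <- load_parameters(list(discount_rate = 0.04))
#' ps$values$discount_rate
#' @export
load_parameters <- function(config_source = NULL, quiet = TRUE) {
  ps <- default_parameters()
  if (is.null(config_source)) return(ps)
  ov <- config_source
  if (is.character(ov) && length(ov) == 1) {
    if (!file.exists(ov)) stop("config file not found: ", ov, call. = FALSE)
    ov <- if (grepl("\\.json$", ov, ignore.case = TRUE))
      jsonlite::read_json(ov, simplifyVector = TRUE)
    else yaml::read_yaml(ov)
  }
  if (!is.list(ov)) stop("config must be a named list or a file path", call. = FALSE)
  if (length(ov) == 0) return(ps)
  soc <- ov$societal
  ov$societal <- NULL
  unknown <- setdiff(names(ov), ps$meta$name)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(ov)) {
    if (!quiet) message("override: ", nm, " = ", ov[[nm]],
                        " (default ", ps$values[[nm]], ")")
    ps$values[[nm]] <- as.numeric(ov[[nm]])
    ps$meta$value[ps$meta$name == nm] <- as.numeric(ov[[nm]])
  }
  if (!is.null(soc)) ps$societal <- utils::modifyList(ps$societal, soc)
  validate_parameters(ps)
  ps
}

#' Replace one parameter value
#'
#' Convenience used by the sensitivity analyses; leaves ranges and
#' distribution metadata untouched and skips bracket revalidation so that
#' one-way excursions to a range endpoint are representable.
#'
#' @param ps an `lpi_params` object.
#' @param name parameter name.
#' @param value new value.
#' @keywords internal
set_parameter <- function(ps, name, value) {
  if (!name %in% ps$meta$name) stop("unknown parameter: ", name, call. = FALSE)
  ps$values[[name]] <- value
  ps$meta$value[ps$meta$name == name] <- value
  ps
}

#' Export the resolved parameter set as a data frame / CSV
#'
#' @param ps an `lpi_params` object.
#' @param file optional path; when given, the table is also written as CSV.
#' @return data frame with one row per parameter (name, value, dsa range,
#'   distribution family and SD fraction, label).
#' @export
parameters_table <- function(ps, file = NULL) {
  out <- ps$meta[, c("name", "value", "type", "dsa_low", "dsa_high",
                     "psa_family", "psa_sd_frac", "label")]
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Serialise parameters to YAML or JSON
#'
#' Round-trips through [load_parameters()]: reloading the written document
#' reproduces every field exactly.
#'
#' @param ps an `lpi_params` object.
#' @param file output path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_parameters <- function(ps, file) {
  vals <- ps$values
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(vals, file, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, file, precision = 15)
  }
  invisible(file)
}

#' @export
print.lpi_params <- function(x, ...) {
  cat("<lpi_params> ", nrow(x$meta), " parameters\n", sep = "")
  cat("  discount rate: ", x$values$discount_rate,
      ", WTP: ", format(x$values$wtp, big.mark = ",", scientific = FALSE),
      " JPY/QALY\n", sep = "")
  n_var <- sum(!is.na(x$meta$dsa_low))
  cat("  ", n_var, " parameters varied in sensitivity analyses\n", sep = "")
  invisible(x)
}
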