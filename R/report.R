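#' Run configuration for the reporting pipeline
#'
#' @param scenarios Character vector of catalogue scenario names, or `"all"`.
#'   Unknown names are rejected here, before any solve.
#' @param constants A [physio_constants()] set.
#' @param control A [chain_control()].
#' @param perturbations A list of [perturbation()] specs for the sensitivity
#'   block (default: a single deterministic 10% sinus-pressure reduction).
#' @param output_dir Directory the artifact bundle is written to.
#' @param formats Output formats, subset of `c("csv", "json")`.
#' @param verbose Log scenario, closure mode, iterations, residual and
#'   saturation flags per solve.
#' @return An object of class `run_config`.
#' @export
model_config <- function(scenarios = "all",
                         constants = normal_baseline(),
                         control = chain_control(),
                         perturbations = list(
                           perturbation("sinus_pressure", magnitude = -0.10)),
                         output_dir = tempfile("cvchain-run-"),
                         formats = c("csv", "json"),
                         verbose = FALSE) {
  catalogue <- scenario_catalogue()
  if (identical(scenarios, "all")) scenarios <- names(catalogue)
  unknown <- setdiff(scenarios, names(catalogue))
  if (length(unknown))
    stop("unknown scenario name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  formats <- match.arg(formats, several.ok = TRUE)
  structure(list(scenarios = scenarios, constants = constants,
                 control = control, perturbations = perturbations,
                 output_dir = output_dir, formats = formats,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `scenarios` (names or `all`), `constants` (named overrides
#' of the normal baseline), `control` (`relative_tolerance`,
#' `max_iterations`, `damping`), `perturbations` (list of perturbation
#' mappings), `output_dir`, `formats`, `verbose`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  constants <- do.call(physio_constants, as.list(doc$constants))
  control <- do.call(chain_control, as.list(doc$control))
  perts <- if (is.null(doc$perturbations))
    list(perturbation("sinus_pressure", magnitude = -0.10))
  else lapply(doc$perturbations, function(p) do.call(perturbation, p))
  model_config(
    scenarios = if (is.null(doc$scenarios)) "all" else unlist(doc$scenarios),
    constants = constants, control = control, perturbations = perts,
    output_dir = if (is.null(doc$output_dir)) tempfile("cvchain-run-") else doc$output_dir,
    formats = if (is.null(doc$formats)) c("csv", "json") else unlist(doc$formats),
    verbose = isTRUE(doc$verbose))
}

#' Run the full reporting pipeline
#'
#' Solves every configured scenario and writes the artifact bundle: one
#' per-segment CSV and one full-precision summary JSON per scenario, the three
#' figure-data tables (capillary TMP vs CBF, venous volume vs CBF, capillary
#' TMP vs ICP), the outflow-resistance correction report and the sensitivity
#' report. Solver failures are aggregated per scenario and raised after the
#' surviving artifacts are written.
#'
#' @param config A [model_config()] (or a YAML path accepted by
#'   [read_config()]).
#' @param timestamp Write a `#`-comment timestamp header on CSVs (numerical
#'   payload unaffected; off by default so reruns are byte-identical).
#' @return Invisibly, a list with the solved states, the sweep tables, the
#'   correction report and the sensitivity table.
#' @export
run_model <- function(config = model_config(), timestamp = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  catalogue <- scenario_catalogue()
  states <- list()
  failures <- character(0)
  for (nm in config$scenarios) {
    st <- tryCatch(
      solve_chain(catalogue[[nm]], config$constants, chain_laws(),
                  config$control, catalogue),
      error = function(e) e)
    if (inherits(st, "error")) {
      failures <- c(failures, sprintf("%s: %s", nm, conditionMessage(st)))
      next
    }
    states[[nm]] <- st
    if (config$verbose)
      message(sprintf("%-14s closure=%-18s iterations=%4d residual=%.2e flags=[%s]",
                      nm, st$report$closure, st$report$iterations,
                      st$report$residual,
                      paste(st$report$saturation_flags, collapse = ",")))
    write_chain_state(
      st,
      csv_path = if ("csv" %in% config$formats)
        file.path(config$output_dir, paste0(nm, ".csv")),
      json_path = if ("json" %in% config$formats)
        file.path(config$output_dir, paste0(nm, ".json")),
      timestamp = timestamp)
  }

  sweeps <- list(cbf_tmp = figure_data("cbf_tmp", config$constants,
                                       control = config$control),
                 cbf_veinvol = figure_data("cbf_veinvol", config$constants,
                                           control = config$control),
                 icp_tmp = figure_data("icp_tmp", config$constants,
                                       control = config$control))
  if ("csv" %in% config$formats)
    for (nm in names(sweeps))
      write_csv_payload(sweeps[[nm]],
                        file.path(config$output_dir, paste0("fig_", nm, ".csv")),
                        timestamp)

  correction <- correction_report()
  if ("json" %in% config$formats)
    jsonlite::write_json(unclass(correction),
                         file.path(config$output_dir, "rout_correction.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if ("csv" %in% config$formats)
    write_csv_payload(as.data.frame(unclass(correction)),
                      file.path(config$output_dir, "rout_correction.csv"),
                      timestamp)

  sens <- do.call(rbind, lapply(config$perturbations, function(p)
    sensitivity_report(spec = p, constants = config$constants,
                       control = config$control)))
  if (!is.null(sens) && "csv" %in% config$formats)
    write_csv_payload(sens, file.path(config$output_dir, "sensitivity.csv"),
                      timestamp)

  if (length(failures))
    stop("solver failures:\n  ", paste(failures, collapse = "\n  "), call. = FALSE)
  invisible(list(states = states, sweeps = sweeps, correction = correction,
                 sensitivity = sens, output_dir = config$output_dir))
}

write_csv_payload <- function(df, path, timestamp = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (timestamp) writeLines(sprintf("# generated: %s", format(Sys.time())), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Sensitivity of a solved scenario to a perturbed constant
#'
#' Re-solves a scenario under perturbed physiological constants and reports
#' the change in the mean capillary TMP. The chain is re-closed with the
#' arterial resistance solved residually at the scenario's flow, while the
#' outflow cuff follows a named response policy — the cuff's reaction to a
#' changed sinus pressure is not constrained by the calibration data, so the
#' result is labelled with its policy rather than treated as a hard
#' prediction:
#' \describe{
#'   \item{`tmp-scaled`}{cuff resistance scaled by the ratio of cuff
#'     transmural pressures (default).}
#'   \item{`unchanged`}{cuff resistance kept at the unperturbed value.}
#' }
#'
#' @param scenario Catalogue scenario name (default `"nph_baseline"`).
#' @param spec A [perturbation()] (default: deterministic 10% sinus
#'   reduction).
#' @param cuff_response Cuff policy, see above.
#' @param constants,control Passed to [solve_chain()].
#' @return A `data.frame`, one row per draw: the perturbed value, the solved
#'   capillary TMP, its percent change from the unperturbed state, and the
#'   cuff policy flag.
#' @export
#' @examples
#' sensitivity_report()  # sinus -10% on the NPH baseline
sensitivity_report <- function(scenario = "nph_baseline",
                               spec = perturbation("sinus_pressure",
                                                   magnitude = -0.10),
                               cuff_response = c("tmp-scaled", "unchanged"),
                               constants = normal_baseline(),
                               control = chain_control()) {
  cuff_response <- match.arg(cuff_response)
  catalogue <- scenario_catalogue()
  if (is.null(catalogue[[scenario]]))
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  base_sc <- catalogue[[scenario]]
  base <- solve_chain(base_sc, constants, control = control, catalogue = catalogue)
  r_cuf_base <- base$segments$resistance[base$segments$name == "cuff"]
  drawn <- perturb(constants, spec)
  rows <- lapply(seq_along(drawn), function(i) {
    pc <- drawn[[i]]
    tmp_ratio <- (pc$sinus_pressure - base_sc$icp) /
      (constants$sinus_pressure - base_sc$icp)
    r_cuf <- switch(cuff_response,
                    "tmp-scaled" = r_cuf_base * tmp_ratio,
                    "unchanged" = r_cuf_base)
    sc <- chain_scenario(
      name = paste0(scenario, "_sensitivity"), icp = base_sc$icp,
      arterial_pressure = base_sc$arterial_pressure,
      prescribed_flow = base$flow,
      arterial_policy = "solve-residually",
      cuff_policy = "multiplier-of-normal",
      cuff_multiplier = r_cuf / normal_resistances(pc)[["cuff"]],
      reference_state = paste0(scenario, "_sensitivity"))
    st <- solve_chain(sc, pc, control = control, catalogue = catalogue)
    data.frame(scenario = scenario, draw = i,
               target_field = spec$target_field,
               perturbed_value = pc[[spec$target_field]],
               capillary_tmp_mmHg = st$capillary_tmp,
               capillary_tmp_change_pct =
                 100 * (st$capillary_tmp - base$capillary_tmp) / base$capillary_tmp,
               cuff_policy = paste0(cuff_response, " (policy-dependent)"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Regression checks against the published reference values
#'
#' Recomputes every reference quantity of the model — the analytic
#' (Davson/Starling/regional/correction) arithmetic and the solved scenario
#' states — and compares each with its published value at the model's
#' reporting precision (one decimal mmHg, whole percent). Failures are data,
#' not exceptions: policy-dependent or unreproduced values simply show
#' `pass = FALSE`.
#'
#' @param catalogue Scenario catalogue; an empty catalogue yields an empty
#'   check table.
#' @param constants,control Passed to [solve_chain()].
#' @return A `data.frame` with columns `check`, `type`, `computed`,
#'   `reference`, `tolerance`, `pass`.
#' @export
#' @examples
#' checks <- reference_checks()
#' subset(checks, !pass)  # the mid-ICP prose value is not reproduced
reference_checks <- function(catalogue = scenario_catalogue(),
                             constants = normal_baseline(),
                             control = chain_control()) {
  cols <- c("check", "type", "computed", "reference", "tolerance", "pass")
  empty <- data.frame(check = character(0), type = character(0),
                      computed = numeric(0), reference = numeric(0),
                      tolerance = numeric(0), pass = logical(0),
                      stringsAsFactors = FALSE)
  if (length(catalogue) == 0L) return(empty)
  rows <- list()
  add <- function(check, type, computed, reference, tolerance, digits) {
    reported <- round(computed, digits)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, type = type, computed = reported, reference = reference,
      tolerance = tolerance, pass = abs(reported - reference) <= tolerance + 1e-9,
      stringsAsFactors = FALSE)
  }

  # analytic arithmetic (exact up to printed rounding)
  add("grey-matter CBF reduction (%)", "analytic",
      100 * regional_grey_reduction(0.65, 0.35, 1.7, 0.20, 0.40), 13.7, 0.05, 1)
  add("Davson median ICP (mmHg)", "analytic", davson_icp(0.48, 12.36, 4.91),
      10.8, 0.05, 1)
  add("NPH R_out, low formation rate (mmHg/mL/min)", "analytic",
      davson_rout(13, 0.25, 7.5), 22, 0.05, 1)
  add("corrected infusion R_out (mmHg/mL/min)", "analytic",
      corrected_rout(17.3, 1.0, 0.21), 14.3, 0.05, 1)
  add("infusion overestimation, formation-corrected (%)", "analytic",
      overestimation_percent(17.6, corrected_rout(17.3, 1.0, 0.21)), 23, 0.5, 0)
  add("infusion overestimation, constant-flow vs bolus (%)", "analytic",
      overestimation_percent(13, 9.8), 33, 0.5, 0)
  add("Starling net driving pressure (mmHg)", "analytic",
      starling_flux(1, 12, 1, 25), -13, 0.05, 1)

  # solved model states (paper-scale rounding; +-0.1 mmHg / +-1 pp)
  solved <- function(nm) solve_chain(catalogue[[nm]], constants,
                                     control = control, catalogue = catalogue)
  nph <- solved("nph_baseline")
  pct <- function(st) 100 * (st$capillary_tmp - nph$capillary_tmp) / nph$capillary_tmp
  add("NPH baseline capillary TMP (mmHg)", "model", nph$capillary_tmp, 12.2, 0.1, 1)
  add("restored-CBF capillary TMP change (%)", "model", pct(solved("cbf_restore")),
      28, 1, 0)
  add("-40% CBF capillary TMP change (%)", "model", pct(solved("cbf_minus40")),
      -34, 1, 0)
  m57 <- solved("cbf_minus57")
  add("-57% CBF venous TMP (mmHg)", "model", m57$venous_tmp, 0.1, 0.1, 1)
  add("-57% CBF capillary TMP (mmHg)", "model", m57$capillary_tmp, 4.4, 0.1, 1)
  add("infusion capillary TMP change (%)", "model", pct(solved("infusion")), 26, 1, 0)
  drn <- solved("drainage")
  add("drainage flow change (%)", "model", 100 * (drn$flow - nph$flow) / nph$flow,
      14.5, 1, 1)
  add("drainage capillary TMP change (%)", "model", pct(drn), 24, 1, 0)
  add("mid-ICP capillary TMP (mmHg)", "model", solved("mid_icp")$capillary_tmp,
      13, 0.1, 1)

  # policy-dependent report (cuff response to a changed sinus pressure is
  # unconstrained by the calibration data): shown, not asserted elsewhere
  sens <- sensitivity_report(constants = constants, control = control)
  add("sinus -10% capillary TMP change, policy-dependent (%)", "policy-dependent",
      sens$capillary_tmp_change_pct[1], 7, 1, 0)

  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[, cols]
}
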