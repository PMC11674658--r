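#' Define a chain scenario
#'
#' A named set of prescriptions that closes the steady-state chain: the ICP
#' and arterial boundary pressure, and for each of {flow, arterial
#' resistance, outflow-cuff resistance} either a prescribed value/policy or
#' `solve-residually`. Exactly one of the three may be left residual; when
#' all three are prescribed the capillary resistance is the residual closing
#' the pressure balance (see [solve_chain()]).
#'
#' @param name Scenario label.
#' @param icp Intracranial pressure, mmHg (>= 0; zero means full drainage).
#' @param arterial_pressure Arterial inflow boundary pressure, mmHg.
#' @param prescribed_flow Blood flow, mL/min, or `NA` to solve flow residually.
#' @param arterial_policy How the arterial resistance is set:
#'   `"multiplier-of-normal"`, `"multiplier-of-nph-baseline"` (relative to the
#'   solved NPH baseline arterial resistance) or `"solve-residually"`.
#' @param arterial_multiplier Multiplier used by the first two arterial
#'   policies.
#' @param cuff_policy How the cuff resistance is set:
#'   `"unchanged-from-reference"` (the reference scenario's cuff),
#'   `"multiplier-of-normal"`, `"zero"` (maximal dilation), `"solve-residually"`,
#'   or `"eq13-literal"` (the literal linear cuff law; reference use only).
#' @param cuff_multiplier Multiplier for `"multiplier-of-normal"`.
#' @param reference_state Name of the scenario against which percent changes
#'   are reported (and from which "unchanged" policies inherit).
#' @return An object of class `chain_scenario`.
#' @seealso [scenario_catalogue()], [solve_chain()]
#' @export
chain_scenario <- function(name, icp,
                           arterial_pressure = 100,
                           prescribed_flow = NA_real_,
                           arterial_policy = c("multiplier-of-normal",
                                               "multiplier-of-nph-baseline",
                                               "solve-residually"),
                           arterial_multiplier = NA_real_,
                           cuff_policy = c("unchanged-from-reference",
                                           "multiplier-of-normal", "zero",
                                           "solve-residually", "eq13-literal"),
                           cuff_multiplier = NA_real_,
                           reference_state = "nph_baseline") {
  arterial_policy <- match.arg(arterial_policy)
  cuff_policy <- match.arg(cuff_policy)
  sc <- structure(list(name = name, icp = icp,
                       arterial_pressure = arterial_pressure,
                       prescribed_flow = prescribed_flow,
                       arterial_policy = arterial_policy,
                       arterial_multiplier = arterial_multiplier,
                       cuff_policy = cuff_policy,
                       cuff_multiplier = cuff_multiplier,
                       reference_state = reference_state),
                  class = "chain_scenario")
  validate_scenario(sc)
  sc
}

#' Validate scenario closure before solving
#'
#' Checks that the scenario determines the system with at most one residual
#' unknown among {flow, arterial resistance, cuff resistance}: zero unknowns
#' close through the capillary residual, one unknown closes through the
#' capillary compliance law. More than one unknown (or a policy missing its
#' multiplier) is a configuration error.
#'
#' @param sc A `chain_scenario`.
#' @return `sc` invisibly.
#' @export
validate_scenario <- function(sc) {
  if (!is.numeric(sc$icp) || sc$icp < 0) stop("icp must be >= 0", call. = FALSE)
  if (!is.numeric(sc$arterial_pressure) || sc$arterial_pressure <= 0)
    stop("arterial_pressure must be > 0", call. = FALSE)
  if (!is.na(sc$prescribed_flow) && sc$prescribed_flow < 0)
    stop("prescribed_flow must be >= 0", call. = FALSE)
  unknowns <- c(flow = is.na(sc$prescribed_flow),
                arterial = sc$arterial_policy == "solve-residually",
                cuff = sc$cuff_policy == "solve-residually")
  if (sum(unknowns) > 1L)
    stop("scenario '", sc$name, "' is under-determined: ",
         paste(names(unknowns)[unknowns], collapse = ", "),
         " cannot all be solved residually", call. = FALSE)
  if (sc$arterial_policy != "solve-residually" && is.na(sc$arterial_multiplier))
    stop("arterial_multiplier required for policy '", sc$arterial_policy, "'",
         call. = FALSE)
  if (sc$cuff_policy == "multiplier-of-normal" && is.na(sc$cuff_multiplier))
    stop("cuff_multiplier required for policy 'multiplier-of-normal'", call. = FALSE)
  invisible(sc)
}

#' @export
print.chain_scenario <- function(x, ...) {
  cat(sprintf("Chain scenario '%s': ICP %g mmHg, arterial pressure %g mmHg\n",
              x$name, x$icp, x$arterial_pressure))
  cat(sprintf("  flow: %s\n",
              if (is.na(x$prescribed_flow)) "solve residually"
              else paste0(x$prescribed_flow, " mL/min")))
  cat(sprintf("  arterial resistance: %s%s\n", x$arterial_policy,
              if (is.na(x$arterial_multiplier)) ""
              else sprintf(" (x%g)", x$arterial_multiplier)))
  cat(sprintf("  cuff resistance: %s%s\n", x$cuff_policy,
              if (is.na(x$cuff_multiplier)) "" else sprintf(" (x%g)", x$cuff_multiplier)))
  cat(sprintf("  percent changes reported against '%s'\n", x$reference_state))
  invisible(x)
}

#' Catalogue of the study scenarios
#'
#' The named scenarios of the NPH modelling study:
#' \describe{
#'   \item{normal}{the normal baseline (flow 750 mL/min, ICP 11.5 mmHg).}
#'   \item{nph_baseline}{NPH at rest: flow reduced 20% to 600 mL/min, ICP
#'     13 mmHg, arterial resistance x1.25 of normal, cuff resistance x2 of
#'     normal (the combination that leaves total blood volume normal).}
#'   \item{cbf_restore}{instantaneous return of flow to 750 mL/min at ICP 13,
#'     cuff unchanged from the NPH baseline, arterial resistance solved.}
#'   \item{cbf_minus40}{flow cut to 450 mL/min by raising the arterial
#'     resistance 45% above the NPH baseline, cuff unchanged.}
#'   \item{cbf_minus57}{profound ischemia, flow 322.5 mL/min (57% below
#'     normal), cuff unchanged, arterial resistance solved.}
#'   \item{infusion}{constant-rate infusion study: ICP raised 17 mmHg to 30,
#'     arterial pressure up 8 mmHg to 108, flow 525 mL/min, arterial
#'     resistance 3.9% below the NPH baseline, cuff solved residually.}
#'   \item{drainage}{CSF drainage to ICP 0: cuff fully dilated (zero
#'     resistance), arterial resistance held at the NPH baseline, flow solved.}
#'   \item{mid_icp}{ICP midway at 21.5 mmHg, arterial pressure 104 mmHg, flow
#'     563 mL/min, cuff solved residually as in the infusion scenario.}
#'   \item{cortex}{regional grey-matter variant: flow reduced 13.7% below
#'     normal at ICP 13.}
#'   \item{white_matter}{regional white-matter variant: flow reduced 40%
#'     below normal at ICP 13.}
#' }
#'
#' @return Named list of [chain_scenario()] objects.
#' @export
#' @examples
#' names(scenario_catalogue())
scenario_catalogue <- function() {
  scs <- list(
    chain_scenario("normal", icp = 11.5, prescribed_flow = 750,
                   arterial_policy = "multiplier-of-normal", arterial_multiplier = 1,
                   cuff_policy = "multiplier-of-normal", cuff_multiplier = 1,
                   reference_state = "normal"),
    chain_scenario("nph_baseline", icp = 13, prescribed_flow = 600,
                   arterial_policy = "multiplier-of-normal", arterial_multiplier = 1.25,
                   cuff_policy = "multiplier-of-normal", cuff_multiplier = 2,
                   reference_state = "normal"),
    chain_scenario("cbf_restore", icp = 13, prescribed_flow = 750,
                   arterial_policy = "solve-residually",
                   cuff_policy = "unchanged-from-reference"),
    chain_scenario("cbf_minus40", icp = 13, prescribed_flow = 450,
                   arterial_policy = "multiplier-of-nph-baseline",
                   arterial_multiplier = 1.45,
                   cuff_policy = "unchanged-from-reference"),
    chain_scenario("cbf_minus57", icp = 13, prescribed_flow = 750 * (1 - 0.57),
                   arterial_policy = "solve-residually",
                   cuff_policy = "unchanged-from-reference"),
    chain_scenario("infusion", icp = 30, arterial_pressure = 108,
                   prescribed_flow = 525,
                   arterial_policy = "multiplier-of-nph-baseline",
                   arterial_multiplier = 0.961,
                   cuff_policy = "solve-residually"),
    chain_scenario("drainage", icp = 0, prescribed_flow = NA_real_,
                   arterial_policy = "multiplier-of-nph-baseline",
                   arterial_multiplier = 1,
                   cuff_policy = "zero"),
    chain_scenario("mid_icp", icp = 21.5, arterial_pressure = 104,
                   prescribed_flow = 563,
                   arterial_policy = "multiplier-of-nph-baseline",
                   arterial_multiplier = 1,
                   cuff_policy = "solve-residually"),
    chain_scenario("cortex", icp = 13, prescribed_flow = 750 * (1 - 0.137),
                   arterial_policy = "solve-residually",
                   cuff_policy = "unchanged-from-reference"),
    chain_scenario("white_matter", icp = 13, prescribed_flow = 750 * (1 - 0.40),
                   arterial_policy = "solve-residually",
                   cuff_policy = "unchanged-from-reference")
  )
  stats::setNames(scs, vapply(scs, `[[`, character(1), "name"))
}

scenario_fields <- c("name", "icp", "arterial_pressure", "prescribed_flow",
                     "arterial_policy", "arterial_multiplier", "cuff_policy",
                     "cuff_multiplier", "reference_state")

#' Serialize scenarios to a YAML document
#'
#' One mapping per scenario, keyed by the scenario fields; a `units` block in
#' the header fixes the conventions (mmHg, mL, mL/min). `NA` fields (unused
#' multipliers, residual flow) are dropped on write and restored on read.
#'
#' @param scenarios A list of `chain_scenario` objects (e.g.
#'   [scenario_catalogue()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  if (inherits(scenarios, "chain_scenario")) scenarios <- list(scenarios)
  docs <- lapply(scenarios, function(sc) {
    x <- unclass(sc)[scenario_fields]
    x[!vapply(x, function(v) length(v) == 1L && is.na(v), logical(1))]
  })
  names(docs) <- vapply(scenarios, `[[`, character(1), "name")
  yaml::write_yaml(
    list(units = list(pressure = "mmHg", flow = "mL/min", volume = "mL",
                      resistance = "mmHg.min/mL"),
         scenarios = docs),
    path)
  invisible(path)
}

#' Read scenarios from a YAML document written by [write_scenarios()]
#'
#' @param path YAML file path.
#' @return Named list of validated `chain_scenario` objects.
#' @export
read_scenarios <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$scenarios)) stop("no 'scenarios' block in ", path, call. = FALSE)
  out <- lapply(doc$scenarios, function(x) do.call(chain_scenario, x))
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}
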