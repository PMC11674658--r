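#' Poiseuille resistance scaling with segment volume
#'
#' For a cylindrical vessel of fixed length, resistance scales as radius^-4
#' and volume as radius^2, so resistance scales with the volume ratio to the
#' power -2. Multiplying a segment's normal resistance by this factor gives
#' its resistance at the new volume.
#'
#' @param volume_ratio Volume relative to the reference volume (> 0).
#' @return `volume_ratio^-2`, dimensionless.
#' @export
#' @examples
#' resistance_scale_from_volume(0.5)  # halving volume quadruples resistance
resistance_scale_from_volume <- function(volume_ratio) {
  if (any(!is.finite(volume_ratio)) || any(volume_ratio <= 0))
    stop("volume_ratio must be strictly positive", call. = FALSE)
  volume_ratio^-2
}

#' Normal per-segment resistances
#'
#' Derives the normal resistance of each chain segment from the baseline
#' boundary pressures and flow (Ohm's law per segment): pressure drop across
#' the segment divided by the cerebral blood flow.
#'
#' @param constants A `physio_constants` object.
#' @return Named numeric vector (`artery`, `capillary`, `vein`, `cuff`) in
#'   mmHg.min/mL. The four values sum exactly to the total resistance
#'   (arterial inflow minus sinus pressure over flow).
#' @export
#' @examples
#' normal_resistances(normal_baseline())
normal_resistances <- function(constants = normal_baseline()) {
  validate_constants(constants)
  q <- constants$cbf
  c(artery = (constants$arterial_inflow_pressure - constants$precapillary_pressure) / q,
    capillary = (constants$precapillary_pressure - constants$postcapillary_pressure) / q,
    vein = (constants$postcapillary_pressure - constants$precuff_pressure) / q,
    cuff = (constants$precuff_pressure - constants$sinus_pressure) / q)
}

#' Mean transmural pressure of a segment
#'
#' Midpoint convention: the average of the inlet and outlet pressures minus
#' the external (CSF) pressure. With the normal boundary pressures this gives
#' the normal mean capillary transmural pressure of 12 mmHg
#' ((32 + 15)/2 - 11.5).
#'
#' @param inlet,outlet Segment inlet and outlet pressures, mmHg.
#' @param external External (surrounding CSF) pressure, mmHg.
#' @return Mean transmural pressure, mmHg.
#' @export
mean_transmural_pressure <- function(inlet, outlet, external) {
  (inlet + outlet) / 2 - external
}

#' Thin-walled vessel transmural pressure
#'
#' Elastic thin-wall relation between the transmural pressure and the loaded
#' cross-sectional area: `(4*E*h / (3*R_o)) * (1 - A_o/A)`. Provided as a
#' utility; the empirical response laws in [capillary_volume_from_tmp()] and
#' [venous_tmp_change_from_volume()] supersede it for the chain scenarios.
#'
#' @param E Young's modulus of the wall.
#' @param h Wall thickness.
#' @param R_o Radius in the stress-free state.
#' @param A_o Cross-sectional area in the stress-free state.
#' @param A Loaded cross-sectional area (> 0).
#' @return Transmural pressure in the units of `E`.
#' @export
#' @examples
#' thin_wall_tmp(1e5, 0.01, 0.1, 1, 1)  # stress-free state: 0
thin_wall_tmp <- function(E, h, R_o, A_o, A) {
  if (any(c(E, h, R_o, A_o) <= 0)) stop("E, h, R_o, A_o must be > 0", call. = FALSE)
  if (any(A <= 0)) stop("loaded area A must be > 0", call. = FALSE)
  (4 * E * h / (3 * R_o)) * (1 - A_o / A)
}

# Internal constructor for a solved chain state. Validates the series
# invariants: single flow through all segments (by construction), pressure
# drops additive to the boundary drop within `tol` relative, monotone
# non-increasing pressures for positive flow, cuff TMP = sinus - ICP.
# `segments` is a data.frame(name, inlet_pressure, outlet_pressure,
# resistance, volume, tmp) ordered artery -> capillary -> vein -> cuff.
new_chain_state <- function(flow, icp, sinus_pressure, segments,
                            capillary_tmp, venous_tmp,
                            scenario_name = NA_character_,
                            reference = NULL, percent_changes = NULL,
                            report = NULL, tol = 1e-9) {
  stopifnot(is.data.frame(segments),
            identical(segments$name, c("artery", "capillary", "vein", "cuff")))
  drops <- segments$inlet_pressure - segments$outlet_pressure
  boundary <- segments$inlet_pressure[1L] - sinus_pressure
  if (flow > 0) {
    finite <- is.finite(segments$resistance)
    ohm <- abs(drops[finite] - flow * segments$resistance[finite])
    if (any(ohm > tol * max(1, boundary)))
      stop("segment pressure drops inconsistent with flow x resistance", call. = FALSE)
    if (abs(sum(drops) - boundary) > tol * max(1, abs(boundary)))
      stop("series additivity violated: segment drops do not sum to the boundary drop",
           call. = FALSE)
    p <- c(segments$inlet_pressure[1L], segments$outlet_pressure)
    if (any(diff(p) > tol))
      stop("pressures must be non-increasing along the chain for positive flow",
           call. = FALSE)
  }
  state <- list(
    flow = flow,
    icp = icp,
    sinus_pressure = sinus_pressure,
    segments = segments,
    capillary_tmp = capillary_tmp,
    venous_tmp = venous_tmp,
    cuff_tmp = sinus_pressure - icp,
    scenario = scenario_name,
    reference = reference,
    percent_changes = percent_changes,
    report = report
  )
  class(state) <- "chain_state"
  state
}

#' Export a solved chain state as a per-segment table
#'
#' One row per segment (artery, capillary, vein, cuff) with inlet/outlet
#' pressures, resistance, volume (NA for the cuff, whose volume is not
#' tracked) and transmural pressure, plus the scenario label.
#'
#' @param x A `chain_state`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A `data.frame`.
#' @export
as.data.frame.chain_state <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- cbind(scenario = x$scenario, x$segments)
  rownames(out) <- NULL
  out
}

#' Write a chain state to CSV (per-segment) and JSON (summary)
#'
#' The CSV holds one row per segment (see [as.data.frame.chain_state()]); the
#' JSON twin carries the full-precision summary: flow, ICP, sinus pressure,
#' capillary/venous/cuff transmural pressures and any percent changes
#' against the scenario's reference state.
#'
#' @param state A `chain_state`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @param timestamp Logical; prepend a `#`-comment header with the write time
#'   to the CSV (the numerical payload is unaffected).
#' @return Invisibly, the summary list written to JSON.
#' @export
write_chain_state <- function(state, csv_path = NULL, json_path = NULL,
                              timestamp = FALSE) {
  stopifnot(inherits(state, "chain_state"))
  if (!is.null(csv_path)) {
    con <- file(csv_path, "w")
    on.exit(close(con), add = TRUE)
    if (timestamp) writeLines(sprintf("# generated: %s", format(Sys.time())), con)
    utils::write.csv(as.data.frame(state), con, row.names = FALSE)
  }
  summ <- chain_summary_list(state)
  if (!is.null(json_path))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(summ)
}

chain_summary_list <- function(state) {
  list(
    scenario = state$scenario,
    flow = state$flow,
    icp = state$icp,
    sinus_pressure = state$sinus_pressure,
    capillary_tmp = state$capillary_tmp,
    venous_tmp = state$venous_tmp,
    cuff_tmp = state$cuff_tmp,
    venous_volume_change_pct = state$report$venous_volume_change_pct,
    percent_changes = state$percent_changes,
    converged = state$report$converged,
    iterations = state$report$iterations,
    residual = state$report$residual,
    closure = state$report$closure,
    saturation_flags = state$report$saturation_flags,
    notes = state$report$notes
  )
}
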