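#' Capillary compliance law
#'
#' The capillary bed is a passive conduit: between a transmural-pressure (TMP)
#' floor and the elastic limit its volume rises linearly with TMP (1.7% of
#' the base volume per mmHg). Below the floor the volume stays at the base
#' value; at and above the ceiling it is pinned at the maximally dilated
#' volume.
#'
#' @param base_volume Volume at or below the TMP floor, mL.
#' @param elastic_volume Maximally dilated volume, mL.
#' @param tmp_floor,tmp_ceiling TMP below which volume is unchanged and at
#'   which the elastic limit is reached, mmHg.
#' @param slope Fractional volume increase per mmHg of TMP.
#' @return An object of class `capillary_law`.
#' @export
capillary_law <- function(base_volume = 20.3, elastic_volume = 29.2,
                          tmp_floor = 12, tmp_ceiling = 37.9, slope = 0.017) {
  implied <- base_volume * (1 + slope * (tmp_ceiling - tmp_floor))
  if (abs(implied - elastic_volume) / elastic_volume > 0.002)
    stop("inconsistent capillary law: slope does not connect base to elastic volume",
         call. = FALSE)
  structure(list(base_volume = base_volume, elastic_volume = elastic_volume,
                 tmp_floor = tmp_floor, tmp_ceiling = tmp_ceiling, slope = slope),
            class = "capillary_law")
}

#' Capillary volume at a given transmural pressure
#'
#' Piecewise-linear, continuous and non-decreasing: clamped at the base
#' volume below the TMP floor and at the elastic-limit volume above the
#' ceiling.
#'
#' @param tmp Mean capillary transmural pressure, mmHg (vectorised).
#' @param law A [capillary_law()].
#' @return Capillary volume, mL, in `[base_volume, elastic_volume]`.
#' @export
#' @examples
#' capillary_volume_from_tmp(c(5, 12, 24.95, 37.9))
capillary_volume_from_tmp <- function(tmp, law = capillary_law()) {
  v <- law$base_volume * (1 + law$slope * pmax(0, tmp - law$tmp_floor))
  pmin(v, law$elastic_volume)
}

# Capillary resistance from the compliance law: normal resistance scaled by
# the volume ratio to the power -2.
capillary_resistance_from_tmp <- function(tmp, normal_resistance,
                                          law = capillary_law()) {
  ratio <- capillary_volume_from_tmp(tmp, law) / law$base_volume
  normal_resistance * resistance_scale_from_volume(ratio)
}

#' Venous transmural-pressure/volume law
#'
#' Quadratic relation between the normalised change in venous transmural
#' pressure and the normalised change in venous volume, both expressed as
#' percent change from the normal state (venous TMP 2.5 mmHg, venous volume
#' 17.9 mL):
#' `dTMP = -0.033 dV^2 + 7.49 dV - 3.44` (percent units on both sides).
#' The quadratic peaks at dV ~ 113.5% (dTMP ~ 421.6%); beyond that vertex
#' the law saturates and no further dilation can raise the venous TMP.
#'
#' @param coefficients Quadratic, linear and constant coefficients.
#' @param normal_tmp Normal venous transmural pressure, mmHg.
#' @param normal_volume Normal venous volume, mL.
#' @return An object of class `venous_law` with the vertex location
#'   (`dv_vertex`, percent) and maximum (`dtmp_max`, percent) precomputed.
#' @export
venous_law <- function(coefficients = c(-0.033, 7.49, -3.44),
                       normal_tmp = 2.5, normal_volume = 17.9) {
  stopifnot(length(coefficients) == 3, coefficients[1] < 0)
  a <- coefficients[1]; b <- coefficients[2]; cc <- coefficients[3]
  dv_vertex <- -b / (2 * a)
  dtmp_max <- a * dv_vertex^2 + b * dv_vertex + cc
  structure(list(coefficients = coefficients, normal_tmp = normal_tmp,
                 normal_volume = normal_volume, dv_vertex = dv_vertex,
                 dtmp_max = dtmp_max),
            class = "venous_law")
}

#' Venous TMP change from a venous volume change (forward law)
#'
#' @param dv_percent Venous volume change, percent of the normal venous
#'   volume (vectorised). Must not exceed the vertex of the quadratic
#'   (~113.5%), beyond which the law saturates.
#' @param law A [venous_law()].
#' @return Venous TMP change, percent of the normal venous TMP.
#' @export
#' @examples
#' venous_tmp_change_from_volume(0)   # -3.44
#' venous_tmp_change_from_volume(32)  # ~202.4
venous_tmp_change_from_volume <- function(dv_percent, law = venous_law()) {
  if (any(dv_percent > law$dv_vertex + 1e-12))
    stop(sprintf(
      "venous volume change %.4g%% exceeds the elastic limit of the venous law (vertex %.4g%%)",
      max(dv_percent), law$dv_vertex), call. = FALSE)
  a <- law$coefficients
  a[1] * dv_percent^2 + a[2] * dv_percent + a[3]
}

#' Venous volume change from a venous TMP change (inverse law)
#'
#' Inverts the quadratic venous law on its proximal physical branch: the
#' smaller real root, continuous with zero volume change at the operating
#' point (the larger root, beyond 200% dilation, is unphysical). Negative
#' roots (vein constriction) are permitted. A requested TMP change above the
#' quadratic's maximum raises a saturation error (condition class
#' `cvchain_saturation_error`) rather than clamping, so a non-physical solver
#' excursion is loud.
#'
#' @param dtmp_percent Venous TMP change, percent of the normal venous TMP
#'   (vectorised).
#' @param law A [venous_law()].
#' @return Venous volume change, percent of the normal venous volume.
#' @export
#' @examples
#' venous_volume_change_from_tmp(96)   # ~14.2 (dilation)
#' venous_volume_change_from_tmp(-96)  # ~-11.8 (constriction)
venous_volume_change_from_tmp <- function(dtmp_percent, law = venous_law()) {
  if (any(dtmp_percent > law$dtmp_max + 1e-9))
    stop(structure(class = c("cvchain_saturation_error", "error", "condition"),
                   list(message = sprintf(
      "venous TMP change %.4g%% exceeds the maximum %.4g%% attainable at the elastic limit (vein volume +%.4g%%)",
      max(dtmp_percent), law$dtmp_max, law$dv_vertex), call = NULL)))
  a <- law$coefficients[1]; b <- law$coefficients[2]
  cc <- law$coefficients[3] - dtmp_percent
  # a x^2 + b x + (c - dtmp) = 0 with a < 0; proximal branch is the smaller root
  disc <- pmax(0, b^2 - 4 * a * cc)
  (-b + sqrt(disc)) / (2 * a)
}

#' Venous outflow cuff resistance law
#'
#' The short collapsible segment where cortical veins enter the sagittal
#' sinus behaves as a Starling resistor governed by its transmural pressure
#' (sinus pressure minus ICP, usually negative). Three modes are provided:
#' `literal` evaluates the printed linear relation
#' `R = -2.71 * TMP + 0.008`, clamped at zero for positive TMP (maximal
#' dilation); `scaled` multiplies the literal value by `scale_factor`;
#' `policy-driven` (the default for scenario closure) returns the
#' scenario-prescribed resistance. The literal relation's units cannot be
#' reconciled with the chain-derived normal cuff resistance, so it is kept
#' for reference only and never closes the catalogue scenarios.
#'
#' @param coefficients Slope and intercept of the linear relation.
#' @param mode `"policy-driven"`, `"literal"` or `"scaled"`.
#' @param scale_factor Multiplier applied in `scaled` mode.
#' @return An object of class `cuff_law`.
#' @export
cuff_law <- function(coefficients = c(-2.71, 0.008),
                     mode = c("policy-driven", "literal", "scaled"),
                     scale_factor = 1) {
  mode <- match.arg(mode)
  structure(list(coefficients = coefficients, mode = mode,
                 scale_factor = scale_factor),
            class = "cuff_law")
}

#' Evaluate the cuff resistance law
#'
#' @param tmp_cuf Cuff transmural pressure (sinus pressure minus ICP), mmHg.
#' @param law A [cuff_law()]; its `mode` selects the behaviour.
#' @param reference_resistance The scenario-prescribed resistance returned in
#'   `policy-driven` mode (mmHg.min/mL).
#' @return Cuff resistance, never negative.
#' @export
#' @examples
#' cuff_resistance(0, cuff_law(mode = "literal"))    # 0.008
#' cuff_resistance(7.5, cuff_law(mode = "literal"))  # clamped at 0
cuff_resistance <- function(tmp_cuf, law = cuff_law(), reference_resistance = NULL) {
  val <- switch(law$mode,
    "literal" = law$coefficients[1] * tmp_cuf + law$coefficients[2],
    "scaled" = law$scale_factor * (law$coefficients[1] * tmp_cuf + law$coefficients[2]),
    "policy-driven" = {
      if (is.null(reference_resistance))
        stop("policy-driven cuff mode needs the scenario-prescribed resistance",
             call. = FALSE)
      reference_resistance
    })
  pmax(0, val)
}

#' Default response laws of the chain
#'
#' Convenience bundle of the three vessel response laws at their calibrated
#' values; pass a modified bundle to [solve_chain()] to override coefficients
#' or clamps.
#'
#' @return A list with elements `capillary`, `venous`, `cuff`.
#' @export
chain_laws <- function() {
  list(capillary = capillary_law(), venous = venous_law(), cuff = cuff_law())
}
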