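#' Physiological constants of the cerebral vascular chain
#'
#' Bundle of the pressures, flows and compartment volumes that define the
#' normal adult baseline of the model. All pressures are in mmHg, flows in
#' mL/min and volumes in mL; resistances derived from these are in
#' mmHg.min/mL. The defaults are the normal middle-aged values used to
#' calibrate the chain: arterial inflow 100 mmHg, pre-capillary 32 mmHg,
#' post-capillary 15 mmHg, pre-cuff 14 mmHg, superior sagittal sinus 7.5 mmHg,
#' CSF pressure (ICP) 11.5 mmHg, cerebral blood flow 750 mL/min, and
#' compartment volumes 12.8 / 20.3 / 17.9 mL (arterial / capillary / venous).
#'
#' @param arterial_inflow_pressure Arterial inflow (boundary) pressure, mmHg.
#' @param precapillary_pressure Pressure at the capillary inlet, mmHg.
#' @param postcapillary_pressure Pressure at the capillary outlet, mmHg.
#' @param precuff_pressure Pressure just upstream of the venous outflow cuff, mmHg.
#' @param sinus_pressure Superior sagittal sinus pressure, mmHg.
#' @param icp Intracranial (CSF) pressure, mmHg; the external pressure seen by
#'   the capillaries, veins and cuff.
#' @param cbf Cerebral blood flow, mL/min.
#' @param volume_arterial Arterial blood volume, mL.
#' @param volume_capillary Capillary blood volume, mL (53% of the
#'   non-arterial cerebral blood volume).
#' @param volume_venous Venous blood volume, mL.
#' @param normal_venous_tmp Normal transmural pressure of the subarachnoid
#'   cortical veins, mmHg (primate value, anchors the venous response law).
#' @param normal_csf_formation Normal CSF formation rate, mL/min.
#'
#' @return An object of class `physio_constants` (a validated named list).
#' @seealso [normal_baseline()], [normal_resistances()], [perturb()]
#' @export
#' @examples
#' pc <- physio_constants()
#' pc$cbf
physio_constants <- function(arterial_inflow_pressure = 100,
                             precapillary_pressure = 32,
                             postcapillary_pressure = 15,
                             precuff_pressure = 14,
                             sinus_pressure = 7.5,
                             icp = 11.5,
                             cbf = 750,
                             volume_arterial = 12.8,
                             volume_capillary = 20.3,
                             volume_venous = 17.9,
                             normal_venous_tmp = 2.5,
                             normal_csf_formation = 0.40) {
  x <- list(
    arterial_inflow_pressure = arterial_inflow_pressure,
    precapillary_pressure = precapillary_pressure,
    postcapillary_pressure = postcapillary_pressure,
    precuff_pressure = precuff_pressure,
    sinus_pressure = sinus_pressure,
    icp = icp,
    cbf = cbf,
    volume_arterial = volume_arterial,
    volume_capillary = volume_capillary,
    volume_venous = volume_venous,
    normal_venous_tmp = normal_venous_tmp,
    normal_csf_formation = normal_csf_formation
  )
  class(x) <- "physio_constants"
  validate_constants(x)
  x
}

#' Normal physiological baseline
#'
#' The unmodified normal adult state of the model: all constants at their
#' default values (see [physio_constants()]).
#'
#' @return A `physio_constants` object.
#' @export
#' @examples
#' normal_baseline()$icp
normal_baseline <- function() physio_constants()

#' Validate a set of physiological constants
#'
#' Checks the strict pressure ordering along the chain (arterial inflow >
#' pre-capillary > post-capillary > pre-cuff > sinus, required for positive
#' antegrade flow) and strict positivity of every quantity except the ICP,
#' which may be zero (external drainage). Errors name the violated constraint.
#'
#' @param x A `physio_constants` object (or plain named list with the same fields).
#' @return `x`, invisibly, if valid.
#' @export
validate_constants <- function(x) {
  req <- c("arterial_inflow_pressure", "precapillary_pressure",
           "postcapillary_pressure", "precuff_pressure", "sinus_pressure",
           "icp", "cbf", "volume_arterial", "volume_capillary",
           "volume_venous", "normal_venous_tmp", "normal_csf_formation")
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop("physio_constants is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- vapply(x[req], function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num))
    stop("physio_constants fields must be finite scalars: ",
         paste(req[!num], collapse = ", "), call. = FALSE)
  ord <- c("arterial_inflow_pressure", "precapillary_pressure",
           "postcapillary_pressure", "precuff_pressure", "sinus_pressure")
  v <- unlist(x[ord])
  if (any(diff(v) >= 0)) {
    i <- which(diff(v) >= 0)[1L]
    stop(sprintf(
      "pressure ordering violated: %s (%.4g mmHg) must exceed %s (%.4g mmHg)",
      ord[i], v[i], ord[i + 1L], v[i + 1L]), call. = FALSE)
  }
  pos <- setdiff(req, "icp")
  bad <- pos[unlist(x[pos]) <= 0]
  if (length(bad))
    stop("fields must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (x$icp < 0) stop("icp must be >= 0", call. = FALSE)
  invisible(x)
}

#' @export
print.physio_constants <- function(x, ...) {
  cat("Physiological constants (mmHg, mL, mL/min)\n")
  cat(sprintf("  pressures: arterial %g > precap %g > postcap %g > precuff %g > sinus %g; ICP %g\n",
              x$arterial_inflow_pressure, x$precapillary_pressure,
              x$postcapillary_pressure, x$precuff_pressure, x$sinus_pressure,
              x$icp))
  cat(sprintf("  CBF %g mL/min; volumes art/cap/ven %g/%g/%g mL\n",
              x$cbf, x$volume_arterial, x$volume_capillary, x$volume_venous))
  cat(sprintf("  normal venous TMP %g mmHg; CSF formation %g mL/min\n",
              x$normal_venous_tmp, x$normal_csf_formation))
  invisible(x)
}
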