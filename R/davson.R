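#' Davson's equation: steady-state ICP
#'
#' `ICP = CSF_fr x R_out + P_sss`: at steady state the intracranial pressure
#' equals the CSF formation rate times the CSF outflow resistance plus the
#' sagittal sinus pressure.
#'
#' @param csf_formation CSF formation rate, mL/min (> 0).
#' @param r_out CSF outflow resistance, mmHg/mL/min (>= 0).
#' @param sinus_pressure Sinus (reference) pressure, mmHg.
#' @return ICP, mmHg.
#' @export
#' @examples
#' davson_icp(0.40, 10, 7.5)  # 11.5 mmHg, the normal state
davson_icp <- function(csf_formation, r_out, sinus_pressure) {
  csf_formation * r_out + sinus_pressure
}

#' Davson's equation rearranged: CSF outflow resistance
#'
#' @param icp Intracranial pressure, mmHg.
#' @param csf_formation CSF formation rate, mL/min (> 0).
#' @param sinus_pressure Sinus (reference) pressure, mmHg.
#' @return `(icp - sinus_pressure) / csf_formation`, mmHg/mL/min.
#' @export
#' @examples
#' davson_rout(13, 0.25, 7.5)  # 22: NPH with a low formation-rate estimate
davson_rout <- function(icp, csf_formation, sinus_pressure) {
  if (any(csf_formation <= 0))
    stop("csf_formation must be > 0", call. = FALSE)
  (icp - sinus_pressure) / csf_formation
}

#' Age regression for the normal CSF outflow resistance
#'
#' Linear regression of normal outflow resistance on age:
#' `R_out = 0.075 x age + 9.88` (mmHg/mL/min).
#'
#' @param age Age in years (>= 0).
#' @return Predicted normal outflow resistance, mmHg/mL/min.
#' @export
#' @examples
#' rout_age_regression(60)  # 14.38
rout_age_regression <- function(age) {
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  0.075 * age + 9.88
}

#' Corrected outflow resistance when CSF formation rises during infusion
#'
#' A constant-rate infusion study computes `R_out = dICP / infusion_rate`,
#' assuming the CSF formation rate is constant. If the formation rate rises
#' by `csf_formation_increase` during the test, that extra inflow must be
#' added to the denominator:
#' `R_out = dICP / (infusion_rate + csf_formation_increase)`.
#'
#' @param icp_rise Steady-state ICP rise during the infusion, mmHg.
#' @param infusion_rate Mock-CSF infusion rate, mL/min.
#' @param csf_formation_increase Rise in the CSF formation rate during the
#'   test, mL/min (0 recovers the uncorrected estimate).
#' @return Corrected outflow resistance, mmHg/mL/min.
#' @export
#' @examples
#' corrected_rout(17.3, 1.0, 0.21)  # ~14.3
corrected_rout <- function(icp_rise, infusion_rate, csf_formation_increase) {
  denom <- infusion_rate + csf_formation_increase
  if (any(denom <= 0))
    stop("infusion_rate + csf_formation_increase must be > 0", call. = FALSE)
  icp_rise / denom
}

#' Percent overestimation of an apparent outflow resistance
#'
#' `100 * (apparent - corrected) / corrected`: by how much an apparent
#' (uncorrected) outflow-resistance estimate exceeds the corrected one, as a
#' percentage of the corrected value.
#'
#' @param apparent Apparent (uncorrected) resistance, mmHg/mL/min.
#' @param corrected Corrected resistance, mmHg/mL/min (> 0).
#' @return Percent overestimation.
#' @export
#' @examples
#' overestimation_percent(13, 9.8)  # ~33
overestimation_percent <- function(apparent, corrected) {
  if (any(corrected <= 0)) stop("corrected must be > 0", call. = FALSE)
  100 * (apparent - corrected) / corrected
}

#' Regional partition of a global CBF reduction between grey and white matter
#'
#' Cerebral blood flow is mass- and perfusion-weighted across grey and white
#' matter: with grey mass fraction `m_g`, white `m_w = 1 - m_g` and a
#' grey:white perfusion ratio `rho`, the grey flow share is
#' `w_g = m_g * rho / (m_g * rho + m_w)`. Given the global fractional flow
#' reduction and the white-matter reduction, the implied grey (cortical)
#' reduction solves `w_g * g + (1 - w_g) * white = global`.
#'
#' @param grey_mass_fraction,white_mass_fraction Brain mass fractions
#'   (must sum to 1).
#' @param grey_white_flow_ratio Grey:white perfusion ratio per unit mass.
#' @param global_reduction Global fractional CBF reduction.
#' @param white_reduction White-matter fractional CBF reduction.
#' @return The grey-matter fractional CBF reduction.
#' @export
#' @examples
#' regional_grey_reduction(0.65, 0.35, 1.7, 0.20, 0.40)  # ~0.137
regional_grey_reduction <- function(grey_mass_fraction = 0.65,
                                    white_mass_fraction = 0.35,
                                    grey_white_flow_ratio = 1.7,
                                    global_reduction,
                                    white_reduction) {
  if (abs(grey_mass_fraction + white_mass_fraction - 1) > 1e-12)
    stop("mass fractions must sum to 1", call. = FALSE)
  w_g <- grey_mass_fraction * grey_white_flow_ratio /
    (grey_mass_fraction * grey_white_flow_ratio + white_mass_fraction)
  if (!is.finite(w_g) || w_g <= 0 || w_g >= 1)
    stop("degenerate flow-share weights", call. = FALSE)
  (global_reduction - (1 - w_g) * white_reduction) / w_g
}

#' Starling flux across the capillary wall
#'
#' `J = L * [TMP - sigma * (pi_cap - pi_CSF)]`: net fluid flux across the
#' capillary barrier, positive for filtration into the interstitium/CSF. With
#' an intact blood-brain barrier the reflection coefficient is 1 and the
#' plasma oncotic gradient (~25 mmHg) dominates the normal capillary TMP
#' (~12 mmHg), so the net driving pressure is negative (absorption); barrier
#' breakdown drives sigma toward 0 and enables pressure-dependent CSF
#' formation. The colloid (salt) osmotic pressures are equal across the
#' barrier and omitted by default; `osmotic_gradient` accepts a combined
#' gradient so breakdown cases can be explored.
#'
#' @param hydraulic_conductivity Capillary hydraulic conductivity (flow per
#'   unit pressure).
#' @param capillary_tmp Mean capillary transmural pressure, mmHg.
#' @param reflection_coefficient Osmotic reflection coefficient, in [0, 1].
#' @param osmotic_gradient Effective osmotic pressure gradient (plasma minus
#'   CSF), mmHg.
#' @return Net flux, in the flow units of `hydraulic_conductivity`.
#' @export
#' @examples
#' starling_flux(1, 12, 1, 25)  # net driving pressure -13 mmHg
starling_flux <- function(hydraulic_conductivity, capillary_tmp,
                          reflection_coefficient, osmotic_gradient) {
  if (any(reflection_coefficient < 0 | reflection_coefficient > 1))
    stop("reflection_coefficient must lie in [0, 1]", call. = FALSE)
  hydraulic_conductivity * (capillary_tmp - reflection_coefficient * osmotic_gradient)
}

#' Infusion-study outflow-resistance correction report
#'
#' Assembles the headline correction: if the CSF formation rate rises during
#' a constant-rate infusion study (because the raised ICP raises the
#' capillary TMP with an open blood-brain barrier), the uncorrected Davson
#' estimate overstates the outflow resistance. The defaults reproduce the
#' NPH infusion correction: apparent R_out 17.6 mmHg/mL/min, ICP rise
#' 17.3 mmHg, nominal rate 1.0 mL/min (the back-calculated rate
#' `icp_rise / apparent_rout` = 0.983 is reported alongside), formation rate
#' rising from 0.25 to 0.46 mL/min.
#'
#' @param apparent_rout Uncorrected (reported) outflow resistance, mmHg/mL/min.
#' @param icp_rise ICP rise during the infusion, mmHg.
#' @param infusion_rate Nominal infusion rate, mL/min.
#' @param csf_fr_before,csf_fr_after CSF formation rate before and during the
#'   test, mL/min.
#' @return A list of class `rout_correction`: inputs echoed, the corrected
#'   resistance, the percent overestimation and the back-calculated rate.
#' @export
#' @examples
#' correction_report()$overestimation_pct  # ~23
correction_report <- function(apparent_rout = 17.6, icp_rise = 17.3,
                              infusion_rate = 1.0, csf_fr_before = 0.25,
                              csf_fr_after = 0.46) {
  increase <- csf_fr_after - csf_fr_before
  corrected <- corrected_rout(icp_rise, infusion_rate, increase)
  structure(list(
    apparent_rout = apparent_rout,
    icp_rise = icp_rise,
    infusion_rate = infusion_rate,
    back_calculated_rate = icp_rise / apparent_rout,
    csf_fr_before = csf_fr_before,
    csf_fr_after = csf_fr_after,
    csf_fr_increase = increase,
    corrected_rout = corrected,
    overestimation_pct = overestimation_percent(apparent_rout, corrected)
  ), class = "rout_correction")
}

#' @export
print.rout_correction <- function(x, ...) {
  cat("CSF outflow-resistance correction for a rising formation rate\n")
  cat(sprintf("  apparent R_out: %.2f mmHg/mL/min (ICP rise %.1f mmHg, nominal rate %.2f mL/min;\n",
              x$apparent_rout, x$icp_rise, x$infusion_rate))
  cat(sprintf("   back-calculated rate %.3f mL/min)\n", x$back_calculated_rate))
  cat(sprintf("  CSF formation: %.2f -> %.2f mL/min (+%.2f)\n",
              x$csf_fr_before, x$csf_fr_after, x$csf_fr_increase))
  cat(sprintf("  corrected R_out: %.2f mmHg/mL/min; overestimated by %.0f%%\n",
              x$corrected_rout, x$overestimation_pct))
  invisible(x)
}
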