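#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("Cerebral chain steady state ('%s')\n", x$scenario))
  cat(sprintf("  flow %.1f mL/min; ICP %.1f mmHg; sinus %.2f mmHg\n",
              x$flow, x$icp, x$sinus_pressure))
  cat(sprintf("  capillary TMP %.1f mmHg; venous TMP %.1f mmHg; cuff TMP %.1f mmHg\n",
              x$capillary_tmp, x$venous_tmp, x$cuff_tmp))
  cat(sprintf("  vein volume change %+.1f%% of normal\n",
              x$report$venous_volume_change_pct))
  if (!is.null(x$percent_changes))
    cat(sprintf("  vs '%s': flow %+.1f%%, capillary TMP %+.0f%%\n",
                x$percent_changes$reference, x$percent_changes$flow,
                x$percent_changes$capillary_tmp))
  cat(sprintf("  closure %s; %d iteration(s), residual %.1e%s\n",
              x$report$closure, x$report$iterations, x$report$residual,
              if (length(x$report$saturation_flags))
                paste0("; flags: ", paste(x$report$saturation_flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Summarise a solved chain state
#'
#' @param object A `chain_state`.
#' @param ... Ignored.
#' @return An object of class `summary.chain_state`: the per-segment table,
#'   transmural pressures, percent changes and the solve report.
#' @export
summary.chain_state <- function(object, ...) {
  structure(list(scenario = object$scenario,
                 segments = as.data.frame(object),
                 flow = object$flow, icp = object$icp,
                 sinus_pressure = object$sinus_pressure,
                 capillary_tmp = object$capillary_tmp,
                 venous_tmp = object$venous_tmp,
                 cuff_tmp = object$cuff_tmp,
                 percent_changes = object$percent_changes,
                 report = object$report),
            class = "summary.chain_state")
}

#' @export
print.summary.chain_state <- function(x, ...) {
  cat(sprintf("Scenario '%s' (closure: %s)\n\n", x$scenario, x$report$closure))
  seg <- x$segments
  seg[, sapply(seg, is.numeric)] <- round(seg[, sapply(seg, is.numeric)], 5)
  print(seg, row.names = FALSE)
  cat(sprintf("\nflow %.2f mL/min; ICP %.1f mmHg; sinus %.2f mmHg\n",
              x$flow, x$icp, x$sinus_pressure))
  cat(sprintf("capillary TMP %.4f mmHg; venous TMP %.4f mmHg; cuff TMP %.2f mmHg\n",
              x$capillary_tmp, x$venous_tmp, x$cuff_tmp))
  cat(sprintf("vein volume change %+.2f%% of normal\n",
              x$report$venous_volume_change_pct))
  if (!is.null(x$percent_changes))
    cat(sprintf("vs '%s': flow %+.2f%%, capillary TMP %+.2f%%, venous TMP %+.2f%%\n",
                x$percent_changes$reference, x$percent_changes$flow,
                x$percent_changes$capillary_tmp, x$percent_changes$venous_tmp))
  cat(sprintf("converged in %d iteration(s), residual %.2e\n",
              x$report$iterations, x$report$residual))
  if (length(x$report$saturation_flags))
    cat("saturation flags:", paste(x$report$saturation_flags, collapse = ", "), "\n")
  for (n in x$report$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Segment resistances of a solved chain state
#'
#' @param object A `chain_state`.
#' @param ... Ignored.
#' @return Named numeric vector of the four segment resistances plus their
#'   total, mmHg.min/mL.
#' @export
coef.chain_state <- function(object, ...) {
  r <- stats::setNames(object$segments$resistance, object$segments$name)
  c(r, total = sum(r))
}

#' Pressure profile along the chain
#'
#' Plots the blood pressure at each segment boundary from the arterial inflow
#' to the sinus, with the ICP as a dashed reference line: the vertical gap
#' between the curve and the ICP line is the local transmural pressure.
#'
#' @param x A `chain_state`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.chain_state <- function(x, ...) {
  p <- c(x$segments$inlet_pressure, x$segments$outlet_pressure[4L])
  labs <- c("arterial\ninflow", "pre-\ncapillary", "post-\ncapillary",
            "pre-cuff", "sinus")
  graphics::plot(0:4, p, type = "b", pch = 19, xaxt = "n",
                 xlab = "", ylab = "pressure (mmHg)",
                 main = sprintf("Pressure profile: %s", x$scenario),
                 ylim = range(c(p, x$icp, 0)), ...)
  graphics::axis(1, at = 0:4, labels = labs, padj = 0.5, cex.axis = 0.8)
  graphics::abline(h = x$icp, lty = 2, col = "grey40")
  graphics::text(0.2, x$icp, sprintf("ICP = %.1f", x$icp), pos = 3,
                 col = "grey40", cex = 0.8)
  invisible(x)
}
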