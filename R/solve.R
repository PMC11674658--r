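#' Solver settings for the steady-state chain
#'
#' @param relative_tolerance Convergence tolerance on the scalar fixed-point
#'   iterate (relative).
#' @param max_iterations Iteration cap for each fixed-point loop.
#' @param damping Damping factor in (0, 1] for the fixed-point updates; 0.5
#'   by default. If the damped iteration has not converged after 200
#'   oscillations, a bisection fallback (root of `f(x) - x`) takes over.
#' @return An object of class `chain_control`.
#' @export
chain_control <- function(relative_tolerance = 1e-9, max_iterations = 10000L,
                          damping = 0.5) {
  stopifnot(relative_tolerance > 0, max_iterations >= 1,
            damping > 0, damping <= 1)
  structure(list(relative_tolerance = relative_tolerance,
                 max_iterations = as.integer(max_iterations),
                 damping = damping),
            class = "chain_control")
}

# Damped scalar fixed point x <- (1-d) x + d f(x) with a bisection fallback
# on g(x) = f(x) - x after 200 sign oscillations of the update.
damped_fixed_point <- function(f, x0, control, bracket = c(-1e3, 1e3)) {
  x <- x0
  d <- control$damping
  last_step <- 0
  flips <- 0L
  for (i in seq_len(control$max_iterations)) {
    fx <- f(x)
    step <- fx - x
    resid <- abs(step) / max(1, abs(x))
    if (resid <= control$relative_tolerance)
      return(list(value = x, iterations = i, residual = resid, converged = TRUE))
    if (sign(step) != 0 && sign(step) == -sign(last_step)) flips <- flips + 1L
    if (flips > 200L) {
      root <- stats::uniroot(function(z) f(z) - z, interval = bracket,
                             tol = control$relative_tolerance)
      return(list(value = root$root, iterations = i + root$iter,
                  residual = abs(root$f.root), converged = TRUE))
    }
    last_step <- step
    x <- x + d * step
  }
  list(value = x, iterations = control$max_iterations,
       residual = abs(f(x) - x) / max(1, abs(x)), converged = FALSE)
}

# Resolve the prescribed arterial and cuff resistances of a scenario, looking
# up reference scenarios in the catalogue where a policy inherits from one.
# Returns list(arterial =, cuff =) with NA for residual unknowns.
resolve_resistances <- function(scenario, constants, laws, catalogue, depth = 0L) {
  if (depth > 5L)
    stop("circular scenario references while resolving '", scenario$name, "'",
         call. = FALSE)
  rn <- normal_resistances(constants)
  ref <- function() {
    nm <- scenario$reference_state
    if (identical(nm, scenario$name))
      stop("scenario '", nm, "' cannot inherit resistances from itself", call. = FALSE)
    if (is.null(catalogue[[nm]]))
      stop("reference scenario '", nm, "' not found in the catalogue", call. = FALSE)
    resolve_resistances(catalogue[[nm]], constants, laws, catalogue, depth + 1L)
  }
  nph <- function() {
    if (is.null(catalogue[["nph_baseline"]]))
      stop("'multiplier-of-nph-baseline' needs an 'nph_baseline' catalogue entry",
           call. = FALSE)
    resolve_resistances(catalogue[["nph_baseline"]], constants, laws, catalogue,
                        depth + 1L)$arterial
  }
  arterial <- switch(scenario$arterial_policy,
    "multiplier-of-normal" = scenario$arterial_multiplier * rn[["artery"]],
    "multiplier-of-nph-baseline" = scenario$arterial_multiplier * nph(),
    "solve-residually" = NA_real_)
  cuff <- switch(scenario$cuff_policy,
    "unchanged-from-reference" = ref()$cuff,
    "multiplier-of-normal" = scenario$cuff_multiplier * rn[["cuff"]],
    "zero" = 0,
    "solve-residually" = NA_real_,
    "eq13-literal" = cuff_resistance(constants$sinus_pressure - scenario$icp,
                                     cuff_law(mode = "literal")))
  list(arterial = arterial, cuff = cuff)
}

# Venous resistance and dilation at a given pre-cuff pressure. The venous TMP
# driving the quadratic law is the pre-cuff pressure minus the ICP.
venous_state <- function(precuff_pressure, icp, constants, laws, rn) {
  tmpv <- precuff_pressure - icp
  dtmp <- 100 * (tmpv - constants$normal_venous_tmp) / constants$normal_venous_tmp
  dv <- venous_volume_change_from_tmp(dtmp, laws$venous)
  list(tmp = tmpv, dv = dv,
       volume = constants$volume_venous * (1 + dv / 100),
       resistance = rn[["vein"]] * resistance_scale_from_volume(1 + dv / 100))
}

#' Solve the steady-state cerebral vascular chain for a scenario
#'
#' Closes the nonlinear system — prescribed boundary pressures (arterial
#' inflow and sinus), prescribed flow and/or resistances, the capillary
#' compliance law, the quadratic venous law and the cuff policy — into a
#' self-consistent steady state.
#'
#' Closure follows the scenario's residual unknown:
#' \itemize{
#'   \item flow, arterial and cuff resistance all prescribed: the capillary
#'     resistance is the residual absorbing the pressure balance ("the
#'     capillary adjusted to suit"); the compliance law is evaluated at the
#'     solved capillary TMP as a consistency report.
#'   \item one of flow / arterial resistance / cuff resistance residual: the
#'     capillary compliance law is enforced exactly through a damped scalar
#'     fixed point on the mean capillary TMP (with an inner fixed point on
#'     the venous dilation where the venous pressure is not pinned by the
#'     downstream boundary), and the residual unknown closes the balance.
#' }
#' The ICP is exogenous in every scenario: solved states are instantaneous
#' findings, and the positive-feedback loop between capillary TMP, CSF
#' formation and ICP is deliberately not iterated.
#'
#' @param scenario A [chain_scenario()] (or the name of a catalogue scenario).
#' @param constants A [physio_constants()] set.
#' @param laws Response-law bundle from [chain_laws()].
#' @param control Solver settings from [chain_control()].
#' @param catalogue Scenario catalogue used to resolve reference policies and
#'   the percent-change reference state.
#' @return A `chain_state` object: per-segment inlet/outlet pressures,
#'   resistances, volumes and transmural pressures, the flow, the capillary /
#'   venous / cuff TMPs, percent changes against the scenario's reference
#'   state, and a solve report (`$report`: convergence, iterations, residual,
#'   closure mode, saturation flags, notes).
#' @export
#' @examples
#' st <- solve_chain("nph_baseline")
#' round(st$capillary_tmp, 1)  # 12.3 mmHg
solve_chain <- function(scenario, constants = normal_baseline(),
                        laws = chain_laws(), control = chain_control(),
                        catalogue = scenario_catalogue()) {
  if (is.character(scenario)) {
    if (is.null(catalogue[[scenario]]))
      stop("unknown scenario '", scenario, "'", call. = FALSE)
    scenario <- catalogue[[scenario]]
  }
  stopifnot(inherits(scenario, "chain_scenario"))
  validate_scenario(scenario)
  validate_constants(constants)

  rn <- normal_resistances(constants)
  res <- resolve_resistances(scenario, constants, laws, catalogue)
  # the scalar fixed points iterate to well below the reporting tolerance so
  # that derived quantities (per-segment Ohm consistency, series additivity)
  # hold at `relative_tolerance` itself
  ctl <- control
  ctl$relative_tolerance <- min(control$relative_tolerance,
                                max(1e-13, control$relative_tolerance * 1e-4))
  pa <- scenario$arterial_pressure
  ps <- constants$sinus_pressure
  icp <- scenario$icp
  q <- scenario$prescribed_flow

  unknown <- c("flow", "arterial", "cuff")[c(is.na(q), is.na(res$arterial),
                                             is.na(res$cuff))]
  iterations <- 0L
  residual <- 0
  converged <- TRUE
  notes <- character(0)

  cap_R <- function(tmp) capillary_resistance_from_tmp(tmp, rn[["capillary"]],
                                                       laws$capillary)

  if (length(unknown) == 0L) {
    if (q == 0) {
      # degenerate sweep endpoint: no viscous losses in any law-governed
      # segment; internal pressures equal their adjacent boundary values and
      # the capillary (the residual segment) carries the full boundary drop
      p1 <- pa; p3 <- ps
      ven <- venous_state(p3, icp, constants, laws, rn)
      p2 <- p3
      closure <- "capillary-residual"
      r_cap <- Inf
      notes <- c(notes, "degenerate zero-flow endpoint")
      r_art <- res$arterial; r_cuf <- res$cuff
    } else {
      # capillary residual: both boundaries pinned
      p1 <- pa - q * res$arterial
      p3 <- ps + q * res$cuff
      ven <- venous_state(p3, icp, constants, laws, rn)
      p2 <- p3 + q * ven$resistance
      r_cap <- (p1 - p2) / q
      closure <- "capillary-residual"
      tmp_now <- mean_transmural_pressure(p1, p2, icp)
      mismatch <- abs(r_cap - cap_R(tmp_now)) / r_cap
      if (mismatch > control$relative_tolerance)
        notes <- c(notes, sprintf(
          "capillary law consistency: residual resistance differs from the law value by %.2e (relative)",
          mismatch))
      r_art <- res$arterial; r_cuf <- res$cuff
    }
  } else if (unknown == "arterial") {
    p3 <- ps + q * res$cuff
    ven <- venous_state(p3, icp, constants, laws, rn)
    p2 <- p3 + q * ven$resistance
    fp <- damped_fixed_point(function(t) p2 + q * cap_R(t) / 2 - icp,
                             x0 = laws$capillary$tmp_floor, control = ctl)
    iterations <- fp$iterations; residual <- fp$residual; converged <- fp$converged
    tmp <- fp$value
    r_cap <- cap_R(tmp)
    p1 <- p2 + q * r_cap
    r_art <- (pa - p1) / q
    r_cuf <- res$cuff
    closure <- "arterial-residual"
  } else if (unknown == "cuff") {
    p1 <- pa - q * res$arterial
    fp <- damped_fixed_point(function(t) p1 - q * cap_R(t) / 2 - icp,
                             x0 = laws$capillary$tmp_floor, control = ctl)
    iterations <- fp$iterations; residual <- fp$residual; converged <- fp$converged
    tmp <- fp$value
    r_cap <- cap_R(tmp)
    p2 <- p1 - q * r_cap
    # inner fixed point on the venous dilation: the pre-cuff pressure is not
    # pinned by the sinus boundary here
    fpv <- damped_fixed_point(function(p3) {
      p2 - q * venous_state(p3, icp, constants, laws, rn)$resistance
    }, x0 = p2 - 0.5, control = ctl)
    iterations <- iterations + fpv$iterations
    residual <- max(residual, fpv$residual)
    converged <- converged && fpv$converged
    p3 <- fpv$value
    ven <- venous_state(p3, icp, constants, laws, rn)
    r_cuf <- (p3 - ps) / q
    if (r_cuf < 0)
      stop("cuff closure requires a negative cuff resistance; scenario is not physical",
           call. = FALSE)
    r_art <- res$arterial
    closure <- "cuff-residual"
  } else { # flow residual
    fp <- damped_fixed_point(function(qq) {
      p3 <- ps + qq * res$cuff
      ven <- venous_state(p3, icp, constants, laws, rn)
      p2 <- p3 + qq * ven$resistance
      fpt <- damped_fixed_point(function(t) p2 + qq * cap_R(t) / 2 - icp,
                                x0 = laws$capillary$tmp_floor, control = ctl)
      (pa - ps) / (res$arterial + cap_R(fpt$value) + ven$resistance + res$cuff)
    }, x0 = constants$cbf, control = ctl, bracket = c(1, 5000))
    iterations <- fp$iterations; residual <- fp$residual; converged <- fp$converged
    q <- fp$value
    p3 <- ps + q * res$cuff
    ven <- venous_state(p3, icp, constants, laws, rn)
    p2 <- p3 + q * ven$resistance
    fpt <- damped_fixed_point(function(t) p2 + q * cap_R(t) / 2 - icp,
                              x0 = laws$capillary$tmp_floor, control = ctl)
    iterations <- iterations + fpt$iterations
    r_cap <- cap_R(fpt$value)
    p1 <- p2 + q * r_cap
    r_art <- res$arterial; r_cuf <- res$cuff
    closure <- "flow-residual"
  }

  if (!converged)
    stop(sprintf(
      "chain solve for '%s' did not converge (%d iterations, residual %.3e)",
      scenario$name, iterations, residual), call. = FALSE)

  cap_tmp <- mean_transmural_pressure(p1, p2, icp)
  cap_vol <- capillary_volume_from_tmp(cap_tmp, laws$capillary)

  flags <- character(0)
  if (cap_tmp <= laws$capillary$tmp_floor) flags <- c(flags, "capillary_floor")
  if (cap_tmp >= laws$capillary$tmp_ceiling) flags <- c(flags, "capillary_ceiling")
  if (ven$dv > 0.9 * laws$venous$dv_vertex) flags <- c(flags, "vein_vertex_proximity")

  if (identical(scenario$name, "infusion"))
    notes <- c(notes, sprintf(
      "solved vein dilation %.1f%%: larger than the 32%% sometimes quoted for the infusion state; difference is reported, not resolved",
      ven$dv))

  segments <- data.frame(
    name = c("artery", "capillary", "vein", "cuff"),
    inlet_pressure = c(pa, p1, p2, p3),
    outlet_pressure = c(p1, p2, p3, p3 - q * r_cuf),
    resistance = c(r_art, r_cap, ven$resistance, r_cuf),
    volume = c(constants$volume_arterial, cap_vol, ven$volume, NA_real_),
    tmp = c(mean_transmural_pressure(pa, p1, icp), cap_tmp, ven$tmp, ps - icp),
    stringsAsFactors = FALSE
  )

  report <- list(converged = converged, iterations = iterations,
                 residual = residual, closure = closure,
                 unknown = if (length(unknown)) unknown else "capillary",
                 saturation_flags = flags,
                 venous_volume_change_pct = ven$dv,
                 notes = notes)

  # percent changes against the reference state
  reference <- NULL
  pct <- NULL
  if (!identical(scenario$reference_state, scenario$name) &&
      !is.null(catalogue[[scenario$reference_state]])) {
    reference <- solve_chain(catalogue[[scenario$reference_state]], constants,
                             laws, control, catalogue)
    pct <- list(
      reference = scenario$reference_state,
      flow = 100 * (q - reference$flow) / reference$flow,
      capillary_tmp = 100 * (cap_tmp - reference$capillary_tmp) / reference$capillary_tmp,
      venous_tmp = 100 * (ven$tmp - reference$venous_tmp) / reference$venous_tmp
    )
  }

  new_chain_state(flow = q, icp = icp, sinus_pressure = ps, segments = segments,
                  capillary_tmp = cap_tmp, venous_tmp = ven$tmp,
                  scenario_name = scenario$name, reference = reference,
                  percent_changes = pct, report = report,
                  tol = control$relative_tolerance)
}
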