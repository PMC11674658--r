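#' Specify a parameter perturbation for sensitivity runs
#'
#' Describes a seeded, distributional perturbation of one field of
#' [physio_constants()], emulating single-parameter sensitivity analysis
#' (e.g. a 10% reduction in sinus pressure). `fixed-fractional` multiplies
#' the field by exactly `1 + magnitude` in every draw (deterministic, the
#' default, matching a single-point sensitivity); `uniform-fractional` draws
#' multipliers uniformly from `1 - |magnitude|` to `1 + |magnitude|` for
#' exploratory sweeps.
#'
#' @param target_field Name of the `physio_constants` field to perturb.
#' @param distribution `"fixed-fractional"` or `"uniform-fractional"`.
#' @param magnitude Fractional magnitude, in (-1, 1); e.g. -0.10 for a 10%
#'   reduction.
#' @param n_draws Number of perturbed copies to generate (>= 1).
#' @param seed Integer seed; identical seeds give identical draw sequences.
#' @return An object of class `perturbation_spec`.
#' @seealso [perturb()]
#' @export
#' @examples
#' perturbation("sinus_pressure", magnitude = -0.10)
perturbation <- function(target_field,
                         distribution = c("fixed-fractional", "uniform-fractional"),
                         magnitude,
                         n_draws = 1L,
                         seed = 1L) {
  distribution <- match.arg(distribution)
  fields <- names(normal_baseline())
  if (!is.character(target_field) || length(target_field) != 1L ||
      !target_field %in% fields)
    stop("target_field must be one of: ", paste(fields, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(magnitude) || abs(magnitude) >= 1)
    stop("magnitude must lie in (-1, 1)", call. = FALSE)
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(target_field = target_field, distribution = distribution,
                 magnitude = magnitude, n_draws = n_draws, seed = seed),
            class = "perturbation_spec")
}

#' Generate perturbed copies of the physiological constants
#'
#' Applies a [perturbation()] spec to a constants set, returning `n_draws`
#' perturbed copies. Every copy is re-validated: a perturbation that breaks
#' the pressure ordering along the chain is rejected with an error naming the
#' violated ordering.
#'
#' @param constants A `physio_constants` object.
#' @param spec A `perturbation_spec`.
#' @return A list of `n_draws` `physio_constants` objects.
#' @export
#' @examples
#' drawn <- perturb(normal_baseline(), perturbation("sinus_pressure", magnitude = -0.10))
#' drawn[[1]]$sinus_pressure  # 6.75
perturb <- function(constants, spec) {
  stopifnot(inherits(constants, "physio_constants"),
            inherits(spec, "perturbation_spec"))
  factors <- switch(spec$distribution,
    "fixed-fractional" = rep(1 + spec$magnitude, spec$n_draws),
    "uniform-fractional" = with_preserved_seed(spec$seed, {
      1 + stats::runif(spec$n_draws, -abs(spec$magnitude), abs(spec$magnitude))
    })
  )
  lapply(factors, function(f) {
    y <- constants
    y[[spec$target_field]] <- y[[spec$target_field]] * f
    validate_constants(y)
    y
  })
}

# Run `expr` under `set.seed(seed)` without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
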