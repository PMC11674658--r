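# Solved catalogue states shared across test files (computed once per run).
.states <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]]))
      cache[[name]] <- solve_chain(name)
    cache[[name]]
  }
})

# Percent change of a state's capillary TMP against the solved NPH baseline.
tmp_change_vs_nph <- function(state) {
  nph <- .states("nph_baseline")
  100 * (state$capillary_tmp - nph$capillary_tmp) / nph$capillary_tmp
}

# Comparison against a published value on its printed scale: the computed
# quantity is rounded to the published precision (one decimal mmHg, whole
# percent) and must lie within the stated tolerance of the printed value.
expect_published <- function(computed, printed, tolerance, digits) {
  expect_lte(abs(round(computed, digits) - printed), tolerance + 1e-9)
}
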