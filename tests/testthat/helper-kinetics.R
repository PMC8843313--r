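# Shared fixtures for the kinetics tests: literature-derived constants and
# small simulation helpers. All simulated inputs are built in code.

CP_FACTOR <- 1 + 20 / 17.4            # substrate-competition factor at S = 20 uM

slow_curves <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- simulate_progress_curves(params_gu1303(), assay_conditions(),
                                        inhibitor_grid("slow"))
    memo
  }
})

tight_curves <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- simulate_progress_curves(params_gu2602(), assay_conditions(),
                                        inhibitor_grid("tight"))
    memo
  }
})

# Closed-form progress curve as a progress_curve object
synth_progress <- function(vs, vi, kobs, d = 0, inhibitor_nM = 10,
                           times = seq(0, 2400, 10)) {
  progress_curve(inhibitor_nM, times,
                 progress_signal(times, progress_params(vs, vi, kobs, d)))
}
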