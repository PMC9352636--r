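# Shared fixtures. Simulations in unit tests default to a coarser grid than
# the production settings to keep the suite fast; accuracy-sensitive checks
# override locally.

ref_ps <- function(...) {
  ps <- default_parameters()
  ov <- list(...)
  for (nm in names(ov)) ps <- bapbk:::set_path_ps(ps, nm, ov[[nm]])
  ps
}

quick_ba <- function(ps = ref_ps(), days = 1, sens = 1, ...) {
  simulate_ba(ps, days = days, sens = sens, dt_out = 0.02,
              rtol = 1e-6, atol = 1e-8, ...)
}

quick_coupled <- function(ps = ref_ps(), days = 1, sens = 1, dose_mg = 500, ...) {
  simulate_coupled(ps, days = days, sens = sens, dose_mg = dose_mg,
                   dt_out = 0.02, rtol = 1e-6, atol = 1e-8, ...)
}
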