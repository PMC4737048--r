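# Small, fast variants of the generator defaults for module-level tests;
# the acceptance suite exercises the full default conditions.

fast_image_spec <- function(...) {
  image_spec(width_px = 128, height_px = 128, n_cells = 4,
             cytoplasm_radius_px = 28, ...)
}

short_trace_spec <- function(...) {
  trace_spec(state_plan = default_state_plan(duration_s = 240), ...)
}

# build a trace object directly from a flux vector sampled at 1 Hz
flux_trace <- function(flux, events = data.frame(time_s = 0, label = "PMG"),
                       ...) {
  oxygraph_trace(time_s = seq_along(flux) - 1, flux_pmol_s_per_million = flux,
                 events = events, ...)
}
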