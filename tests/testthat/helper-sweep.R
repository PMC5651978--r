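# The desk-scale angle sweep (6 angles x 3 cases x 20 agents) is used by
# several acceptance checks; run it once per mode and cache for the session.
sweep_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function(mode) {
  if (is.null(sweep_cache[[mode]])) {
    sw <- sim_sweep(sim_config(n_agents = 20), cases = 3, mode = mode,
                    seed = 1)
    m <- evac_metrics(sw$tracks, sw$events, sw$trials)
    sweep_cache[[mode]] <- list(sweep = sw, metrics = m)
  }
  sweep_cache[[mode]]
}
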