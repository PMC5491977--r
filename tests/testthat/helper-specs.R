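# short simulation grids used by the unit tests (the acceptance tests run
# the full 16 s protocol)
short_sim <- function(duration_s = 2, warmup_s = 0.5) {
  simulation_spec(duration_s = duration_s, warmup_s = warmup_s)
}

quiet_noise <- function() noise_spec(sd_p = 0, sd_f = 0)
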