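# shared small objects; built once per test run
published_cfg <- task_config()

small_cfg <- task_config(
  levels = data.frame(label = c("green", "red"),
                      n_go = c(24L, 24L), n_stop = c(0L, 12L)),
  rest_blocks = data.frame(position = numeric(0), duration = numeric(0)))

# deterministic subject: no noise anywhere
rigid_subject <- subject_params(go_mu = 800, go_sigma = 0, go_tau = 0,
                                slow_slope = 0, ssrt_mu = 250, ssrt_sigma = 0)

# the worked SSRT example: 10 Go RTs, 4 Stop trials, 2 responded
ssrt_example <- list(go_rts = seq(700, 880, by = 20), n_stop = 4,
                     n_respond = 2, ssds = c(500, 525, 550, 575))
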