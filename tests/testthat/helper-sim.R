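# Shared small synthetic world, built once per test run.  Scaled down
# from the acceptance-scale genome (200 kb / 50 precursors) to keep the
# unit suite fast; the full-scale run lives in test-acceptance.R.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(genome_length = 40000L, n_precursors = 8L,
                              seed = 101L)
      sim <- plant_genome(cfg)
      sim$config <- cfg
      sim$reads <- make_reads(sim$truth, depth = 30, error_rate = 0.01,
                              seed = 102L)
      cache <<- sim
    }
    cache
  }
})
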