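# Shared haplotype-pool set for the simulation studies: simulated once per
# test run and reused across study tests, mirroring how the evaluation design
# reuses its evolutionary replicates for every sample size.
study_pools <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- demography_config(scale = 100)
      set.seed(20260101)
      ps <- sample.int(.Machine$integer.max, 400)
      cache <<- lapply(ps, function(s) simulate_region(cfg, s))
    }
    cache
  }
})

study_config <- function() demography_config(scale = 100)
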