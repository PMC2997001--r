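# Shared small fixtures for the test suite.

# A ProbeMatrix with `sets` probesets of `k` probes and one column per
# entry of `genotype` (replicates auto-numbered), filled from `values`
# (recycled) on the requested scale.
toy_probe_matrix <- function(values, sets = 2L, k = 3L,
                             genotype = c("AT", "AT", "TC", "TC"),
                             scale = "linear") {
  reps <- stats::ave(seq_along(genotype), genotype, FUN = seq_along)
  ids <- paste(genotype, reps, sep = "_")
  x <- matrix(values, nrow = sets * k, ncol = length(genotype))
  colnames(x) <- ids
  m <- ProbeMatrix(x, rep(sprintf("s%02d", seq_len(sets)), each = k),
                   rep(seq_len(k), sets), scale = scale)
  sheet <- SampleSheet(ids, genotype, reps)
  list(probes = m, samples = sheet)
}

# A PsfRecord-shaped data.frame built directly from simulation truth,
# bypassing discovery (used for null controls and sequence checks).
truth_psf_records <- function(truth) {
  pr <- truth$probes
  data.frame(probeset_id = pr$probeset_id, probe_index = pr$probe_index,
             d = ifelse(pr$class == "TC_specific", 1,
                        ifelse(pr$class == "AT_specific", -1, 0)),
             expected_d = 0, significant = pr$is_psf, class = pr$class,
             stringsAsFactors = FALSE)
}

# One small simulated experiment reused across structural tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_experiment(sim_config(n_probesets = 150L, seed = 42L))
    }
    cache
  }
})
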