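#!/usr/bin/env Rscript

# Step 1: simulate the probe-level experiment.
#
# Generates the standard synthetic design — 2,000 probesets x 11 probes,
# four genotypes (diploid parent AT, tetraploid parent TC, synthetic
# allopolyploid SN, 1:1 parental RNA mix MIX) x 4 replicates — with known
# per-probe and per-gene ground truth, and writes the probe table, sample
# sheet and truth tables to results/ as plain TSV.  Later steps
# regenerate the same experiment deterministically from the study seed.

source("analysis/00_common.R")

sim <- load_sim()
write_probe_table(sim$probes, file.path(results_dir, "probes.tsv"),
                  samples = sim$samples,
                  sample_sheet_path = file.path(results_dir, "samples.tsv"))
write_tsv(sim$truth$probes, "truth_probes.tsv")
write_tsv(sim$truth$genes, "truth_genes.tsv")

cat(sprintf("simulated %d probesets x %d probes, %d samples (seed %d)\n",
            length(unique(sim$probes$probeset_id)),
            max(sim$probes$probe_index), ncol(sim$probes$intensity),
            study_seed))
cat(sprintf("true PSFs: %d (%.1f%% of probes)\n",
            sum(sim$truth$probes$is_psf),
            100 * mean(sim$truth$probes$is_psf)))
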