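#!/usr/bin/env Rscript

# Step 3: homoeolog-specific expression in the synthetic allopolyploid.
#
# For every retained PSF, the tracked genome's contribution to total gene
# expression is measured as the E_p/E_t log2 ratio (PSF intensity over the
# probeset's non-PSF linear-mean intensity).  The one-way genotype model
# is fit to the ratios; contrasts test the SN departure from the 1:1 and
# 1:2 mid-parent references; BH at 0.05 per contrast family classifies
# each PSF into mid_parent / non_additive / fits-one-model categories,
# and probesets with direction-discordant PSFs of the same parent class
# are removed.

source("analysis/00_common.R")

sim <- load_sim()
psf <- discover_psf(sim$probes, sim$samples, sam_config(target_fdr = 0.1))
kept <- filter_probesets(psf)

rt <- compute_ep_et(sim$probes, kept$records)
fit <- fit_ratio_model(rt, sim$samples)
tests <- test_contrasts(fit)
calls <- classify_homoeolog_calls(tests, alpha = 0.05)
flt <- concordance_filter(calls)

write_tsv(flt$calls, "expression_calls.tsv")
summ <- summarize_calls(flt$calls)
write_tsv(as.data.frame(summ$counts), "call_counts.tsv")

cat(sprintf("ratios for %d PSFs (%d probesets excluded with no non-PSF probe)\n",
            nrow(rt$info), rt$n_excluded))
cat(sprintf("concordance filter removed %d probesets\n", flt$n_removed))
print(summ$counts)
cat(sprintf("non-additive calls: %.1f%% up, %.1f%% down\n",
            summ$percentages$nonadditive_split[["up"]],
            summ$percentages$nonadditive_split[["down"]]))

ev <- truth_evaluation(psf, flt$calls, sim$truth)
cat(sprintf("vs truth: additive mid-parent rate %.3f, non-additive detection %.3f, direction accuracy %.3f\n",
            ev$additive_midparent_rate, ev$nonadditive_detection_rate,
            ev$direction_accuracy))
print(ev$confusion)

# parental expression divergence and its overlap with non-additive calls
expr <- summarize_probesets(log2_transform(quantile_normalize(
  linear_transform(sim$probes))))
div <- parental_divergence(expr, sim$samples, calls = flt$calls)
write_tsv(div$table, "parental_divergence.tsv")
cat(sprintf("parental divergence: %.1f%% of probesets; %.1f%% of non-additive calls in divergent genes\n",
            100 * div$fraction_divergent,
            100 * div$fraction_nonadditive_in_divergent))
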