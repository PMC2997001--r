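#!/usr/bin/env Rscript

# Step 5: functional-category statistics over the expression calls.
#
# Assigns simulated genes to arbitrary (round-robin) functional bins and
# runs the two category-level analyses on the non-additive call set:
# Fisher exact over/under-representation per category, and the Wilcoxon
# rank-sum test for coordinated shifts of each bin's mid-parent contrast
# estimates.  With the simulator's category-independent truth both
# analyses act as a negative control: BH-significant hits should be rare.

source("analysis/00_common.R")

sim <- load_sim()
psf <- discover_psf(sim$probes, sim$samples, sam_config(target_fdr = 0.1))
kept <- filter_probesets(psf)
rt <- compute_ep_et(sim$probes, kept$records)
calls <- concordance_filter(
  classify_homoeolog_calls(test_contrasts(fit_ratio_model(rt, sim$samples))))$calls

genes <- unique(calls$probeset_id)
bins <- sprintf("BIN%02d", (seq_along(genes) - 1L) %% 12L + 1L)
categories <- data.frame(gene_id = genes, category = bins,
                         stringsAsFactors = FALSE)

na_genes <- unique(calls$probeset_id[calls$category == "non_additive"])
fis <- fisher_enrichment(categories, na_genes, genes, alpha = 0.05)
write_tsv(fis, "fisher_enrichment.tsv")
cat(sprintf("Fisher: %d of %d categories significant at FDR 0.05\n",
            sum(fis$significant), nrow(fis)))

score <- tapply(calls$est11, calls$probeset_id, mean)
wb <- wilcoxon_bin_test(as.numeric(score[genes]), bins, alpha = 0.05)
write_tsv(wb, "wilcoxon_bins.tsv")
cat(sprintf("Wilcoxon: %d of %d bins significant at FDR 0.05\n",
            sum(wb$significant), nrow(wb)))
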