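# Shared settings for the analysis scripts.
#
# Every step regenerates the simulated experiment deterministically from
# the study seed instead of passing binary artifacts between steps; all
# files under results/ are plain text.

library(homoeoExpr)

study_seed <- 17L

load_sim <- function() generate_experiment(sim_config(seed = study_seed))

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

write_tsv <- function(df, name) {
  utils::write.table(df, file.path(results_dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
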