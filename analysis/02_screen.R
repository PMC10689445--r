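#!/usr/bin/env Rscript
# Stage 2: run the full analysis pipeline on the simulated inputs.
#
# Quality-filters the genomes (completeness >= 85%, contamination <= 2%),
# screens every retained metabolic model with 21 drop-out FBA solves,
# predicts growth-normalized fermentation by-products, computes the
# community statistics, the longitudinal stability analysis and the
# confounder-adjusted metabolome screen, and writes every stage table
# under results/pipeline/.

suppressPackageStartupMessages(library(auxoflux))

config <- readRDS("scratch/synthetic/config.rds")
res <- run_pipeline(config)

truth <- read.table("scratch/synthetic/truth_profiles.tsv", header = TRUE,
                    sep = "\t")
aa <- amino_acids()$amino_acid
expl <- data.frame(
  genome_id = rep(truth$genome_id, times = 20),
  amino_acid = rep(aa, each = nrow(truth)),
  status = ifelse(as.vector(as.matrix(truth[, aa])) == 1,
                  "auxotroph", "prototroph"))
vm <- suppressWarnings(validation_metrics(res$profiles, expl))
print(vm)
cat(sprintf(paste0(
  "Screened %d genomes; the drop-out screen recovered the planted truth\n",
  "with sensitivity %.1f%% and specificity %.1f%%.\n",
  "Completeness-bias QC: rho = %.2f (p = %.2g).\n"),
  nrow(res$profiles), vm$sensitivity, vm$specificity,
  res$bias$estimate, res$bias$p_raw))
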