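#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds the full desk-scale stand-in for the study design: a 200-genome
# chassis collection with planted auxotrophies (knockout probability 0.3
# per amino acid, all transporters present), assembly metadata, a
# 185-sample cross-sectional cohort, 100 paired longitudinal subjects,
# and a confounded serum-like metabolome.  Everything downstream reads
# these files; nothing is fetched from outside the repository.

suppressPackageStartupMessages(library(auxoflux))

seed <- 20260930L
input_dir <- "scratch/synthetic"
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(n_genomes = 200, n_samples = 185, n_subjects = 100,
                    auxotrophy_prob = 0.3, seed = seed)
sim <- simulate_inputs(spec, input_dir, out_dir = "results/pipeline")
saveRDS(sim$config, file.path(input_dir, "config.rds"))
write.table(sim$planted, file.path(input_dir, "planted_metabolome.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(paste0(
  "Simulated %d genomes (median %.0f planted auxotrophies per genome),\n",
  "%d cross-sectional samples, %d longitudinal subjects.\n",
  "Inputs written under %s.\n"),
  spec$n_genomes, median(sim$truth$n_auxotrophies),
  spec$n_samples, spec$n_subjects, input_dir))
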