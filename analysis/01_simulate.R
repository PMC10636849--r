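#!/usr/bin/env Rscript
# Simulate the study scenario: 67 mother-infant families, two skin sites,
# infants at 2-3 and 12 months, vertical strain transmission with q = 0.7.
# Writes the full labeled dataset (quality tables, ANI edges, abundances,
# SNVs, ST profiles, gene matrices, classified fractions) for the later
# stages.

source("analysis/config.R")

cfg <- analysis_config()
print(cfg)
sim <- simulate_scenario(cfg)
write_scenario(sim, SCENARIO_DIR)

cat(sprintf("samples: %d (%d infants, %d mothers)\n",
            nrow(sim$samples), sum(sim$samples$role == "infant"),
            sum(sim$samples$role == "mother")))
cat(sprintf("recovered genomes: %d cellular MAGs, %d viral sequences\n",
            nrow(sim$genomes), nrow(sim$viral)))
cat(sprintf("SNV records: %d across %d species\n",
            nrow(sim$snv), length(unique(sim$snv$species_id))))
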