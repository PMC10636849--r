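#!/usr/bin/env Rscript
# Genome quality control: chimera exclusion, MIMAG-style tier assignment
# for prokaryotic and eukaryotic MAGs, CheckV-style bins for viral
# sequences, and the per-kingdom tier tally.

source("analysis/config.R")

sc <- read_scenario(SCENARIO_DIR)
genomes <- sc$genomes

keep <- apply_chimera_filter(genomes)
cat(sprintf("chimera filter: %d of %d genomes discarded\n",
            sum(!keep), nrow(genomes)))

genomes$tier <- NA_character_
prok <- genomes$kingdom == "prokaryote"
genomes$tier[prok] <- assign_prokaryotic_tier(genomes[prok, ])
genomes$tier[!prok] <- assign_eukaryotic_tier(genomes[!prok, ])
genomes$score <- compute_quality_score(genomes$completeness_primary,
                                       genomes$contamination_primary)
genomes$chimera_filter <- ifelse(keep, "keep", "discard")

counts <- tier_summary(genomes)
print(counts)
save_table(genomes[, c("genome_id", "sample_id", "kingdom", "tier",
                       "score", "chimera_filter")], "tiers.tsv")
save_table(counts, "tier_counts.tsv")

if (!is.null(sc$viral) && nrow(sc$viral)) {
  sc$viral$tier <- assign_viral_tier(sc$viral$completeness)
  cat("viral sequence tiers:\n")
  print(table(sc$viral$tier))
  save_table(sc$viral, "viral_tiers.tsv")
}
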