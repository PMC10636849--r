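#!/usr/bin/env Rscript
# Strain-level sharing: conspecific SNV density (two-genome occurrence
# rule, per-kb, >= 10 genomes), the related-versus-unrelated pairwise SNV
# contrast, the SNV source partition, the maternal-strain sharing
# fraction, and the sequence-type sharing permutation test.

source("analysis/config.R")

sc <- read_scenario(SCENARIO_DIR)
cfg <- analysis_config()

dens <- species_snv_density(
  sc$snv, stats::setNames(rep(cfg$genome_length, nrow(sc$pool)),
                          sc$pool$species_id),
  genome_map = sc$truth$genomes[, c("species_id", "genome_id")])
save_table(dens, "snv_density.tsv")
cat(sprintf("SNV density over %d species: median %.2f per kb (max %.2f)\n",
            nrow(dens), median(dens$density_per_kb), max(dens$density_per_kb)))

tests <- related_vs_unrelated_snv_test(sc$pairwise)
save_table(tests, "snv_tests.tsv")
cat(sprintf("species with >= 4 related pairs: %d; significant at 0.01: %d\n",
            nrow(tests), sum(tests$p_value < 0.01)))

roles <- stats::setNames(sc$truth$genomes$role, sc$truth$genomes$genome_id)
part <- snv_source_partition(sc$snv, roles)
save_table(part, "snv_partition.tsv")
shared <- part[part$class == "shared", ]
cat(sprintf("shared SNV proportion: mean %.2f across species\n",
            mean(shared$proportion)))

fam <- stats::setNames(sc$truth$genomes$family_id, sc$truth$genomes$genome_id)
pw <- sc$pairwise
pw$family_id <- fam[pw$genome_a]
est <- estimate_sharing_fraction(pw)
cat(sprintf("estimated maternal-strain sharing fraction: %.2f over %d dyads (true q = %.2f)\n",
            est$sharing_fraction, est$n_pairs, cfg$sharing_prob))

st <- st_permutation_test(sc$st_profiles, n_perm = 1000, seed = ANALYSIS_SEED)
cat(sprintf("ST sharing: %d of %d families share a sequence type; permutation p = %.3g\n",
            st$observed, length(unique(sc$st_profiles$family_id)), st$p_value))
jsonlite::write_json(list(observed = st$observed, p_value = st$p_value,
                          mode = st$mode),
                     file.path(RESULTS_DIR, "st_test.json"),
                     auto_unbox = TRUE, digits = NA)
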