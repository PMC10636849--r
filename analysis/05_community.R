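#!/usr/bin/env Rscript
# Community structure: depth filtering and rarefying, alpha diversity,
# Bray-Curtis ordination, the related-versus-unrelated dyad contrast, the
# longitudinal within-individual contrast, and kingdom composition with
# genome-size normalization.

source("analysis/config.R")

sc <- read_scenario(SCENARIO_DIR)
rarefied <- filter_low_depth_and_rarefy(sc$abundance, min_reads = 800000,
                                        seed = ANALYSIS_SEED)
cat(sprintf("%d of %d samples pass the 800k-read filter; rarefied to %d reads\n",
            ncol(rarefied), ncol(sc$abundance), sum(rarefied[, 1])))

alpha <- alpha_diversity(rarefied)
save_table(alpha, "alpha.tsv")
meta <- sc$samples[sc$samples$sample_id %in% colnames(rarefied), ]
grp <- paste(meta$site, meta$age_group, sep = "/")[
  match(colnames(rarefied), meta$sample_id)]
cat("median richness by group:\n")
print(tapply(alpha$richness, grp, median))

d <- transform_and_distance(rarefied)
ord <- pcoa(d, k = 2)
coords <- data.frame(sample_id = rownames(ord$coordinates),
                     axis1 = ord$coordinates[, 1], axis2 = ord$coordinates[, 2],
                     group = grp)
save_table(coords, "pcoa.tsv")
cat(sprintf("PCoA axes explain %.1f%% and %.1f%% of dissimilarity\n",
            100 * ord$explained[1], 100 * ord$explained[2]))

dyad <- dyad_dissimilarity_test(d, meta)
save_table(dyad$per_infant, "dyads.tsv")
cat(sprintf("dyads: median related %.3f vs unrelated %.3f, Wilcoxon p = %.2g\n",
            dyad$median_related, dyad$median_unrelated, dyad$p_value))

long <- tryCatch(longitudinal_dissimilarity_test(d, meta),
                 error = function(e) NULL)
if (!is.null(long)) {
  cat(sprintf("longitudinal: median within %.3f vs between %.3f, p = %.2g\n",
              long$median_within, long$median_between, long$p_value))
}

comp <- kingdom_composition(rarefied,
                            data.frame(species_id = sc$pool$species_id,
                                       kingdom = sc$pool$kingdom,
                                       genome_size = sc$pool$genome_size))
comp_norm <- kingdom_composition(rarefied,
                                 data.frame(species_id = sc$pool$species_id,
                                            kingdom = sc$pool$kingdom,
                                            genome_size = sc$pool$genome_size),
                                 normalize = TRUE)
comp$normalized <- FALSE
comp_norm$normalized <- TRUE
save_table(rbind(comp, comp_norm), "kingdom_composition.tsv")
cat("kingdom proportions (read counts):\n")
print(comp)
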