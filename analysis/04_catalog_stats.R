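#!/usr/bin/env Rscript
# Catalog saturation and classification gain: rarefaction of species
# discovery versus nonredundant genomes (with and without singleton
# species) and the per-sample classification-improvement statistic.

source("analysis/config.R")

sc <- read_scenario(SCENARIO_DIR)
clusters <- utils::read.delim(file.path(RESULTS_DIR, "clusters.tsv"))
nr <- clusters[clusters$nonredundant, ]
sample_of <- stats::setNames(sc$genomes$sample_id, sc$genomes$genome_id)
map <- data.frame(genome_id = nr$genome_id,
                  species_cluster_id = nr$species_cluster_id,
                  sample_id = unname(sample_of[nr$genome_id]))

full <- rarefaction_curve(map, n_perm = 50, seed = ANALYSIS_SEED)
nosingle <- rarefaction_curve(map, n_perm = 50, seed = ANALYSIS_SEED,
                              exclude_singletons = "by_sample")
full$curve <- "all_species"
nosingle$curve <- "no_singletons"
save_table(rbind(full, nosingle), "rarefaction.tsv")
cat(sprintf("species at full catalog: %d; without singleton species: %d\n",
            round(max(full$mean_species)), round(max(nosingle$mean_species))))

imp <- classification_improvement(sc$classified)
save_table(imp$per_sample, "improvement.tsv")
cat(sprintf("classification improvement: median %.1f%% (IQR %.1f-%.1f) over %d samples\n",
            imp$summary[["median"]], imp$summary[["q1"]],
            imp$summary[["q3"]], imp$summary[["n"]]))

## prevalence vs genome count: name each cluster by the generator species
## its members carry (majority vote) so detection can be read from the
## abundance table
truth_sp <- stats::setNames(sc$truth$genomes$species_id,
                            sc$truth$genomes$genome_id)
majority <- tapply(truth_sp[map$genome_id], map$species_cluster_id,
                   function(x) names(which.max(table(x))))
map_sp <- transform(map, species_cluster_id = unname(majority[species_cluster_id]))
prev <- prevalence_summary(map_sp, sc$abundance)
save_table(prev$per_species, "prevalence.tsv")
cat(sprintf("correlation of log genome count with prevalence: %.2f\n",
            prev$correlation))
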