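#' Run the full catalog pipeline on a synthetic scenario
#'
#' Orchestrates the stages in dependency order: simulate -> genome QC
#' (chimera filter and quality tiers) -> two-stage dereplication and
#' species clustering -> catalog statistics (rarefaction, classification
#' improvement) -> community analyses (rarefying, alpha diversity,
#' Bray-Curtis, PCoA, dyad test) -> pan-genome partition and enrichment ->
#' strain sharing (SNV density, related-versus-unrelated test, SNV source
#' partition, ST permutation test). All tables are written under `outdir`
#' and a manifest records the seed, package version, and an md5 checksum
#' per output, so reruns with an identical config are byte-identical.
#'
#' @param config a [scenario_config()].
#' @param outdir output directory.
#' @param min_reads community-stage sample inclusion threshold.
#' @param pangenome_min_genomes qualifying-genome threshold for pan-genome
#'   eligibility.
#' @param snv_min_genomes conspecific-genome threshold for SNV density.
#' @param n_perm_st Monte-Carlo permutations for the ST sharing test.
#' @return invisibly, a list bundle with every stage result and
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir, min_reads = 800000,
                         pangenome_min_genomes = 10, snv_min_genomes = 10,
                         n_perm_st = 1000) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_scenario(config)
  write_scenario(sim, file.path(outdir, "inputs"))

  ## --- genome QC ---
  genomes <- sim$genomes
  keep <- apply_chimera_filter(genomes)
  genomes$chimera_filter <- ifelse(keep, "keep", "discard")
  genomes$tier <- NA_character_
  prok <- genomes$kingdom == "prokaryote"
  genomes$tier[prok] <- assign_prokaryotic_tier(genomes[prok, , drop = FALSE])
  genomes$tier[!prok] <- assign_eukaryotic_tier(genomes[!prok, , drop = FALSE])
  genomes$score <- score_genome(genomes)
  tiers <- genomes[, c("genome_id", "sample_id", "kingdom", "tier",
                       "score", "chimera_filter")]
  viral <- sim$viral
  if (nrow(viral)) viral$tier <- assign_viral_tier(viral$completeness)
  tier_counts <- tier_summary(genomes)
  write_tsv_file(tiers, file.path(outdir, "tiers.tsv"))
  if (nrow(viral)) write_tsv_file(viral, file.path(outdir, "viral_tiers.tsv"))

  ## --- dereplication & species clustering ---
  pass <- genomes[genomes$tier != "fail" & keep, , drop = FALSE]
  if (nrow(pass) < 2) stop_input("dereplication stage: fewer than two QC-passing genomes")
  edges <- sim$ani
  edges <- edges[edges$genome_a %in% pass$genome_id &
                   edges$genome_b %in% pass$genome_id, , drop = FALSE]
  derep <- dereplicate_catalog(pass, edges)
  write_tsv_file(derep$genome_table, file.path(outdir, "clusters.tsv"))

  ## --- catalog statistics ---
  sample_of <- stats::setNames(pass$sample_id, pass$genome_id)
  map <- data.frame(
    genome_id = derep$nonredundant,
    species_cluster_id = derep$genome_table$species_cluster_id[
      match(derep$nonredundant, derep$genome_table$genome_id)],
    sample_id = unname(sample_of[derep$nonredundant]),
    stringsAsFactors = FALSE
  )
  rare <- rarefaction_curve(map, n_perm = 10, seed = config$seed)
  rare_nosingle <- rarefaction_curve(map, n_perm = 10, seed = config$seed,
                                     exclude_singletons = "by_sample")
  improvement <- classification_improvement(sim$classified)
  write_tsv_file(rare, file.path(outdir, "rarefaction.tsv"))
  write_tsv_file(improvement$per_sample, file.path(outdir, "improvement.tsv"))

  ## --- community analyses ---
  rarefied <- filter_low_depth_and_rarefy(sim$abundance, min_reads = min_reads,
                                          seed = config$seed)
  alpha <- alpha_diversity(rarefied)
  d <- transform_and_distance(rarefied)
  ord <- pcoa(d, k = 2)
  meta <- sim$samples[sim$samples$sample_id %in% colnames(rarefied), ]
  dyad <- dyad_dissimilarity_test(d, meta)
  comp <- kingdom_composition(rarefied,
                              data.frame(species_id = sim$pool$species_id,
                                         kingdom = sim$pool$kingdom,
                                         genome_size = sim$pool$genome_size))
  write_tsv_file(alpha, file.path(outdir, "alpha.tsv"))
  write_tsv_file(dyad$per_infant, file.path(outdir, "dyads.tsv"))

  ## --- pan-genome ---
  qual_clusters <- derep$genome_table[derep$genome_table$nonredundant,
                                      c("genome_id", "species_cluster_id")]
  elig_truth <- eligible_species(
    tiers[, c("genome_id", "tier")],
    data.frame(genome_id = sim$truth$genomes$genome_id,
               species_cluster_id = sim$truth$genomes$species_id,
               stringsAsFactors = FALSE),
    min_genomes = pangenome_min_genomes
  )
  qual_ids <- tiers$genome_id[tiers$tier %in% c("high_quality", "near_complete")]
  pan_rows <- list()
  for (sp in intersect(elig_truth, unique(sim$genes$species_id))) {
    gsp <- sim$genes[sim$genes$species_id == sp, , drop = FALSE]
    freq <- gene_frequencies(gsp, genome_ids = intersect(unique(gsp$genome_id),
                                                         qual_ids))
    lab <- partition_core_accessory(freq)
    meta_sp <- sim$gene_meta[sim$gene_meta$species_id == sp, , drop = FALSE]
    pan_rows[[length(pan_rows) + 1L]] <- data.frame(
      species_id = sp, gene_id = names(lab), label = unname(lab),
      category = meta_sp$category[match(names(lab), meta_sp$gene_id)],
      stringsAsFactors = FALSE
    )
  }
  pangenome <- NULL
  enrichment <- NULL
  if (length(pan_rows)) {
    pangenome <- do.call(rbind, pan_rows)
    enrichment <- tryCatch(category_enrichment(pangenome),
                           error = function(e) NULL)
    write_tsv_file(pangenome, file.path(outdir, "pangenome.tsv"))
    if (!is.null(enrichment)) {
      write_tsv_file(enrichment$per_category, file.path(outdir, "enrichment.tsv"))
    }
  }

  ## --- strain sharing ---
  density <- species_snv_density(
    sim$snv, stats::setNames(rep(config$genome_length, nrow(sim$pool)),
                             sim$pool$species_id),
    min_genomes = snv_min_genomes,
    genome_map = sim$truth$genomes[, c("species_id", "genome_id")]
  )
  snv_tests <- related_vs_unrelated_snv_test(sim$pairwise)
  roles <- stats::setNames(sim$truth$genomes$role, sim$truth$genomes$genome_id)
  partition <- snv_source_partition(sim$snv, roles)
  sharing_est <- estimate_sharing_fraction(
    merge(sim$pairwise,
          data.frame(genome_a = sim$truth$genomes$genome_id,
                     family_id = sim$truth$genomes$family_id,
                     stringsAsFactors = FALSE),
          by = "genome_a")
  )
  st_test <- st_permutation_test(sim$st_profiles, n_perm = n_perm_st,
                                 seed = config$seed)
  write_tsv_file(density, file.path(outdir, "snv_density.tsv"))
  write_tsv_file(snv_tests, file.path(outdir, "snv_tests.tsv"))
  write_tsv_file(partition, file.path(outdir, "snv_partition.tsv"))
  jsonlite::write_json(
    list(observed = st_test$observed, p_value = st_test$p_value,
         mode = st_test$mode, n_perm = n_perm_st),
    file.path(outdir, "st_test.json"), auto_unbox = TRUE, digits = NA
  )

  outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("skincat")),
    seed = as.integer(config$seed),
    files = lapply(stats::setNames(outputs, basename(outputs)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    sim = sim, tiers = tiers, tier_counts = tier_counts, viral = viral,
    derep = derep, rarefaction = rare, rarefaction_nosingleton = rare_nosingle,
    improvement = improvement, rarefied = rarefied, alpha = alpha,
    distance = d, pcoa = ord, dyad = dyad, kingdom = comp,
    pangenome = pangenome, enrichment = enrichment,
    snv_density = density, snv_tests = snv_tests, snv_partition = partition,
    sharing_estimate = sharing_est, st_test = st_test, manifest = manifest
  ))
}

#' Human-readable summary of a pipeline bundle
#'
#' Collects the headline numbers every stage produced (tier counts,
#' species counts, classification-improvement median, dyad test, SNV
#' tests, ST sharing test) into a markdown summary. Stochastic sections
#' are flagged with the seed they derive from.
#'
#' @param bundle result of [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
report <- function(bundle) {
  if (is.null(bundle) || is.null(bundle$tier_counts)) {
    stop_input("empty or incomplete pipeline bundle")
  }
  tc <- bundle$tier_counts
  n_species <- length(unique(bundle$derep$species$cluster_id))
  lines <- c(
    "# Catalog pipeline summary",
    sprintf("Seed: %d (stochastic sections derive from this seed)",
            bundle$manifest$seed),
    "",
    "## Genome quality tiers",
    sprintf("- %s / %s: %d", tc$kingdom, tc$tier, tc$n),
    "",
    "## Catalog",
    sprintf("- nonredundant genomes: %d", length(bundle$derep$nonredundant)),
    sprintf("- species-level clusters: %d", n_species),
    "",
    "## Classification improvement",
    sprintf("- median improvement: %.1f%% (IQR %.1f-%.1f)",
            bundle$improvement$summary[["median"]],
            bundle$improvement$summary[["q1"]],
            bundle$improvement$summary[["q3"]]),
    "",
    "## Mother-infant sharing",
    sprintf("- community dyad test: median related %.3f vs unrelated %.3f, p = %.3g",
            bundle$dyad$median_related, bundle$dyad$median_unrelated,
            bundle$dyad$p_value),
    sprintf("- species with SNV related-vs-unrelated p < 0.01: %d of %d",
            sum(bundle$snv_tests$p_value < 0.01), nrow(bundle$snv_tests)),
    sprintf("- estimated maternal-strain sharing fraction: %.2f",
            bundle$sharing_estimate$sharing_fraction),
    sprintf("- ST sharing: %d families, permutation p = %.3g",
            bundle$st_test$observed, bundle$st_test$p_value)
  )
  lines
}
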