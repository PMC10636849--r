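test_that("config validation enforces the documented invariants", {
  expect_error(scenario_config(n_species = 0), "positive count")
  expect_error(scenario_config(sharing_prob = 1.2), "\\[0, 1\\]")
  expect_error(scenario_config(divergence_time_related = 10,
                               divergence_time_unrelated = 5),
               "must not exceed")
  expect_error(scenario_config(ani_between_range = c(80, 96)), "below 95")
})

test_that("species pool is reproducible, seed-sensitive, and in range", {
  cfg <- scenario_config(n_species = 10, seed = 1)
  p1 <- generate_species_pool(cfg)
  p2 <- generate_species_pool(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10)
  expect_true(all(p1$prevalence > 0 & p1$prevalence <= 1))
  expect_true(all(p1$genome_size > 0))

  p3 <- generate_species_pool(scenario_config(n_species = 10, seed = 2))
  expect_false(identical(p1$mean_abundance, p3$mean_abundance))

  all_bact <- generate_species_pool(
    scenario_config(n_species = 10, kingdom_props = c(bacteria = 1, fungi = 0, virus = 0)))
  expect_true(all(all_bact$kingdom == "bacteria"))
})

test_that("sampling design arithmetic holds: one mother, up to 4 infant samples", {
  cfg <- scenario_config(n_families = 5, n_species = 5)
  ab <- generate_samples_and_abundances(cfg, generate_species_pool(cfg))
  meta <- ab$samples
  mothers <- meta[meta$role == "mother", ]
  expect_equal(nrow(mothers), 5)
  expect_true(all(mothers$site == "antecubital"))
  expect_lte(sum(meta$role == "infant"), 20)
  expect_true(all(ab$abundance >= 0))
  expect_true(is.integer(ab$abundance))
})

test_that("with no family signal related and unrelated dyads are exchangeable", {
  set.seed(1)
  diffs <- replicate(50, {
    cfg <- small_config(seed = sample.int(1e6, 1), n_families = 8,
                        site_effect_sd = 0, age_effect_sd = 0,
                        relatedness_cor = 0)
    sim <- generate_samples_and_abundances(cfg, generate_species_pool(cfg))
    d <- tryCatch(transform_and_distance(sim$abundance, prevalence_cut = 0),
                  error = function(e) NULL)
    if (is.null(d)) return(NA)
    dy <- dyad_dissimilarity_test(d, sim$samples)
    mean(dy$per_infant$related) - mean(dy$per_infant$unrelated)
  })
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.03)
})

test_that("strong family correlation makes related dyads more similar", {
  set.seed(2)
  wins <- replicate(50, {
    cfg <- small_config(seed = sample.int(1e6, 1), n_families = 8,
                        relatedness_cor = 0.9)
    sim <- generate_samples_and_abundances(cfg, generate_species_pool(cfg))
    d <- transform_and_distance(sim$abundance, prevalence_cut = 0)
    dy <- dyad_dissimilarity_test(d, sim$samples)
    stats::median(dy$per_infant$related) < stats::median(dy$per_infant$unrelated)
  })
  expect_gt(mean(wins), 0.9)
})

test_that("genome recoveries respect ANI structure and contamination knobs", {
  cfg <- small_config(seed = 2, contamination_mean = 1e-9)
  pool <- generate_species_pool(cfg)
  ab <- generate_samples_and_abundances(cfg, pool)
  rec <- generate_genome_recoveries(cfg, ab, pool)
  # degenerate contamination: nobody fails the contamination rule
  expect_true(all(rec$genomes$contamination_primary < 5))
  # ANI ranges: conspecific >= 95, duplicates of one lineage >= 99.9
  tr <- rec$truth$genomes
  sp <- stats::setNames(tr$species_id, tr$genome_id)
  lin <- stats::setNames(tr$lineage_id, tr$genome_id)
  within <- sp[rec$ani$genome_a] == sp[rec$ani$genome_b]
  expect_true(all(rec$ani$ani[within] >= 95))
  expect_true(all(rec$ani$ani[!within] < 95))
  expect_true(all(rec$ani$aligned_fraction[within] >= 0.30))
  dup <- within & lin[rec$ani$genome_a] == lin[rec$ani$genome_b]
  expect_true(all(rec$ani$ani[dup] >= 99.9))
})

test_that("recovery probability increases with abundance", {
  cfg <- small_config(seed = 4, n_families = 25, depth_meanlog = log(5e4))
  pool <- generate_species_pool(cfg)
  ab <- generate_samples_and_abundances(cfg, pool)
  rec <- generate_genome_recoveries(cfg, ab, pool)
  rel <- sweep(ab$abundance, 2, pmax(colSums(ab$abundance), 1), "/")
  recovered_key <- paste(rec$truth$genomes$species_id, rec$truth$genomes$sample_id)
  cells <- which(ab$abundance > 0 &
                   matrix(pool$kingdom != "virus", nrow(ab$abundance),
                          ncol(ab$abundance)), arr.ind = TRUE)
  key <- paste(rownames(ab$abundance)[cells[, 1]],
               colnames(ab$abundance)[cells[, 2]])
  hit <- key %in% recovered_key
  la <- log10(rel[cells])
  top <- la > stats::median(la)
  expect_gt(mean(hit[top]), mean(hit[!top]))
})

test_that("identical strains give zero related SNVs; Poisson expectation holds", {
  cfg <- small_config(seed = 6, sharing_prob = 1, divergence_time_related = 0)
  pool <- generate_species_pool(cfg)
  ab <- generate_samples_and_abundances(cfg, pool)
  rec <- generate_genome_recoveries(cfg, ab, pool)
  st <- generate_strain_transmission(cfg, rec$truth)
  rel <- st$pairwise[st$pairwise$relationship == "related_pair", ]
  expect_gt(nrow(rel), 0)
  expect_true(all(rel$n_snvs == 0))

  # mean pairwise count ~ 2 mu t L within 10 percent
  cfg2 <- small_config(seed = 8, n_families = 15, mutation_rate = 1e-6,
                       divergence_time_related = 1000,
                       divergence_time_unrelated = 1000,
                       genome_length = 1e6)
  pool2 <- generate_species_pool(cfg2)
  ab2 <- generate_samples_and_abundances(cfg2, pool2)
  rec2 <- generate_genome_recoveries(cfg2, ab2, pool2)
  st2 <- generate_strain_transmission(cfg2, rec2$truth)
  mi <- st2$pairwise[st2$pairwise$relationship %in%
                       c("related_pair", "unrelated_pair"), ]
  expect_gte(nrow(mi), 50)
  expect_lt(abs(mean(mi$n_snvs) - 2000) / 2000, 0.10)
})

test_that("mutation saturation is guarded with a warning", {
  cfg <- small_config(seed = 9, n_families = 2, n_species = 3,
                      mutation_rate = 1, divergence_time_related = 10,
                      divergence_time_unrelated = 10, genome_length = 1000)
  pool <- generate_species_pool(cfg)
  ab <- generate_samples_and_abundances(cfg, pool)
  rec <- generate_genome_recoveries(cfg, ab, pool)
  w <- capture_warnings(st <- generate_strain_transmission(cfg, rec$truth))
  expect_true(any(grepl("saturating", w)))
  expect_true(all(table(paste(st$snv$genome_id, st$snv$species_id)) <= 1000))
})

test_that("gene matrices honor core fraction, thinning, and enrichment nulls", {
  cfg <- small_config(seed = 10, core_fraction = 0.5, n_genes = 400)
  pool <- generate_species_pool(cfg)
  ab <- generate_samples_and_abundances(cfg, pool)
  rec <- generate_genome_recoveries(cfg, ab, pool)
  rec$genomes$completeness_primary <- 100  # no thinning
  gm <- generate_gene_matrix(cfg, rec$truth, rec$genomes)
  sp <- unique(gm$genes$species_id)[1]
  freq <- gene_frequencies(
    gm$genes[gm$genes$species_id == sp, ],
    genome_ids = rec$truth$genomes$genome_id[rec$truth$genomes$species_id == sp])
  expect_equal(sum(freq == 1), 200)  # exactly the core half at frequency 1

  # no configured enrichment: mean |log OR| across categories is near zero
  set.seed(3)
  lors <- replicate(20, {
    cfg0 <- small_config(seed = sample.int(1e6, 1), n_genes = 500,
                         core_fraction = 0.5, enrichment = numeric(0))
    pool0 <- generate_species_pool(cfg0)
    ab0 <- generate_samples_and_abundances(cfg0, pool0)
    rec0 <- generate_genome_recoveries(cfg0, ab0, pool0)
    gm0 <- generate_gene_matrix(cfg0, rec0$truth, rec0$genomes)
    sp0 <- unique(gm0$genes$species_id)[1]
    meta0 <- gm0$gene_meta[gm0$gene_meta$species_id == sp0, ]
    labels <- data.frame(species_id = sp0, gene_id = meta0$gene_id,
                         label = meta0$true_label, category = meta0$category)
    enr <- category_enrichment(labels)
    mean(log(enr$per_species$odds_ratio))
  })
  expect_lt(abs(mean(lors)), 0.1)
})

test_that("classification fractions hit the configured uplift", {
  cfg <- scenario_config(classification_uplift = 0, classification_noise_sd = 0)
  f <- generate_classification_fractions(cfg, sprintf("s%d", 1:50))
  expect_equal(f$fraction_custom, f$fraction_reference)
  imp0 <- classification_improvement(f)
  expect_true(all(imp0$per_sample$improvement == 0))

  expect_equal(classification_improvement(
    data.frame(sample_id = "a", fraction_reference = 0.5,
               fraction_custom = 0.6))$per_sample$improvement, 20)

  cfg2 <- scenario_config(seed = 12)
  f2 <- generate_classification_fractions(cfg2, sprintf("s%d", 1:200))
  med <- classification_improvement(f2)$summary[["median"]]
  expect_lt(abs(med - 21), 2)
})

test_that("scenario tables round-trip losslessly through the TSV writers", {
  sim <- simulate_scenario(small_config(seed = 13))
  dir <- tempfile()
  write_scenario(sim, dir)
  back <- read_scenario(dir)
  expect_equal(back$abundance, sim$abundance)
  for (nm in c("pool", "samples", "genomes", "ani", "snv", "pairwise",
               "st_profiles", "scheme", "genes", "gene_meta", "classified")) {
    expect_equal(back[[nm]], sim[[nm]], ignore_attr = TRUE)
  }
  expect_equal(back$typed_species, sim$typed_species)
})

test_that("the full scenario is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_scenario(simulate_scenario(cfg), d1)
  write_scenario(simulate_scenario(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})
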