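test_that("pan-genome eligibility requires ten qualifying genomes", {
  tiers <- data.frame(
    genome_id = sprintf("g%02d", 1:25),
    tier = c(rep("high_quality", 5), rep("near_complete", 5),
             rep("high_quality", 9), rep("medium_quality", 6))
  )
  clusters <- data.frame(
    genome_id = sprintf("g%02d", 1:25),
    species_cluster_id = c(rep("spA", 10), rep("spB", 15))
  )
  # spA has exactly 10 qualifying genomes, spB only 9 (6 are medium)
  expect_equal(eligible_species(tiers, clusters), "spA")
  # brute-force check on a random instance
  set.seed(4)
  tiers$tier <- sample(c("high_quality", "near_complete", "medium_quality", "fail"),
                       25, replace = TRUE)
  clusters$species_cluster_id <- sample(c("spA", "spB", "spC"), 25, replace = TRUE)
  got <- eligible_species(tiers, clusters, min_genomes = 3)
  qual <- tiers$tier %in% c("high_quality", "near_complete")
  expected <- sort(names(which(table(
    clusters$species_cluster_id[qual]) >= 3)))
  expect_equal(got, expected)
})

test_that("gene frequencies and the core threshold are computed exactly", {
  genes <- data.frame(
    gene_id = c(rep("gA", 10), rep("gB", 9), "gC"),
    genome_id = c(sprintf("g%02d", 1:10), sprintf("g%02d", 1:9), "g01")
  )
  freq <- gene_frequencies(genes, genome_ids = sprintf("g%02d", 1:10))
  expect_equal(unname(freq[c("gA", "gB", "gC")]), c(1, 0.9, 0.1))
  lab <- partition_core_accessory(freq)
  expect_equal(unname(lab[c("gA", "gB", "gC")]), c("core", "core", "accessory"))
  expect_equal(unname(partition_core_accessory(c(g = 0.89))["g"]), "accessory")
  expect_error(gene_frequencies(genes[0, ]), "empty")
  expect_error(partition_core_accessory(freq, 0), "core_threshold")
})

test_that("generator gene frequencies are bimodal and core recovery is sensitive", {
  cfg <- small_config(seed = 31, n_genes = 800, core_fraction = 0.4,
                      completeness_high_weight = 1,
                      completeness_high_shape1 = 20,
                      completeness_high_shape2 = 1)
  pool <- generate_species_pool(cfg)
  ab <- generate_samples_and_abundances(cfg, pool)
  rec <- generate_genome_recoveries(cfg, ab, pool)
  gm <- generate_gene_matrix(cfg, rec$truth, rec$genomes, min_genomes = 8)
  sp <- names(sort(table(rec$truth$genomes$species_id), decreasing = TRUE))[1]
  gid <- rec$truth$genomes$genome_id[rec$truth$genomes$species_id == sp]
  freq <- gene_frequencies(gm$genes[gm$genes$species_id == sp, ], gid)
  # bimodal: substantial mass near 1 (core) and well below it (accessory)
  expect_gt(mean(freq >= 0.9), 0.2)
  expect_gt(mean(freq <= 0.6), 0.2)
  # core sensitivity with high completeness
  lab <- partition_core_accessory(freq)
  truth_lab <- gm$gene_meta[gm$gene_meta$species_id == sp, ]
  called_core <- names(lab)[lab == "core"]
  true_core <- truth_lab$gene_id[truth_lab$true_label == "core"]
  sensitivity <- mean(true_core %in% called_core)
  expect_gte(sensitivity, 0.95)
})

test_that("odds ratios follow the 2x2 arithmetic with zero correction", {
  labels <- data.frame(
    species_id = "sp",
    gene_id = sprintf("g%03d", 1:200),
    label = rep(c("core", "accessory"), each = 100),
    category = c(rep("V", 10), rep("O", 90), rep("V", 10), rep("O", 90))
  )
  enr <- category_enrichment(labels)
  expect_equal(enr$per_species$odds_ratio, c(1, 1))

  labels2 <- labels
  labels2$category <- c(rep("V", 20), rep("O", 80), rep("V", 5), rep("O", 95))
  enr2 <- category_enrichment(labels2)
  or_v <- enr2$per_species$odds_ratio[enr2$per_species$category == "V"]
  expect_equal(or_v, (20 * 95) / (80 * 5))
  expect_error(category_enrichment(transform(labels, category = "V")),
               "two categories")
})

test_that("a configured accessory enrichment is flagged across 50 species", {
  set.seed(6)
  fams <- sprintf("F%03d", 1:50)
  truth <- list(genomes = data.frame(
    genome_id = sprintf("g%04d", 1:600),
    species_id = rep(sprintf("sp%02d", 1:50), each = 12),
    stringsAsFactors = FALSE
  ))
  genomes <- data.frame(genome_id = truth$genomes$genome_id,
                        completeness_primary = 95)
  cfg <- small_config(seed = 41, n_genes = 400, core_fraction = 0.5,
                      enrichment = c(V = 2))
  gm <- generate_gene_matrix(cfg, truth, genomes)
  labels <- gm$gene_meta[, c("species_id", "gene_id")]
  labels$label <- gm$gene_meta$true_label
  labels$category <- gm$gene_meta$category
  enr <- category_enrichment(labels)
  row_v <- enr$per_category[enr$per_category$category == "V", ]
  expect_lt(row_v$p_adjusted, 0.05)
  expect_lt(row_v$mean_log_or, 0)  # enriched among accessory genes
  # other categories shift far less than the enriched one
  others <- enr$per_category[enr$per_category$category != "V", ]
  expect_lt(max(abs(others$mean_log_or)), abs(row_v$mean_log_or))
})

test_that("catalog overlap counts and specific-gene recovery are exact", {
  meta <- data.frame(
    species_id = "sp", gene_id = sprintf("g%d", 1:6),
    category = c("V", "O", "V", "O", "V", "O"),
    origin = c("both", "both", "a_specific", "a_specific", "b_specific", "both")
  )
  ov <- catalog_overlap(meta)
  expect_equal(ov$counts$shared, 3L)
  expect_equal(ov$counts$a_specific, 2L)
  expect_equal(ov$counts$b_specific, 1L)
  expect_error(catalog_overlap(transform(meta, origin = NA)), "origin")

  # all genes shared: zero specific genes
  all_both <- transform(meta, origin = "both")
  expect_equal(catalog_overlap(all_both)$counts$a_specific, 0L)

  # configured 30 percent A-specific genes recovered within 3 points
  cfg <- small_config(seed = 43, n_genes = 1000,
                      origin_props = c(both = 0.6, a_specific = 0.3,
                                       b_specific = 0.1))
  truth <- list(genomes = data.frame(genome_id = sprintf("g%02d", 1:10),
                                     species_id = "sp01"))
  genomes <- data.frame(genome_id = sprintf("g%02d", 1:10),
                        completeness_primary = 100)
  gm <- generate_gene_matrix(cfg, truth, genomes)
  frac_a <- mean(gm$gene_meta$origin == "a_specific")
  expect_lt(abs(frac_a - 0.3), 0.03)
})
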