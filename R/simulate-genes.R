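#' Generate conspecific gene presence/absence matrices with ground truth
#'
#' For every species with at least `min_genomes` recovered cellular
#' genomes, draws a pan-genome of `n_genes` gene clusters: a `core_fraction`
#' of genes is truly present in every conspecific genome, and accessory
#' genes receive U-shaped (Beta) frequencies realised as a fixed-size
#' random subset of genomes (never all of them), producing the bimodal
#' conspecific gene-frequency spectrum the downstream partition expects.
#' Observed presence is thinned by each genome's primary completeness.
#' Genes are annotated to functional categories at `annotation_rate`;
#' `enrichment` multiplies the odds of the named categories among accessory
#' genes, and `origin_props` assigns catalog-origin flags used by the
#' catalog-overlap comparison.
#'
#' @param config a [scenario_config()].
#' @param truth ground truth from [generate_genome_recoveries()].
#' @param genomes GenomeQuality table (for completeness thinning).
#' @param min_genomes smallest conspecific genome count for which a gene
#'   matrix is drawn.
#' @return list with `genes` (long data.frame: species_id, gene_id,
#'   genome_id) and `gene_meta` (species_id, gene_id, category with `""`
#'   for unannotated, true_label core/accessory, true_frequency, origin).
#' @export
generate_gene_matrix <- function(config, truth, genomes, min_genomes = 2) {
  stopifnot(inherits(config, "scenario_config"))
  check_fraction(config$core_fraction, "core_fraction")
  gt <- truth$genomes
  compl <- stats::setNames(genomes$completeness_primary, genomes$genome_id)
  with_seed(stage_seed(config$seed, "genes"), {
    cats <- config$gene_categories
    enr <- config$enrichment
    genes_blocks <- list(); meta_blocks <- list()
    for (sp in unique(gt$species_id)) {
      gid <- gt$genome_id[gt$species_id == sp]
      n_gen <- length(gid)
      if (n_gen < min_genomes) next
      ng <- as.integer(config$n_genes)
      n_core <- round(config$core_fraction * ng)
      is_core <- seq_len(ng) <= n_core
      freq <- ifelse(is_core, 1,
                     stats::rbeta(ng, config$accessory_shape1, config$accessory_shape2))
      gene_id <- sprintf("%s_gene%05d", sp, seq_len(ng))

      ## category weights: accessory odds multiplied by the enrichment map
      w_core <- rep(1, length(cats))
      w_acc <- w_core
      if (length(enr)) {
        hit <- match(names(enr), cats)
        w_acc[hit[!is.na(hit)]] <- enr[!is.na(hit)]
      }
      category <- character(ng)
      annotated <- stats::runif(ng) < config$annotation_rate
      category[annotated & is_core] <-
        sample(cats, sum(annotated & is_core), replace = TRUE, prob = w_core)
      category[annotated & !is_core] <-
        sample(cats, sum(annotated & !is_core), replace = TRUE, prob = w_acc)

      origin <- sample(names(config$origin_props), ng, replace = TRUE,
                       prob = config$origin_props)

      ## realised presence: core in all genomes; accessory in a fixed-size
      ## random subset (at least 1, at most n_gen - 1 genomes)
      present_idx <- vector("list", ng)
      n_present <- ifelse(is_core, n_gen,
                          pmax(1L, pmin(n_gen - 1L, round(freq * n_gen))))
      for (j in seq_len(ng)) {
        present_idx[[j]] <- if (n_present[j] == n_gen) seq_len(n_gen) else
          sample.int(n_gen, n_present[j])
      }
      gene_rep <- rep(seq_len(ng), lengths(present_idx))
      genome_rep <- gid[unlist(present_idx)]
      ## thin by completeness
      keep <- stats::runif(length(gene_rep)) < compl[genome_rep] / 100
      genes_blocks[[length(genes_blocks) + 1L]] <- data.frame(
        species_id = sp, gene_id = gene_id[gene_rep[keep]],
        genome_id = unname(genome_rep[keep]), stringsAsFactors = FALSE
      )
      meta_blocks[[length(meta_blocks) + 1L]] <- data.frame(
        species_id = sp, gene_id = gene_id,
        category = category,
        true_label = ifelse(is_core, "core", "accessory"),
        true_frequency = round(n_present / n_gen, 4),
        origin = origin, stringsAsFactors = FALSE
      )
    }
    if (!length(genes_blocks)) stop_input("no species with enough genomes for a gene matrix")
    list(genes = do.call(rbind, genes_blocks),
         gene_meta = do.call(rbind, meta_blocks))
  })
}

#' Generate per-sample classified read fractions for two databases
#'
#' Draws, for each sample, the fraction of reads classified against a
#' reference database and against a custom database augmented with the
#' catalog under study. The custom fraction applies a relative uplift
#' (`classification_uplift`, default 0.21 so the median per-sample
#' improvement targets 21 percent) plus per-sample noise, truncated so the
#' custom fraction never falls below the reference and never exceeds 1.
#'
#' @param config a [scenario_config()].
#' @param sample_ids optional character vector of sample ids; defaults to
#'   `4 * n_families` synthetic ids.
#' @return data.frame: sample_id, fraction_reference, fraction_custom.
#' @export
generate_classification_fractions <- function(config, sample_ids = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%04d", seq_len(4 * config$n_families))
  }
  with_seed(stage_seed(config$seed, "classified"), {
    n <- length(sample_ids)
    ref <- pmin(0.95, pmax(0.05,
      stats::rnorm(n, config$classified_ref_mean, config$classified_ref_sd)))
    uplift <- config$classification_uplift +
      stats::rnorm(n, sd = config$classification_noise_sd)
    custom <- pmin(1, pmax(ref, ref * (1 + uplift)))
    data.frame(sample_id = sample_ids,
               fraction_reference = round(ref, 5),
               fraction_custom = round(custom, 5),
               stringsAsFactors = FALSE)
  })
}
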