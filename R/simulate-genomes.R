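#' Generate synthetic genome recoveries with quality metrics and ANI edges
#'
#' For every sample and species present in it, a MAG is recovered with a
#' probability that increases with relative abundance (logistic in log10
#' abundance). Recovered genomes carry the strain lineage of their subject
#' for that species: mothers found their own maternal lineage, and each
#' infant inherits the maternal lineage with probability `sharing_prob`
#' (drawn once per family and species) or founds an independent lineage
#' otherwise. Quality metrics (completeness mixture with a high mode,
#' truncated-exponential contamination, rRNA/tRNA presence, N50, strain
#' heterogeneity, GUNC metrics with a small chimeric fraction) are drawn so
#' that every quality-tier boundary is populated. ANI edges connect all
#' conspecific genome pairs (at or above 99.9 for duplicate recoveries of
#' one strain, 95-99.5 otherwise) plus a thin sample of between-species
#' pairs below 95; aligned fractions within species stay above 0.30.
#' Species of kingdom `virus` yield viral sequences with a completeness
#' value instead of MAGs.
#'
#' @param config a [scenario_config()].
#' @param abund output of [generate_samples_and_abundances()].
#' @param pool species pool from [generate_species_pool()].
#' @return list with `genomes` (GenomeQuality data.frame), `ani` (edge
#'   list), `viral` (sequence_id, sample_id, species_id, completeness), and
#'   `truth` (list: `genomes` with species/lineage/subject/family/role per
#'   genome, `transmitted` flags per family and species, and the species
#'   pool).
#' @export
generate_genome_recoveries <- function(config, abund, pool) {
  stopifnot(inherits(config, "scenario_config"))
  abundance <- abund$abundance
  samples <- abund$samples
  if (is.null(abundance) || nrow(abundance) == 0) {
    stop_input("abundance table is empty")
  }
  with_seed(stage_seed(config$seed, "genomes"), {
    families <- unique(samples$family_id)
    ## Transmission ground truth: one draw per family x species.
    transmitted <- expand.grid(family_id = families,
                               species_id = pool$species_id,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)
    transmitted$transmitted <-
      stats::runif(nrow(transmitted)) < config$sharing_prob
    trans_key <- paste(transmitted$family_id, transmitted$species_id)
    trans_map <- stats::setNames(transmitted$transmitted, trans_key)

    totals <- colSums(abundance)
    rec <- list()
    for (i in seq_len(ncol(abundance))) {
      present <- which(abundance[, i] > 0)
      if (!length(present) || totals[i] == 0) next
      rel <- abundance[present, i] / totals[i]
      p <- config$recovery_max *
        stats::plogis(config$recovery_slope * (log10(rel) - config$recovery_mid))
      hit <- present[stats::runif(length(present)) < p]
      if (!length(hit)) next
      rec[[length(rec) + 1L]] <- data.frame(
        sample_id = samples$sample_id[i],
        subject_id = samples$subject_id[i],
        family_id = samples$family_id[i],
        role = samples$role[i],
        species_id = rownames(abundance)[hit],
        stringsAsFactors = FALSE
      )
    }
    if (!length(rec)) stop_input("no genomes recovered; increase depth or recovery_max")
    rec <- do.call(rbind, rec)
    rec$kingdom_pool <- pool$kingdom[match(rec$species_id, pool$species_id)]

    ## Viral species yield sequences assessed by completeness only.
    viral <- rec[rec$kingdom_pool == "virus", , drop = FALSE]
    rec <- rec[rec$kingdom_pool != "virus", , drop = FALSE]
    if (nrow(viral)) {
      complete <- stats::runif(nrow(viral)) < 0.23
      viral$completeness <- ifelse(
        complete, 100, round(30 + 69.9 * stats::rbeta(nrow(viral), 3, 1), 2))
      viral$sequence_id <- sprintf("v%04d", seq_len(nrow(viral)))
      viral <- viral[, c("sequence_id", "sample_id", "species_id", "completeness")]
    } else {
      viral <- data.frame(sequence_id = character(), sample_id = character(),
                          species_id = character(), completeness = numeric())
    }
    if (!nrow(rec)) stop_input("no cellular genomes recovered")

    ## Lineage per genome: mothers found the maternal lineage; infants
    ## inherit it when the family x species transmission flag is set.
    key <- paste(rec$family_id, rec$species_id)
    maternal <- paste0("lin_", rec$family_id, "_", rec$species_id, "_m")
    own <- paste0("lin_", rec$family_id, "_", rec$species_id, "_i")
    rec$lineage_id <- ifelse(rec$role == "mother" | trans_map[key], maternal, own)
    rec$genome_id <- sprintf("g%05d", seq_len(nrow(rec)))

    n <- nrow(rec)
    high <- stats::runif(n) < config$completeness_high_weight
    completeness <- ifelse(high,
                           70 + 30 * stats::rbeta(n, config$completeness_high_shape1,
                                                  config$completeness_high_shape2),
                           stats::runif(n, 40, 70))
    contamination <- pmin(stats::rexp(n, rate = 1 / config$contamination_mean),
                          config$contamination_max)
    clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    genome_size <- pool$genome_size[match(rec$species_id, pool$species_id)]
    n50 <- pmax(2000, round(stats::rlnorm(n, log(5e4), 1)))
    chimera <- stats::runif(n) < config$p_chimera
    genomes <- data.frame(
      genome_id = rec$genome_id,
      sample_id = rec$sample_id,
      kingdom = ifelse(rec$kingdom_pool == "bacteria", "prokaryote", "eukaryote"),
      completeness_primary = round(completeness, 2),
      contamination_primary = round(contamination, 2),
      completeness_secondary = round(clamp(completeness + stats::rnorm(n, sd = 3), 0, 100), 2),
      contamination_secondary = round(clamp(contamination + stats::rnorm(n, sd = 1), 0, 100), 2),
      rrna_5s = stats::runif(n) < config$rrna_prob,
      rrna_ssu = stats::runif(n) < config$rrna_prob,
      rrna_lsu = stats::runif(n) < config$rrna_prob,
      n_unique_trnas = stats::rbinom(n, 20, config$trna_prob),
      n_contigs = pmax(1L, as.integer(round(genome_size / n50 * stats::runif(n, 0.5, 1.5)))),
      n50 = n50,
      mean_depth = round(stats::rlnorm(n, log(20), 0.8), 1),
      strain_heterogeneity = round(pmin(stats::rexp(n, rate = 1 / 0.25), 5), 3),
      gunc_contamination = ifelse(chimera, stats::runif(n, 0.06, 0.30),
                                  stats::runif(n, 0, 0.05)),
      gunc_css = ifelse(chimera, stats::runif(n, 0.50, 0.90),
                        stats::runif(n, 0, 0.45)),
      gunc_rrs = ifelse(chimera, stats::runif(n, 0.55, 0.95),
                        stats::runif(n, 0, 1)),
      stringsAsFactors = FALSE
    )

    ani <- simulate_ani_edges(config, rec)

    truth <- list(
      genomes = rec[, c("genome_id", "species_id", "lineage_id",
                        "subject_id", "family_id", "role", "sample_id")],
      transmitted = transmitted,
      pool = pool
    )
    list(genomes = genomes, ani = ani, viral = viral, truth = truth)
  })
}

## All conspecific pairs get an edge; between-species pairs are thinned to
## a small random subset (they never pass the species threshold anyway).
simulate_ani_edges <- function(config, rec) {
  edges <- list()
  for (sp in unique(rec$species_id)) {
    idx <- which(rec$species_id == sp)
    if (length(idx) < 2) next
    pr <- utils::combn(idx, 2)
    same_lineage <- rec$lineage_id[pr[1, ]] == rec$lineage_id[pr[2, ]]
    m <- ncol(pr)
    ani <- ifelse(same_lineage,
                  stats::runif(m, config$ani_dup_min, 100),
                  stats::runif(m, config$ani_within_range[1],
                               config$ani_within_range[2]))
    edges[[length(edges) + 1L]] <- data.frame(
      genome_a = rec$genome_id[pr[1, ]],
      genome_b = rec$genome_id[pr[2, ]],
      ani = round(ani, 4),
      aligned_fraction = round(stats::runif(m, config$af_within_range[1],
                                            config$af_within_range[2]), 3),
      stringsAsFactors = FALSE
    )
  }
  n_between <- min(5000L, nrow(rec))
  if (nrow(rec) >= 2 && n_between > 0) {
    a <- sample.int(nrow(rec), n_between, replace = TRUE)
    b <- sample.int(nrow(rec), n_between, replace = TRUE)
    keep <- rec$species_id[a] != rec$species_id[b]
    a <- a[keep]; b <- b[keep]
    if (length(a)) {
      edges[[length(edges) + 1L]] <- data.frame(
        genome_a = rec$genome_id[a],
        genome_b = rec$genome_id[b],
        ani = round(stats::runif(length(a), config$ani_between_range[1],
                                 config$ani_between_range[2]), 4),
        aligned_fraction = round(stats::runif(length(a), config$af_between_range[1],
                                              config$af_between_range[2]), 3),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(edges)) {
    return(data.frame(genome_a = character(), genome_b = character(),
                      ani = numeric(), aligned_fraction = numeric()))
  }
  out <- do.call(rbind, edges)
  ## drop accidental duplicate between-species pairs and self edges
  out <- out[out$genome_a != out$genome_b, ]
  pair_key <- ifelse(out$genome_a < out$genome_b,
                     paste(out$genome_a, out$genome_b),
                     paste(out$genome_b, out$genome_a))
  out[!duplicated(pair_key), ]
}
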