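#' Scenario configuration for the synthetic skin-microbiome generator
#'
#' Builds the single configuration object consumed by every generator stage
#' (species pool, samples and abundances, genome recoveries, strain
#' transmission, gene matrices, classification fractions). Defaults emulate
#' the study design the downstream analyses assume: 67 mother-infant
#' families sampled at the cheek and antecubital fossa, infants at 2-3 and
#' 12 months with a subset sampled longitudinally, mothers at the
#' antecubital fossa only, and vertical strain transmission with a tunable
#' maternal-sharing probability. No distributional parameters for these
#' structures are published; all defaults are package decisions documented
#' here and in the methods vignette.
#'
#' @param n_families number of mother-infant families.
#' @param n_species number of species in the pool.
#' @param sites infant body-site labels; mothers are always sampled at
#'   `"antecubital"` only.
#' @param ages age-group labels, infant groups first, `"mother"` last.
#' @param sharing_prob probability `q` in `[0, 1]` that an infant carries the
#'   maternal strain of a given species.
#' @param mutation_rate substitutions per site per unit time (`mu`).
#' @param divergence_time_related,divergence_time_unrelated time since the
#'   common ancestor of the two genomes of a related (transmitted) pair and
#'   of an unrelated pair; related must not exceed unrelated. With defaults
#'   `mu = 1e-6`, `L = 1e6`, related pairs differ at about
#'   `2 * mu * t * L = 100` sites and unrelated pairs at about 5000,
#'   i.e. roughly the two well-separated modes seen in mother-infant SNV
#'   comparisons.
#' @param genome_length shared coordinate-system length `L` in bp
#'   (infinite-sites approximation; no indels).
#' @param core_fraction fraction of a species' gene pool at frequency 1
#'   before completeness-thinning.
#' @param seed integer master seed; each stage derives a named substream.
#' @param kingdom_props named proportions for `bacteria`, `fungi`, `virus`
#'   species; renormalised to sum to 1.
#' @param prob_longitudinal probability an infant is sampled at both infant
#'   ages (the rest are sampled at the later age only), matching the roughly
#'   one-third longitudinal design of the emulated study.
#' @param site_effect_sd,age_effect_sd standard deviations of per-species
#'   log-fold abundance shifts between sites and between age groups.
#' @param relatedness_cor correlation in `[0, 1]` of the latent per-subject
#'   species deviations within a family; 0 makes related and unrelated dyads
#'   exchangeable.
#' @param abundance_sigma log-scale SD of per-subject species abundance.
#' @param depth_meanlog,depth_sdlog lognormal parameters of per-sample
#'   classified read totals; defaults put about 4-5 percent of samples below
#'   the 800,000-read inclusion threshold used downstream.
#' @param recovery_max,recovery_slope,recovery_mid logistic parameters of
#'   the probability that a species present in a sample yields a MAG, as a
#'   function of log10 relative abundance.
#' @param completeness_high_shape1,completeness_high_shape2,completeness_high_weight
#'   completeness is a mixture: with `completeness_high_weight` a Beta draw
#'   scaled to `[70, 100]`, otherwise a uniform tail on `[40, 70]`, so every
#'   tier boundary is populated.
#' @param contamination_mean,contamination_max exponential mean and
#'   truncation for contamination percent.
#' @param rrna_prob,trna_prob per-rRNA presence probability and per-tRNA
#'   detection probability (out of 20 standard tRNAs).
#' @param p_chimera fraction of genomes given GUNC metrics that trip the
#'   chimera filter.
#' @param ani_within_range uniform range of ANI between distinct conspecific
#'   strains; must stay at or above 95.
#' @param ani_dup_min minimum ANI between duplicate recoveries of one
#'   strain (at or above 99.9).
#' @param ani_between_range uniform range of between-species ANI (< 95).
#' @param af_within_range,af_between_range aligned-fraction ranges.
#' @param n_genes genes per species pan-genome.
#' @param accessory_shape1,accessory_shape2 Beta parameters of accessory
#'   gene frequencies (U-shaped by default).
#' @param gene_categories character vector of functional-category labels
#'   (COG-style single letters).
#' @param annotation_rate probability a gene receives a category label.
#' @param enrichment named numeric: odds multipliers applied to the named
#'   categories among accessory genes (1 = no enrichment; empty vector =
#'   global null). The default emulates the usual pan-genome picture:
#'   accessory genes enriched for replication/recombination (L), defense
#'   (V), and transcription (K); core genes enriched for metabolism (C)
#'   and translation (J).
#' @param classified_ref_mean,classified_ref_sd Gaussian (truncated to
#'   `[0.05, 0.95]`) parameters of the reference-database classified
#'   fraction.
#' @param classification_uplift,classification_noise_sd relative uplift of
#'   the custom database over the reference and its per-sample noise; the
#'   default 0.21 targets a median per-sample improvement of 21 percent.
#' @param origin_props named proportions of genes flagged as present in
#'   both catalogs, specific to catalog A, or specific to catalog B.
#' @param n_isolates_range range of cultured isolates per individual for
#'   sequence typing.
#' @param st_loci,st_alleles number of MLST loci and alleles per locus.
#' @param p_second_lineage probability an individual carries a second,
#'   private strain lineage of the typed species.
#'
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_families = 67,
                            n_species = 40,
                            sites = c("cheek", "antecubital"),
                            ages = c("2-3m", "12m", "mother"),
                            sharing_prob = 0.7,
                            mutation_rate = 1e-6,
                            divergence_time_related = 50,
                            divergence_time_unrelated = 2500,
                            genome_length = 1e6,
                            core_fraction = 0.4,
                            seed = 1,
                            kingdom_props = c(bacteria = 0.90, fungi = 0.07, virus = 0.03),
                            prob_longitudinal = 0.33,
                            site_effect_sd = 1.0,
                            age_effect_sd = 0.7,
                            relatedness_cor = 0.5,
                            abundance_sigma = 1.5,
                            depth_meanlog = log(2e6),
                            depth_sdlog = 0.55,
                            recovery_max = 0.9,
                            recovery_slope = 2.5,
                            recovery_mid = -2.5,
                            completeness_high_shape1 = 4,
                            completeness_high_shape2 = 1,
                            completeness_high_weight = 0.75,
                            contamination_mean = 2.5,
                            contamination_max = 15,
                            rrna_prob = 0.6,
                            trna_prob = 0.92,
                            p_chimera = 0.02,
                            ani_within_range = c(96, 99.5),
                            ani_dup_min = 99.92,
                            ani_between_range = c(80, 94),
                            af_within_range = c(0.55, 0.95),
                            af_between_range = c(0.05, 0.45),
                            n_genes = 1500,
                            accessory_shape1 = 0.45,
                            accessory_shape2 = 1.1,
                            gene_categories = c("C", "E", "J", "K", "L", "M", "P", "T", "V", "X"),
                            annotation_rate = 0.7,
                            enrichment = c(L = 2.0, V = 2.0, K = 1.6,
                                           C = 0.55, J = 0.5),
                            classified_ref_mean = 0.63,
                            classified_ref_sd = 0.10,
                            classification_uplift = 0.21,
                            classification_noise_sd = 0.08,
                            origin_props = c(both = 0.7, a_specific = 0.2, b_specific = 0.1),
                            n_isolates_range = c(4, 12),
                            st_loci = 7,
                            st_alleles = 20,
                            p_second_lineage = 0.3) {
  cfg <- as.list(environment())
  validate_scenario_config(cfg)
  cfg$kingdom_props <- cfg$kingdom_props / sum(cfg$kingdom_props)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario_config <- function(cfg) {
  counts <- c("n_families", "n_species", "genome_length", "n_genes",
              "st_loci", "st_alleles")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop_input(nm, " must be a positive count")
    }
  }
  probs <- c("sharing_prob", "core_fraction", "prob_longitudinal",
             "relatedness_cor", "rrna_prob", "trna_prob", "p_chimera",
             "annotation_rate", "classification_uplift", "p_second_lineage",
             "recovery_max")
  for (nm in probs) check_fraction(cfg[[nm]], nm)
  if (cfg$mutation_rate < 0) stop_input("mutation_rate must be non-negative")
  if (cfg$divergence_time_related > cfg$divergence_time_unrelated) {
    stop_input("divergence_time_related must not exceed divergence_time_unrelated")
  }
  if (any(cfg$kingdom_props < 0) || sum(cfg$kingdom_props) <= 0) {
    stop_input("kingdom_props must be non-negative and not all zero")
  }
  if (cfg$ani_within_range[1] < 95) {
    stop_input("ani_within_range must stay at or above the 95 species boundary")
  }
  if (cfg$ani_dup_min < 99.9) stop_input("ani_dup_min must be at least 99.9")
  if (cfg$ani_between_range[2] >= 95) {
    stop_input("ani_between_range must stay below 95")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic skin-microbiome scenario\n")
  cat(sprintf("  families: %d, species: %d, seed: %d\n",
              x$n_families, x$n_species, as.integer(x$seed)))
  cat(sprintf("  sharing probability q = %.2f, mu = %g, t(rel/unrel) = %g/%g, L = %g bp\n",
              x$sharing_prob, x$mutation_rate, x$divergence_time_related,
              x$divergence_time_unrelated, x$genome_length))
  invisible(x)
}
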