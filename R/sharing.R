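#' Call SNVs between two pre-aligned, gap-free sequences
#'
#' One record per position where both bases are in ACGT and differ;
#' positions with N in either sequence are skipped. Positions are 1-based
#' on the shared coordinate system.
#'
#' @param seq_a,seq_b equal-length nucleotide strings (alphabet ACGTN).
#' @return data.frame: `position`, `ref` (from `seq_a`), `alt` (from
#'   `seq_b`).
#' @export
call_snvs_aligned <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop_input("sequences must have equal length")
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(c(a, b)), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop_input("unexpected characters: ", paste(bad, collapse = ", "))
  ok <- a != "N" & b != "N"
  hit <- which(ok & a != b)
  data.frame(position = hit, ref = a[hit], alt = b[hit],
             stringsAsFactors = FALSE)
}

#' Conspecific SNV density per kilobase
#'
#' An SNV (identified by position and alternate allele on the species
#' representative) counts for a genome only when the same SNV occurs in at
#' least `min_occurrence` conspecific genomes. Each genome's density is
#' its retained SNV count divided by the representative length (reported
#' per kb); the species density is the mean over genomes. Species with
#' fewer than `min_genomes` conspecific genomes are skipped.
#'
#' @param snvs data.frame: `species_id`, `genome_id`, `position`, `alt`.
#' @param rep_length named numeric: representative genome length in bp per
#'   species (a single number is recycled).
#' @param min_genomes minimum conspecific genomes (default 10).
#' @param min_occurrence minimum genomes an SNV must occur in (default 2).
#' @param genome_map optional data.frame (`species_id`, `genome_id`)
#'   listing every conspecific genome, so genomes without retained SNVs
#'   still enter the per-genome mean (and the `min_genomes` gate) with
#'   density 0. Defaults to the genomes appearing in `snvs`.
#' @return data.frame: `species_id`, `n_genomes`, `density_per_kb` (mean
#'   over genomes); species below `min_genomes` are absent.
#' @export
species_snv_density <- function(snvs, rep_length, min_genomes = 10,
                                min_occurrence = 2, genome_map = NULL) {
  check_columns(snvs, c("species_id", "genome_id", "position", "alt"), "SNV table")
  species <- if (is.null(genome_map)) unique(snvs$species_id) else
    unique(genome_map$species_id)
  out <- list()
  for (sp in species) {
    s <- snvs[snvs$species_id == sp, , drop = FALSE]
    genomes <- if (is.null(genome_map)) unique(s$genome_id) else
      unique(genome_map$genome_id[genome_map$species_id == sp])
    if (length(genomes) < min_genomes) next
    L <- if (length(rep_length) == 1 && is.null(names(rep_length))) {
      rep_length
    } else {
      rep_length[[sp]]
    }
    if (is.null(L) || is.na(L) || L <= 0) {
      stop_input("missing representative length for species ", sp)
    }
    key <- paste(s$position, s$alt)
    occ <- table(key[!duplicated(paste(key, s$genome_id))])
    retained <- names(occ)[occ >= min_occurrence]
    s_ret <- s[key %in% retained, , drop = FALSE]
    per_genome <- table(factor(s_ret$genome_id, levels = genomes))
    dens <- as.numeric(per_genome) / (L / 1000)
    out[[length(out) + 1L]] <- data.frame(
      species_id = sp, n_genomes = length(genomes),
      density_per_kb = mean(dens), stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(species_id = character(), n_genomes = integer(),
                      density_per_kb = numeric()))
  }
  do.call(rbind, out)
}

#' Related versus unrelated pairwise SNV comparison per species
#'
#' Two-sided Wilcoxon rank-sum test between the SNV counts of related
#' (own mother-infant) and unrelated (infant x other mother) genome
#' pairs, per species. Species need at least `min_pairs` related pairs
#' (default 4). With `collapse_per_infant = TRUE` the unrelated
#' distribution is collapsed to one median per infant genome, mirroring
#' the dyad convention of the community-level contrast.
#'
#' @param pairs data.frame: `species_id`, `genome_a`, `genome_b`,
#'   `n_snvs`, `relationship` (`related_pair`/`unrelated_pair`).
#' @param min_pairs minimum related pairs per species.
#' @param collapse_per_infant collapse unrelated counts per infant genome.
#' @return data.frame: `species_id`, `n_related`, `n_unrelated`,
#'   `median_related`, `median_unrelated`, `p_value`.
#' @export
related_vs_unrelated_snv_test <- function(pairs, min_pairs = 4,
                                          collapse_per_infant = FALSE) {
  check_columns(pairs, c("species_id", "n_snvs", "relationship"), "pair table")
  out <- list()
  for (sp in unique(pairs$species_id)) {
    p <- pairs[pairs$species_id == sp, , drop = FALSE]
    rel <- p[p$relationship == "related_pair", , drop = FALSE]
    unrel <- p[p$relationship == "unrelated_pair", , drop = FALSE]
    ## count related mother-infant families, not genome pairs
    if (nrow(rel) < min_pairs) next
    if (!nrow(unrel)) stop_input("no unrelated pairs for species ", sp)
    x <- rel$n_snvs
    y <- if (collapse_per_infant) {
      as.numeric(tapply(unrel$n_snvs, unrel$genome_a, stats::median))
    } else {
      unrel$n_snvs
    }
    out[[length(out) + 1L]] <- data.frame(
      species_id = sp, n_related = length(x), n_unrelated = length(y),
      median_related = stats::median(x), median_unrelated = stats::median(y),
      p_value = rank_sum_p(x, y), stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(species_id = character(), n_related = integer(),
                      n_unrelated = integer(), median_related = numeric(),
                      median_unrelated = numeric(), p_value = numeric()))
  }
  do.call(rbind, out)
}

#' Estimate the maternal-strain sharing fraction
#'
#' Classifies each related mother-infant pair as carrying the maternal
#' strain when its SNV count falls below a threshold taken from the
#' unrelated distribution's 1st percentile, and returns the fraction of
#' related pairs classified as shared. The unit is one family-species
#' dyad: when `family_id` (and `species_id`) columns are present, multiple
#' genome pairs of the same dyad collapse to their minimum count.
#'
#' @param pairs pairwise SNV table with `relationship` labels and
#'   optionally `family_id`/`species_id` for dyad collapsing.
#' @param quantile threshold quantile of the unrelated distribution.
#' @return list with `threshold`, `n_pairs`, `sharing_fraction`.
#' @export
estimate_sharing_fraction <- function(pairs, quantile = 0.01) {
  rel <- pairs[pairs$relationship == "related_pair", , drop = FALSE]
  unrel <- pairs[pairs$relationship == "unrelated_pair", , drop = FALSE]
  if (!nrow(rel) || !nrow(unrel)) stop_input("need related and unrelated pairs")
  thr <- stats::quantile(unrel$n_snvs, quantile, names = FALSE)
  group_cols <- intersect(c("species_id", "family_id"), names(rel))
  counts <- if ("family_id" %in% group_cols) {
    key <- do.call(paste, rel[group_cols])
    as.numeric(tapply(rel$n_snvs, key, min))
  } else {
    rel$n_snvs
  }
  list(threshold = thr, n_pairs = length(counts),
       sharing_fraction = mean(counts < thr))
}

#' Partition SNVs by host role
#'
#' Assigns every distinct SNV (position + alternate allele per species) to
#' `infant_only`, `mother_only`, or `shared` according to the roles of the
#' genomes carrying it; proportions sum to 1.
#'
#' @param snvs data.frame: `species_id`, `genome_id`, `position`, `alt`.
#' @param roles named character vector: genome_id -> `infant`/`mother`.
#' @return data.frame: `species_id`, `class`, `n`, `proportion`.
#' @export
snv_source_partition <- function(snvs, roles) {
  check_columns(snvs, c("species_id", "genome_id", "position", "alt"), "SNV table")
  role <- roles[snvs$genome_id]
  if (any(is.na(role))) stop_input("unlabeled genome(s) in SNV table")
  out <- list()
  for (sp in unique(snvs$species_id)) {
    idx <- snvs$species_id == sp
    key <- paste(snvs$position[idx], snvs$alt[idx])
    has_inf <- tapply(role[idx] == "infant", key, any)
    has_mom <- tapply(role[idx] == "mother", key, any)
    cls <- ifelse(has_inf & has_mom, "shared",
                  ifelse(has_inf, "infant_only", "mother_only"))
    tab <- table(factor(cls, c("infant_only", "mother_only", "shared")))
    out[[length(out) + 1L]] <- data.frame(
      species_id = sp, class = names(tab), n = as.integer(tab),
      proportion = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
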