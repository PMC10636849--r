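#' Species eligible for pan-genome analysis
#'
#' Species with at least `min_genomes` (10 by default) nonredundant
#' genomes of tier high-quality or near-complete.
#'
#' @param tiers data.frame: `genome_id`, `tier`.
#' @param clusters data.frame: `genome_id`, `species_cluster_id` (typically
#'   restricted to nonredundant genomes).
#' @param min_genomes minimum qualifying genome count.
#' @return character vector of eligible species ids.
#' @export
eligible_species <- function(tiers, clusters, min_genomes = 10) {
  check_columns(tiers, c("genome_id", "tier"), "tier table")
  check_columns(clusters, c("genome_id", "species_cluster_id"), "cluster table")
  qual <- tiers$genome_id[tiers$tier %in% c("high_quality", "near_complete")]
  cl <- clusters[clusters$genome_id %in% qual, , drop = FALSE]
  tab <- table(cl$species_cluster_id)
  sort(names(tab)[tab >= min_genomes])
}

#' Conspecific gene frequencies
#'
#' Fraction of the species' genomes containing each gene cluster.
#'
#' @param genes long data.frame (`gene_id`, `genome_id`) for one species.
#' @param genome_ids the conspecific genomes over which frequency is
#'   computed (defaults to those appearing in `genes`).
#' @return named numeric vector of frequencies in `(0, 1]`.
#' @export
gene_frequencies <- function(genes, genome_ids = NULL) {
  check_columns(genes, c("gene_id", "genome_id"), "gene table")
  if (nrow(genes) == 0) stop_input("empty gene matrix")
  if (is.null(genome_ids)) genome_ids <- unique(genes$genome_id)
  genes <- genes[genes$genome_id %in% genome_ids, , drop = FALSE]
  n <- length(genome_ids)
  counts <- tapply(genes$genome_id, genes$gene_id,
                   function(x) length(unique(x)))
  stats::setNames(as.numeric(counts) / n, names(counts))
}

#' Partition genes into core and accessory
#'
#' A gene is core when its conspecific frequency is at least
#' `core_threshold` (0.90 by default; the threshold is non-strict because
#' the rule is "at least 90 percent").
#'
#' @param frequencies named frequency vector from [gene_frequencies()].
#' @param core_threshold fraction in `(0, 1]`.
#' @return named character vector: `"core"` or `"accessory"` per gene.
#' @export
partition_core_accessory <- function(frequencies, core_threshold = 0.90) {
  if (core_threshold <= 0 || core_threshold > 1) {
    stop_input("core_threshold must be in (0, 1]")
  }
  stats::setNames(ifelse(frequencies >= core_threshold, "core", "accessory"),
                  names(frequencies))
}

## One species x category 2x2 odds ratio with Haldane-Anscombe correction.
odds_ratio_2x2 <- function(core_in, core_out, acc_in, acc_out) {
  cells <- c(core_in, core_out, acc_in, acc_out)
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Functional-category enrichment of core versus accessory genes
#'
#' For every species and category, builds the 2x2 contingency table with
#' core/accessory genes on one axis and membership in the tested category
#' versus all other categories on the other axis, and computes its odds
#' ratio (Haldane-Anscombe 0.5 correction when any cell is zero; OR > 1
#' means the category is enriched among core genes). Across species each
#' category is tested with a two-tailed one-sample t-test of the
#' log-transformed odds ratios against 0 (or, with
#' `test = "two_sample"`, a two-sample t-test of the per-species logit
#' category proportions among core versus accessory genes), with
#' Bonferroni adjustment over categories. Unannotated genes (empty
#' category) are excluded from the category axes.
#'
#' @param labels data.frame: `species_id`, `gene_id`, `label`
#'   (core/accessory), `category` (`""` or `NA` = unannotated).
#' @param test `"one_sample"` (default) or `"two_sample"`.
#' @return list with `per_species` (species_id, category, odds_ratio) and
#'   `per_category` (category, n_species, mean_log_or, p, p_adjusted).
#' @export
category_enrichment <- function(labels, test = c("one_sample", "two_sample")) {
  test <- match.arg(test)
  check_columns(labels, c("species_id", "gene_id", "label", "category"),
                "gene labels")
  labels <- labels[!is.na(labels$category) & labels$category != "", , drop = FALSE]
  cats <- sort(unique(labels$category))
  if (length(cats) < 2) stop_input("need at least two categories present")
  per_species <- list()
  for (sp in unique(labels$species_id)) {
    ls <- labels[labels$species_id == sp, , drop = FALSE]
    core <- ls$label == "core"
    for (cat in cats) {
      inc <- ls$category == cat
      if (!any(inc)) next
      per_species[[length(per_species) + 1L]] <- data.frame(
        species_id = sp, category = cat,
        odds_ratio = odds_ratio_2x2(sum(core & inc), sum(core & !inc),
                                    sum(!core & inc), sum(!core & !inc)),
        core_prop = mean(ls$category[core] == cat),
        accessory_prop = mean(ls$category[!core] == cat),
        stringsAsFactors = FALSE
      )
    }
  }
  per_species <- do.call(rbind, per_species)
  rows <- lapply(cats, function(cat) {
    d <- per_species[per_species$category == cat, , drop = FALSE]
    lor <- log(d$odds_ratio)
    p <- NA_real_
    if (nrow(d) >= 2 && stats::sd(lor) > 0) {
      p <- if (test == "one_sample") {
        stats::t.test(lor, mu = 0)$p.value
      } else {
        eps <- 1e-6
        logit <- function(x) log((x + eps) / (1 - x + eps))
        stats::t.test(logit(d$core_prop), logit(d$accessory_prop))$p.value
      }
    }
    data.frame(category = cat, n_species = nrow(d),
               mean_log_or = mean(lor), p = p, stringsAsFactors = FALSE)
  })
  per_category <- do.call(rbind, rows)
  per_category$p_adjusted <- stats::p.adjust(per_category$p, method = "bonferroni")
  list(per_species = per_species[, c("species_id", "category", "odds_ratio")],
       per_category = per_category)
}

#' Catalog overlap of conspecific gene clusters
#'
#' Counts shared and catalog-specific genes per species and runs the same
#' odds-ratio/t-test machinery with specific-versus-shared as the first
#' axis: for each catalog, genes specific to it are contrasted with
#' shared genes over category membership.
#'
#' @param gene_meta data.frame: `species_id`, `gene_id`, `category`,
#'   `origin` in `{both, a_specific, b_specific}`.
#' @return list with `counts` per species and `enrichment_a`,
#'   `enrichment_b` ([category_enrichment()] results contrasting each
#'   catalog's specific genes against shared genes).
#' @export
catalog_overlap <- function(gene_meta) {
  check_columns(gene_meta, c("species_id", "gene_id", "category", "origin"),
                "gene meta")
  if (any(is.na(gene_meta$origin))) stop_input("missing origin flags")
  bad <- setdiff(unique(gene_meta$origin), c("both", "a_specific", "b_specific"))
  if (length(bad)) stop_input("unknown origin flag(s): ", paste(bad, collapse = ", "))
  counts <- as.data.frame.matrix(
    table(gene_meta$species_id,
          factor(gene_meta$origin, c("both", "a_specific", "b_specific")))
  )
  counts <- data.frame(species_id = rownames(counts),
                       shared = counts$both,
                       a_specific = counts$a_specific,
                       b_specific = counts$b_specific,
                       stringsAsFactors = FALSE,
                       row.names = NULL)
  contrast <- function(flag) {
    d <- gene_meta[gene_meta$origin %in% c("both", flag), , drop = FALSE]
    d$label <- ifelse(d$origin == flag, "core", "accessory")
    ## "core" slot carries the specific genes; OR > 1 = enriched in specific
    category_enrichment(d[, c("species_id", "gene_id", "label", "category")])
  }
  list(counts = counts,
       enrichment_a = contrast("a_specific"),
       enrichment_b = contrast("b_specific"))
}
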