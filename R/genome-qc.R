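#' MAG quality score
#'
#' The scalar quality gate for medium-quality genomes:
#' `completeness - 5 * contamination`. May be negative.
#'
#' @param completeness,contamination percentages in `[0, 100]`.
#' @return numeric score.
#' @export
compute_quality_score <- function(completeness, contamination) {
  check_percent(completeness, "completeness")
  check_percent(contamination, "contamination")
  completeness - 5 * contamination
}

rrna_trna_ok <- function(g) {
  g$rrna_5s & g$rrna_ssu & g$rrna_lsu & g$n_unique_trnas >= 18
}

medium_rule <- function(completeness, contamination, with_score = TRUE) {
  ok <- !is.na(completeness) & !is.na(contamination) &
    completeness > 50 & contamination < 10
  if (with_score) ok <- ok & (completeness - 5 * contamination > 50)
  ok
}

#' Assign MIMAG-style quality tiers to prokaryotic MAGs
#'
#' High quality requires primary (CheckM2-step) completeness > 90,
#' contamination < 5, all of the 5S/16S/23S rRNAs, and at least 18 of the
#' 20 standard tRNAs. Near-complete genomes meet the completeness and
#' contamination bounds but miss the rRNA/tRNA requirement. Medium quality
#' (completeness > 50, contamination < 10, quality score > 50) is judged
#' inclusively: it suffices that either the primary or the secondary
#' (CheckM-step) estimates satisfy the rule; high/near-complete are judged
#' on the primary estimates only. All comparisons are strict, so boundary
#' values fall to the lower tier.
#'
#' @param g GenomeQuality data.frame (see [generate_genome_recoveries()]
#'   for the column schema).
#' @return character vector: one of `"high_quality"`, `"near_complete"`,
#'   `"medium_quality"`, `"fail"` per row.
#' @export
assign_prokaryotic_tier <- function(g) {
  check_columns(g, c("completeness_primary", "contamination_primary",
                     "rrna_5s", "rrna_ssu", "rrna_lsu", "n_unique_trnas"),
                "genome table")
  check_percent(g$completeness_primary, "completeness_primary")
  check_percent(g$contamination_primary, "contamination_primary")
  nc_numeric <- g$completeness_primary > 90 & g$contamination_primary < 5
  high <- nc_numeric & rrna_trna_ok(g)
  med_primary <- medium_rule(g$completeness_primary, g$contamination_primary)
  med_secondary <- if (all(c("completeness_secondary", "contamination_secondary")
                           %in% names(g))) {
    medium_rule(g$completeness_secondary, g$contamination_secondary)
  } else {
    rep(FALSE, nrow(g))
  }
  tier <- rep("fail", nrow(g))
  tier[med_primary | med_secondary] <- "medium_quality"
  tier[nc_numeric] <- "near_complete"
  tier[high] <- "high_quality"
  tier
}

#' Assign quality tiers to eukaryotic MAGs
#'
#' Same thresholds as [assign_prokaryotic_tier()] (with 18S/26S standing in
#' for 16S/23S in the `rrna_ssu`/`rrna_lsu` columns), except that the
#' medium tier requires only completeness > 50 and contamination < 10,
#' without the quality-score clause.
#'
#' @param g GenomeQuality data.frame with `kingdom == "eukaryote"` rows.
#' @return character vector of tiers.
#' @export
assign_eukaryotic_tier <- function(g) {
  if (!is.null(g$kingdom) && any(g$kingdom != "eukaryote")) {
    stop_input("assign_eukaryotic_tier expects eukaryote rows only")
  }
  check_percent(g$completeness_primary, "completeness_primary")
  check_percent(g$contamination_primary, "contamination_primary")
  nc_numeric <- g$completeness_primary > 90 & g$contamination_primary < 5
  high <- nc_numeric & rrna_trna_ok(g)
  med_primary <- medium_rule(g$completeness_primary, g$contamination_primary,
                             with_score = FALSE)
  med_secondary <- if (all(c("completeness_secondary", "contamination_secondary")
                           %in% names(g))) {
    medium_rule(g$completeness_secondary, g$contamination_secondary,
                with_score = FALSE)
  } else {
    rep(FALSE, nrow(g))
  }
  tier <- rep("fail", nrow(g))
  tier[med_primary | med_secondary] <- "medium_quality"
  tier[nc_numeric] <- "near_complete"
  tier[high] <- "high_quality"
  tier
}

#' Assign CheckV-style tiers to eukaryotic viral sequences
#'
#' `complete` iff completeness equals 100; `high_quality` above 90;
#' `medium_quality` above 50; everything else, including exactly 50, is
#' `low_quality`.
#'
#' @param completeness percentages in `[0, 100]`.
#' @return character vector of tiers.
#' @export
assign_viral_tier <- function(completeness) {
  check_percent(completeness, "completeness")
  ifelse(completeness == 100, "complete",
         ifelse(completeness > 90, "high_quality",
                ifelse(completeness > 50, "medium_quality", "low_quality")))
}

#' Chimera (GUNC) exclusion filter
#'
#' A genome is discarded when its GUNC contamination exceeds 0.05, clade
#' separation score exceeds 0.45, and reference representation score
#' exceeds 0.5. The default reads the three criteria as a conjunction; set
#' `rule = "any"` for the disjunctive reading as a sensitivity analysis.
#' Genomes with missing GUNC metrics are kept with a warning.
#'
#' @param g data.frame with `gunc_contamination`, `gunc_css`, `gunc_rrs`.
#' @param rule `"all"` (default) or `"any"`.
#' @return logical vector, `TRUE` = keep.
#' @export
apply_chimera_filter <- function(g, rule = c("all", "any")) {
  rule <- match.arg(rule)
  check_columns(g, c("gunc_contamination", "gunc_css", "gunc_rrs"), "genome table")
  crit <- cbind(g$gunc_contamination > 0.05,
                g$gunc_css > 0.45,
                g$gunc_rrs > 0.5)
  missing <- apply(is.na(crit), 1, any)
  if (any(missing)) {
    warning(sum(missing), " genome(s) with missing GUNC metrics kept unfiltered",
            call. = FALSE)
  }
  discard <- if (rule == "all") {
    apply(crit, 1, all)
  } else {
    apply(crit, 1, any)
  }
  discard[is.na(discard) | missing] <- FALSE
  !discard
}

#' Remove contigs matching eukaryotic viral genomes
#'
#' A contig is removed before MAG quality assessment when its top BLAST
#' hit is a eukaryotic viral genome with > 95 percent nucleotide identity,
#' > 1000 bp aligned, and > 70 percent of the contig aligned.
#'
#' @param hits data.frame with `contig_id`, `length`,
#'   `top_hit_is_eukaryotic_viral`, `percent_identity`, `aligned_length`.
#' @return character vector of retained contig ids.
#' @export
filter_viral_contigs <- function(hits) {
  check_columns(hits, c("contig_id", "length", "top_hit_is_eukaryotic_viral",
                        "percent_identity", "aligned_length"), "contig hits")
  if (any(hits$length <= 0)) stop_input("zero-length contig in hits table")
  if (any(hits$aligned_length > hits$length)) {
    stop_input("aligned_length exceeds contig length")
  }
  removed <- hits$top_hit_is_eukaryotic_viral &
    hits$percent_identity > 95 &
    hits$aligned_length > 1000 &
    hits$aligned_length / hits$length > 0.70
  hits$contig_id[!removed]
}

#' Tabulate tier counts per kingdom
#'
#' @param genomes GenomeQuality table with a `tier` column (and optionally
#'   `kingdom`).
#' @return data.frame of kingdom, tier, n; all tier levels are listed,
#'   including `fail`, and counts sum to `nrow(genomes)`.
#' @export
tier_summary <- function(genomes) {
  tiers <- c("high_quality", "near_complete", "medium_quality", "fail")
  kingdom <- if (is.null(genomes$kingdom)) rep("all", nrow(genomes)) else genomes$kingdom
  kingdoms <- unique(c(kingdom, character(0)))
  if (nrow(genomes) == 0) {
    return(data.frame(kingdom = character(), tier = character(), n = integer()))
  }
  out <- expand.grid(kingdom = kingdoms, tier = tiers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- table(factor(kingdom, levels = kingdoms),
               factor(genomes$tier, levels = tiers))
  out$n <- as.integer(tab[cbind(out$kingdom, out$tier)])
  out
}
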