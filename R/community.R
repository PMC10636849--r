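#' Drop low-depth samples and rarefy the rest to equal depth
#'
#' Samples with fewer than `min_reads` classified reads (800,000 by
#' default) are excluded; the remaining samples are subsampled without
#' replacement to exactly `depth` reads (the minimum retained sample total
#' when `depth = "auto"`). Samples whose total falls below an explicit
#' `depth` are dropped with a warning.
#'
#' @param table species-by-sample integer count matrix.
#' @param min_reads inclusion threshold on the per-sample total.
#' @param depth target depth, or `"auto"`.
#' @param seed integer seed for the subsampling.
#' @return rarefied integer matrix with equal column sums.
#' @export
filter_low_depth_and_rarefy <- function(table, min_reads = 800000,
                                        depth = "auto", seed = 1) {
  totals <- colSums(table)
  keep <- totals >= min_reads
  if (!any(keep)) stop_input("no sample passes the minimum-read filter")
  table <- table[, keep, drop = FALSE]
  totals <- totals[keep]
  if (identical(depth, "auto")) {
    depth <- min(totals)
  } else {
    short <- totals < depth
    if (any(short)) {
      warning(sum(short), " sample(s) below the rarefaction depth dropped",
              call. = FALSE)
      table <- table[, !short, drop = FALSE]
    }
    if (ncol(table) == 0) stop_input("no sample reaches the rarefaction depth")
  }
  with_seed(stage_seed(seed, "rarefy"), {
    out <- t(suppressWarnings(vegan::rrarefy(t(table), sample = depth)))
  })
  storage.mode(out) <- "integer"
  out
}

#' Per-sample richness and Shannon index
#'
#' Richness counts species with at least `min_species_reads` reads (5 by
#' default); Shannon is the natural-log index over nonzero proportions.
#' All-zero samples get richness 0 and Shannon 0.
#'
#' @param table rarefied species-by-sample count matrix.
#' @param min_species_reads read threshold for richness.
#' @return data.frame: `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table, min_species_reads = 5) {
  richness <- colSums(table >= min_species_reads)
  shannon <- vegan::diversity(t(table), index = "shannon")
  shannon[colSums(table) == 0] <- 0
  data.frame(sample_id = colnames(table),
             richness = as.integer(richness),
             shannon = unname(shannon),
             stringsAsFactors = FALSE)
}

#' Prevalence filter, log transform, and Bray-Curtis dissimilarity
#'
#' Removes species present (count > 0) in at most `prevalence_cut` of the
#' samples, log-transforms the remaining counts after adding
#' `pseudocount`, and returns the Bray-Curtis dissimilarity between
#' samples on the transformed values.
#'
#' @param table species-by-sample count matrix.
#' @param prevalence_cut removal fraction (strict `<=`), default 0.20.
#' @param pseudocount added before the natural log, default 1.
#' @return a `dist` object over samples.
#' @export
transform_and_distance <- function(table, prevalence_cut = 0.20, pseudocount = 1) {
  presence <- rowMeans(table > 0)
  keep <- presence > prevalence_cut
  if (!any(keep)) stop_input("all species removed by the prevalence filter")
  kept <- table[keep, , drop = FALSE]
  empty <- colSums(kept) == 0
  if (any(empty)) {
    warning(sum(empty), " sample(s) with no reads left after the prevalence ",
            "filter dropped", call. = FALSE)
    kept <- kept[, !empty, drop = FALSE]
  }
  x <- log(kept + pseudocount)
  vegan::vegdist(t(x), method = "bray")
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Double-centred Gram eigendecomposition of the squared dissimilarities.
#' Negative eigenvalues are truncated from the coordinates; their total
#' magnitude is reported. Explained proportions are positive eigenvalues
#' over the sum of absolute eigenvalues, so they sum to at most 1.
#'
#' @param d symmetric dissimilarity matrix or `dist` with zero diagonal.
#' @param k number of output dimensions.
#' @return list with `coordinates` (samples x k), `explained`,
#'   `negative_magnitude`.
#' @export
pcoa <- function(d, k = 2) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop_input("dissimilarity matrix must be square and symmetric")
  }
  fit <- stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE)
  eig <- fit$eig
  pos <- pmax(eig, 0)
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  rownames(coords) <- rownames(m)
  list(coordinates = coords,
       explained = (pos / sum(abs(eig)))[seq_len(min(k, length(eig)))],
       negative_magnitude = sum(abs(eig[eig < 0])))
}

#' Related versus unrelated mother-infant community dissimilarity
#'
#' For each infant with an own-mother sample, the related value is the
#' dissimilarity to the own mother and the unrelated value summarises the
#' dissimilarities to other mothers; the two per-infant vectors are
#' compared with a two-sided Wilcoxon rank-sum test (exact null
#' distribution when both groups have at most 25 observations and no ties,
#' normal approximation with continuity correction otherwise). By default
#' the contrast uses the best-sampled infant age group at the mothers'
#' body site.
#'
#' The default unrelated summary is the median over all other mothers.
#' Because a median of many draws is less variable than the single related
#' draw, and because every infant contributes one value to each group, the
#' rank-sum p-value under this summary is conservative rather than uniform
#' when there is no family signal. `unrelated_summary = "split"` instead
#' divides the families in two: odd-indexed families contribute their
#' related dissimilarity and even-indexed families contribute one
#' dissimilarity to a rotation-matched mother of another even family, so
#' every distance involves distinct individuals, the two groups are iid
#' under the null, and the p-value is uniform (up to the exact test's
#' discreteness). Use `"median"` for the headline contrast and `"split"`
#' for calibration studies.
#'
#' @param d `dist` or matrix of sample dissimilarities.
#' @param meta sample metadata (`sample_id`, `subject_id`, `family_id`,
#'   `role`, `site`, `age_group`).
#' @param infant_age,site infant age group and body site of the contrast.
#' @param unrelated_summary `"median"` (default) or `"split"`.
#' @return list with `per_infant` data.frame (`"median"` mode: family_id,
#'   related, unrelated; `"split"` mode: family_id, group, value),
#'   medians, and `p_value`.
#' @export
dyad_dissimilarity_test <- function(d, meta, infant_age = NULL,
                                    site = "antecubital",
                                    unrelated_summary = c("median", "split")) {
  unrelated_summary <- match.arg(unrelated_summary)
  m <- as.matrix(d)
  if (is.null(infant_age)) {
    ## default: the infant age group best sampled at the contrast site
    cand <- meta[meta$role == "infant" & meta$site == site &
                   meta$sample_id %in% rownames(m), "age_group"]
    if (!length(cand)) stop_input("no infant samples at the contrast site")
    tab <- table(cand)
    infant_age <- names(tab)[which.max(tab)]
  }
  mothers <- meta[meta$role == "mother" & meta$sample_id %in% rownames(m), ]
  infants <- meta[meta$role == "infant" & meta$age_group == infant_age &
                    meta$site == site & meta$sample_id %in% rownames(m), ]
  mothers <- mothers[!duplicated(mothers$family_id), ]
  infants <- infants[order(infants$family_id), ]
  ## complete dyads: families with both an infant and a mother sample
  infants <- infants[!duplicated(infants$family_id), ]
  infants <- infants[infants$family_id %in% mothers$family_id, , drop = FALSE]
  mom_of <- stats::setNames(mothers$sample_id, mothers$family_id)
  n <- nrow(infants)
  if (n < 2) stop_input("need at least two families with mother and infant samples")

  if (unrelated_summary == "median") {
    rows <- lapply(seq_len(n), function(i) {
      fam <- infants$family_id[i]
      others <- unname(mom_of[names(mom_of) != fam])
      data.frame(family_id = fam,
                 related = m[infants$sample_id[i], mom_of[[fam]]],
                 unrelated = stats::median(m[infants$sample_id[i], others]),
                 stringsAsFactors = FALSE)
    })
    per_infant <- do.call(rbind, rows)
    related <- per_infant$related
    unrelated <- per_infant$unrelated
  } else {
    odd <- seq(1, n, by = 2)
    even <- seq(2, n, by = 2)
    if (length(even) < 2) stop_input("split mode needs at least four families")
    related <- vapply(odd, function(i) {
      m[infants$sample_id[i], mom_of[[infants$family_id[i]]]]
    }, numeric(1))
    rotated <- even[c(seq_along(even)[-1], 1)]  # even family -> next even's mother
    unrelated <- vapply(seq_along(even), function(k) {
      m[infants$sample_id[even[k]], mom_of[[infants$family_id[rotated[k]]]]]
    }, numeric(1))
    per_infant <- rbind(
      data.frame(family_id = infants$family_id[odd], group = "related",
                 value = related, stringsAsFactors = FALSE),
      data.frame(family_id = infants$family_id[even], group = "unrelated",
                 value = unrelated, stringsAsFactors = FALSE)
    )
  }
  list(per_infant = per_infant,
       median_related = stats::median(related),
       median_unrelated = stats::median(unrelated),
       p_value = rank_sum_p(related, unrelated))
}

#' Within- versus between-individual longitudinal dissimilarity
#'
#' For each infant sampled at two age groups at one site, the within value
#' is the dissimilarity between their own two time points and the between
#' value the median dissimilarity to other infants' samples at the same
#' site; a two-sided rank-sum test compares the vectors.
#'
#' @inheritParams dyad_dissimilarity_test
#' @return list like [dyad_dissimilarity_test()].
#' @export
longitudinal_dissimilarity_test <- function(d, meta, site = "antecubital") {
  m <- as.matrix(d)
  inf <- meta[meta$role == "infant" & meta$site == site &
                meta$sample_id %in% rownames(m), ]
  rows <- list()
  for (subj in unique(inf$subject_id)) {
    own <- inf$sample_id[inf$subject_id == subj]
    if (length(own) < 2) next
    others <- inf$sample_id[inf$subject_id != subj]
    if (!length(others)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subj,
      within = m[own[1], own[2]],
      between = stats::median(c(m[own[1], others], m[own[2], others])),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) < 2) stop_input("need at least two longitudinal infants")
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       median_within = stats::median(per_subject$within),
       median_between = stats::median(per_subject$between),
       p_value = rank_sum_p(per_subject$within, per_subject$between))
}

## Two-sided Wilcoxon rank-sum with the documented exact/approximate policy.
rank_sum_p <- function(x, y) {
  exact <- length(x) <= 25 && length(y) <= 25 && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Kingdom composition of grouped samples
#'
#' Read-count proportions of bacteria, fungi, and viruses per sample
#' group, optionally normalising counts by genome size (proportions of
#' counts divided by genome size, renormalised to 1) to approximate cell
#' proportions.
#'
#' @param table species-by-sample count matrix.
#' @param species_meta data.frame: `species_id`, `kingdom`, `genome_size`.
#' @param groups factor/character of length `ncol(table)`; one overall
#'   group when `NULL`.
#' @param normalize divide counts by genome size before forming
#'   proportions.
#' @return data.frame: group, kingdom, proportion (sums to 1 per group).
#' @export
kingdom_composition <- function(table, species_meta, groups = NULL,
                                normalize = FALSE) {
  check_columns(species_meta, c("species_id", "kingdom"), "species meta")
  idx <- match(rownames(table), species_meta$species_id)
  if (any(is.na(idx))) stop_input("species missing from species_meta")
  kingdom <- species_meta$kingdom[idx]
  x <- table
  if (normalize) {
    gs <- species_meta$genome_size[idx]
    if (any(is.na(gs)) || is.null(gs)) {
      stop_input("genome sizes required when normalize = TRUE")
    }
    x <- table / gs
  }
  if (is.null(groups)) groups <- rep("all", ncol(table))
  out <- list()
  for (g in unique(groups)) {
    tot <- rowSums(x[, groups == g, drop = FALSE])
    by_k <- tapply(tot, kingdom, sum)
    by_k <- by_k / sum(by_k)
    out[[length(out) + 1L]] <- data.frame(
      group = g, kingdom = names(by_k), proportion = as.numeric(by_k),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
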