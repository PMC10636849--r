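#' Rarefaction of species discovery versus number of genomes
#'
#' For each subsample size on a grid (20 evenly spaced sizes plus the
#' endpoint by default) draws `n_perm` random subsets of nonredundant
#' genomes without replacement and counts the distinct species they
#' represent. Singleton species can be excluded before counting, either
#' species backed by a single genome (`"by_genome"`) or recovered from a
#' single distinct sample (`"by_sample"`); exclusion is decided on the
#' full catalog, mirroring how saturation is judged after dropping
#' possibly transient species.
#'
#' @param map data.frame: `genome_id`, `species_cluster_id`, `sample_id`.
#' @param n_perm subsamples per grid size.
#' @param seed integer seed.
#' @param exclude_singletons `"none"`, `"by_genome"`, or `"by_sample"`.
#' @param grid_points number of evenly spaced sizes (endpoint always
#'   included).
#' @return data.frame: `n_genomes`, `mean_species`, `sd_species`.
#' @export
rarefaction_curve <- function(map, n_perm = 10, seed = 1,
                              exclude_singletons = c("none", "by_genome", "by_sample"),
                              grid_points = 20) {
  exclude_singletons <- match.arg(exclude_singletons)
  check_columns(map, c("genome_id", "species_cluster_id", "sample_id"), "genome map")
  if (nrow(map) == 0) stop_input("empty genome-species map")
  if (n_perm < 1) stop_input("n_perm must be at least 1")
  excluded <- character(0)
  if (exclude_singletons == "by_genome") {
    tab <- table(map$species_cluster_id)
    excluded <- names(tab)[tab == 1]
  } else if (exclude_singletons == "by_sample") {
    nsamp <- tapply(map$sample_id, map$species_cluster_id,
                    function(x) length(unique(x)))
    excluded <- names(nsamp)[nsamp == 1]
  }
  species <- ifelse(map$species_cluster_id %in% excluded, NA,
                    map$species_cluster_id)
  n <- nrow(map)
  sizes <- sort(unique(c(round(seq(1, n, length.out = grid_points)), n)))
  with_seed(stage_seed(seed, "rarefaction"), {
    ## one genome permutation per replicate; prefixes of length m are
    ## uniform subsets, and each replicate's curve is monotone
    counts <- vapply(seq_len(n_perm), function(i) {
      s <- species[sample.int(n)]
      cum <- cumsum(!is.na(s) & !duplicated(s))
      cum[sizes]
    }, numeric(length(sizes)))
    counts <- matrix(counts, nrow = length(sizes))
    sds <- apply(counts, 1, stats::sd)
    sds[is.na(sds)] <- 0
    data.frame(n_genomes = sizes,
               mean_species = rowMeans(counts),
               sd_species = sds)
  })
}

#' Per-sample classification improvement between two databases
#'
#' `(fraction_custom - fraction_reference) / fraction_reference * 100` per
#' sample; samples with a zero reference fraction are excluded with a
#' warning. The cross-sample summary reports the median and quartiles.
#'
#' @param f data.frame: `sample_id`, `fraction_reference`,
#'   `fraction_custom`.
#' @return list with `per_sample` (sample_id, improvement) and `summary`
#'   (median, q1, q3, n).
#' @export
classification_improvement <- function(f) {
  check_columns(f, c("sample_id", "fraction_reference", "fraction_custom"),
                "classified fractions")
  check_fraction(f$fraction_reference, "fraction_reference")
  check_fraction(f$fraction_custom, "fraction_custom")
  zero <- f$fraction_reference == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero reference fraction excluded",
            call. = FALSE)
    f <- f[!zero, , drop = FALSE]
  }
  imp <- (f$fraction_custom - f$fraction_reference) / f$fraction_reference * 100
  q <- stats::quantile(imp, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_sample = data.frame(sample_id = f$sample_id, improvement = imp,
                               stringsAsFactors = FALSE),
       summary = c(median = q[2], q1 = q[1], q3 = q[3], n = length(imp)))
}

#' Per-species prevalence and genome counts
#'
#' Counts, for every species in the genome map, the number of samples in
#' which it is detected (count > 0 in the abundance table; 0 when the
#' species is absent from the table) and the number of genomes backing it,
#' plus the Pearson correlation between log10 genome count and prevalence.
#'
#' @param map data.frame: `genome_id`, `species_cluster_id`, `sample_id`.
#' @param abundance species-by-sample count matrix whose rownames share
#'   the map's species ids.
#' @return list with `per_species` (species_cluster_id, n_genomes,
#'   prevalence) and `correlation`.
#' @export
prevalence_summary <- function(map, abundance) {
  check_columns(map, c("genome_id", "species_cluster_id"), "genome map")
  n_genomes <- table(map$species_cluster_id)
  detected <- rowSums(abundance > 0)
  out <- data.frame(
    species_cluster_id = names(n_genomes),
    n_genomes = as.integer(n_genomes),
    prevalence = as.integer(detected[names(n_genomes)]),
    stringsAsFactors = FALSE
  )
  out$prevalence[is.na(out$prevalence)] <- 0L
  correlation <- if (nrow(out) > 2 && stats::sd(out$prevalence) > 0 &&
                       stats::sd(log10(out$n_genomes)) > 0) {
    stats::cor(log10(out$n_genomes), out$prevalence)
  } else {
    NA_real_
  }
  list(per_species = out, correlation = correlation)
}
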