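# Shared fixtures, built in code.

# A desk-scale scenario: small families/species/depth so full pipelines run
# in well under a second, with the genome length trimmed to keep SNV tables
# small while preserving the related/unrelated separation.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    n_families = 10, n_species = 10, depth_meanlog = log(3e4),
    genome_length = 5e4, seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

# Independent flood-fill connected components (oracle for single linkage).
flood_fill_components <- function(nodes, edge_a, edge_b) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- c(edge_b[edge_a == v], edge_a[edge_b == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

# Adjusted-free Rand index between two labelings of the same items.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Plain GenomeQuality row builder for tier tests.
gq_row <- function(completeness = 95, contamination = 1,
                   completeness2 = NA, contamination2 = NA,
                   r5 = TRUE, rssu = TRUE, rlsu = TRUE, trnas = 20,
                   kingdom = "prokaryote") {
  data.frame(
    genome_id = "g1", sample_id = "s1", kingdom = kingdom,
    completeness_primary = completeness, contamination_primary = contamination,
    completeness_secondary = completeness2, contamination_secondary = contamination2,
    rrna_5s = r5, rrna_ssu = rssu, rrna_lsu = rlsu, n_unique_trnas = trnas,
    n_contigs = 10L, n50 = 50000, mean_depth = 20,
    strain_heterogeneity = 0.2, gunc_contamination = 0.01,
    gunc_css = 0.1, gunc_rrs = 0.2, stringsAsFactors = FALSE
  )
}

# Random metric vectors spanning all tier boundaries (for oracle tests).
random_quality_table <- function(n, seed) {
  set.seed(seed)
  boundary_jitter <- function(n, centers) {
    x <- sample(centers, n, replace = TRUE) +
      sample(c(-0.5, -0.1, 0, 0.1, 0.5), n, replace = TRUE)
    pmin(100, pmax(0, x))
  }
  data.frame(
    genome_id = sprintf("g%05d", seq_len(n)),
    sample_id = "s",
    kingdom = sample(c("prokaryote", "eukaryote"), n, replace = TRUE),
    completeness_primary = boundary_jitter(n, c(50, 70, 90, 95)),
    contamination_primary = boundary_jitter(n, c(0, 2, 5, 10)),
    completeness_secondary = ifelse(stats::runif(n) < 0.2, NA,
                                    boundary_jitter(n, c(50, 70, 90, 95))),
    contamination_secondary = ifelse(stats::runif(n) < 0.2, NA,
                                     boundary_jitter(n, c(0, 2, 5, 10))),
    rrna_5s = stats::runif(n) < 0.7,
    rrna_ssu = stats::runif(n) < 0.7,
    rrna_lsu = stats::runif(n) < 0.7,
    n_unique_trnas = sample(15:20, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Independently coded plain-predicate tiering (the oracle; deliberately a
# different formulation from the package's vectorised rule).
oracle_tier <- function(row, eukaryote = FALSE) {
  c1 <- row$completeness_primary; x1 <- row$contamination_primary
  c2 <- row$completeness_secondary; x2 <- row$contamination_secondary
  rna <- isTRUE(row$rrna_5s) && isTRUE(row$rrna_ssu) && isTRUE(row$rrna_lsu) &&
    row$n_unique_trnas >= 18
  if (c1 > 90 && x1 < 5) {
    if (rna) return("high_quality") else return("near_complete")
  }
  med <- function(cc, xx) {
    if (is.na(cc) || is.na(xx)) return(FALSE)
    if (eukaryote) cc > 50 && xx < 10 else cc > 50 && xx < 10 && cc - 5 * xx > 50
  }
  if (med(c1, x1) || med(c2, x2)) return("medium_quality")
  "fail"
}
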