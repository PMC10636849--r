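#' Build the ANI graph at a threshold
#'
#' Keeps edges with ANI at or above `ani_threshold` and aligned fraction
#' (relative to the larger genome) at or above `min_cov`. When the same
#' unordered pair is reported more than once (for example both directions
#' of the comparison), the record with maximal ANI is kept.
#'
#' @param edges data.frame: `genome_a`, `genome_b`, `ani`,
#'   `aligned_fraction`.
#' @param genomes character vector of all genome ids (isolated nodes are
#'   allowed and become singleton clusters).
#' @param ani_threshold ANI percentage threshold.
#' @param min_cov aligned-fraction threshold.
#' @return an [igraph::graph] with vertex names = genome ids.
#' @export
build_ani_graph <- function(edges, genomes, ani_threshold = 95, min_cov = 0.30) {
  check_columns(edges, c("genome_a", "genome_b", "ani", "aligned_fraction"),
                "ANI edges")
  check_percent(edges$ani, "ani")
  check_fraction(edges$aligned_fraction, "aligned_fraction")
  if (any(edges$genome_a == edges$genome_b)) {
    stop_input("self edges are not allowed in the ANI list")
  }
  unknown <- setdiff(unique(c(edges$genome_a, edges$genome_b)), genomes)
  if (length(unknown)) {
    stop_input("ANI edges reference unknown genome(s): ",
               paste(utils::head(unknown, 5), collapse = ", "))
  }
  ## collapse duplicate records of one unordered pair to the max-ANI record
  key <- ifelse(edges$genome_a < edges$genome_b,
                paste(edges$genome_a, edges$genome_b),
                paste(edges$genome_b, edges$genome_a))
  if (anyDuplicated(key)) {
    ord <- order(key, -edges$ani)
    edges <- edges[ord, ][!duplicated(key[ord]), ]
  }
  keep <- edges$ani >= ani_threshold & edges$aligned_fraction >= min_cov
  el <- edges[keep, c("genome_a", "genome_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = genomes))
  g
}

#' Single-linkage species clusters from an ANI graph
#'
#' Clusters are the connected components of the thresholded graph
#' (single-linkage clustering at the ANI threshold). Cluster ids are
#' deterministic: clusters are numbered by their lexicographically
#' smallest member id.
#'
#' @param graph output of [build_ani_graph()].
#' @return data.frame: `genome_id`, `cluster_id`.
#' @export
cluster_genomes <- function(graph) {
  comp <- igraph::components(graph)
  genome_id <- igraph::V(graph)$name
  membership <- comp$membership
  smallest <- tapply(genome_id, membership, min)
  rank <- match(smallest[as.character(membership)],
                sort(unname(smallest)))
  out <- data.frame(genome_id = genome_id,
                    cluster_id = sprintf("c%04d", rank),
                    stringsAsFactors = FALSE)
  out[order(out$genome_id), , drop = FALSE]
}

#' dRep-style representative score
#'
#' Additive score over the ingredients used for representative selection:
#' completeness, contamination, strain heterogeneity, and contig N50:
#' `completeness - weight_contamination * contamination +
#' contamination * (strain_heterogeneity / 100) + weight_n50 * log10(N50)`.
#' The weights follow the cited dereplication tool's default form and are
#' exposed as arguments.
#'
#' @param g GenomeQuality data.frame.
#' @param weight_contamination,weight_n50 scoring weights.
#' @return numeric score per row.
#' @export
score_genome <- function(g, weight_contamination = 5, weight_n50 = 0.5) {
  check_columns(g, c("completeness_primary", "contamination_primary",
                     "strain_heterogeneity", "n50"), "genome table")
  if (any(g$n50 <= 0)) stop_input("N50 must be positive")
  g$completeness_primary - weight_contamination * g$contamination_primary +
    g$contamination_primary * (g$strain_heterogeneity / 100) +
    weight_n50 * log10(g$n50)
}

#' Select a cluster representative
#'
#' Argmax of the score; ties broken by lexicographically smaller genome id.
#'
#' @param members character vector of genome ids in the cluster.
#' @param scores named numeric vector covering all members.
#' @return the representative genome id.
#' @export
select_representative <- function(members, scores) {
  if (!length(members)) stop_input("empty cluster")
  s <- scores[members]
  if (any(is.na(s))) stop_input("unscored member(s) in cluster")
  cand <- members[s == max(s)]
  min(cand)
}

#' Two-stage dereplication: redundancy removal then species clustering
#'
#' Stage 1 collapses clusters at ANI >= `t1` (99.9 by default, no coverage
#' gate, matching redundancy removal of duplicate recoveries) to their
#' best-scoring representative. Stage 2 clusters the stage-1 survivors at
#' ANI >= `t2` (95) with aligned fraction >= `min_cov` (0.30) and selects
#' a species representative per cluster.
#'
#' @param genomes GenomeQuality data.frame (scored with [score_genome()]).
#' @param edges ANI edge list covering all pairs above roughly 90 percent
#'   similarity.
#' @param t1,t2 stage ANI thresholds.
#' @param min_cov stage-2 aligned-fraction gate (stage 1 uses `min_cov1`).
#' @param min_cov1 stage-1 aligned-fraction gate, default 0.
#' @return list with `genome_table` (genome_id, nonredundant,
#'   species_cluster_id, representative), `nonredundant` ids,
#'   `species` (cluster table over nonredundant genomes), and
#'   `representatives` (species_cluster_id -> genome_id).
#' @export
dereplicate_catalog <- function(genomes, edges, t1 = 99.9, t2 = 95,
                                min_cov = 0.30, min_cov1 = 0) {
  scores <- stats::setNames(score_genome(genomes), genomes$genome_id)
  g1 <- build_ani_graph(edges, genomes$genome_id, t1, min_cov1)
  cl1 <- cluster_genomes(g1)
  nonredundant <- vapply(split(cl1$genome_id, cl1$cluster_id),
                         select_representative, character(1), scores = scores)
  nonredundant <- sort(unname(nonredundant))

  keep_edge <- edges$genome_a %in% nonredundant & edges$genome_b %in% nonredundant
  g2 <- build_ani_graph(edges[keep_edge, , drop = FALSE], nonredundant,
                        t2, min_cov)
  cl2 <- cluster_genomes(g2)
  reps <- vapply(split(cl2$genome_id, cl2$cluster_id),
                 select_representative, character(1), scores = scores)

  ## map every input genome to its species cluster via its stage-1 rep
  stage1_rep <- stats::setNames(
    vapply(split(cl1$genome_id, cl1$cluster_id), select_representative,
           character(1), scores = scores)[cl1$cluster_id],
    cl1$genome_id
  )
  species_of <- stats::setNames(cl2$cluster_id, cl2$genome_id)
  genome_table <- data.frame(
    genome_id = genomes$genome_id,
    nonredundant = genomes$genome_id %in% nonredundant,
    species_cluster_id = unname(species_of[stage1_rep[genomes$genome_id]]),
    stringsAsFactors = FALSE
  )
  genome_table$representative <-
    genome_table$genome_id %in% unname(reps)
  list(genome_table = genome_table, nonredundant = nonredundant,
       species = cl2, representatives = reps)
}

#' Novelty of query representatives against reference catalogs
#'
#' A query representative is `known` iff single-linkage clustering at the
#' species threshold places it in a cluster containing at least one
#' reference genome; otherwise it is `novel`.
#'
#' @param query_reps,reference_reps character vectors of genome ids.
#' @param edges cross-catalog ANI edges on the usual schema.
#' @param ani_threshold,min_cov species-clustering gates.
#' @return list with `labels` (data.frame genome_id, label) and `counts`.
#' @export
assess_novelty <- function(query_reps, reference_reps, edges,
                           ani_threshold = 95, min_cov = 0.30) {
  all_ids <- c(query_reps, reference_reps)
  g <- build_ani_graph(edges, all_ids, ani_threshold, min_cov)
  cl <- cluster_genomes(g)
  ref_clusters <- unique(cl$cluster_id[cl$genome_id %in% reference_reps])
  lab <- ifelse(cl$cluster_id %in% ref_clusters, "known", "novel")
  labels <- data.frame(genome_id = cl$genome_id, label = lab,
                       stringsAsFactors = FALSE)
  labels <- labels[labels$genome_id %in% query_reps, , drop = FALSE]
  rownames(labels) <- NULL
  list(labels = labels,
       counts = c(novel = sum(labels$label == "novel"),
                  known = sum(labels$label == "known")))
}
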