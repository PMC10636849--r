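test_that("ANI graph applies threshold, coverage gate, and max-of-directions", {
  e <- data.frame(genome_a = "a", genome_b = "b", ani = 96, aligned_fraction = 0.5)
  g <- build_ani_graph(e, c("a", "b"), 95, 0.30)
  expect_equal(igraph::gsize(g), 1)

  e$aligned_fraction <- 0.2
  g <- build_ani_graph(e, c("a", "b"), 95, 0.30)
  expect_equal(igraph::gsize(g), 0)

  # both directions reported: the max-ANI record wins
  e2 <- data.frame(genome_a = c("a", "b"), genome_b = c("b", "a"),
                   ani = c(94.9, 95.2), aligned_fraction = c(0.5, 0.5))
  g <- build_ani_graph(e2, c("a", "b"), 95, 0.30)
  expect_equal(igraph::gsize(g), 1)

  expect_error(build_ani_graph(
    data.frame(genome_a = "a", genome_b = "a", ani = 99, aligned_fraction = 1),
    "a", 95, 0.3), "self edges")
  expect_error(build_ani_graph(e, "a", 95, 0.3), "unknown genome")
})

test_that("single-linkage clusters are connected components with stable ids", {
  e <- data.frame(genome_a = c("a", "b"), genome_b = c("b", "c"),
                  ani = c(96, 96), aligned_fraction = c(0.9, 0.9))
  cl <- cluster_genomes(build_ani_graph(e, c("a", "b", "c"), 95, 0.3))
  expect_equal(length(unique(cl$cluster_id)), 1)

  cl0 <- cluster_genomes(build_ani_graph(
    data.frame(genome_a = character(), genome_b = character(),
               ani = numeric(), aligned_fraction = numeric()),
    letters[1:5], 95, 0.3))
  expect_equal(length(unique(cl0$cluster_id)), 5)
})

test_that("components match a brute-force flood fill on random graphs", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    e <- data.frame(genome_a = sample(nodes, m, replace = TRUE),
                    genome_b = sample(nodes, m, replace = TRUE),
                    ani = 99, aligned_fraction = 0.9)
    e <- e[e$genome_a != e$genome_b, , drop = FALSE]
    cl <- cluster_genomes(build_ani_graph(e, nodes, 95, 0.3))
    oracle <- flood_fill_components(nodes, e$genome_a, e$genome_b)
    expect_equal(rand_index(cl$cluster_id[match(nodes, cl$genome_id)],
                            unname(oracle)), 1)
  }
})

test_that("representative score follows the additive dRep-style form", {
  g <- gq_row(100, 0)
  g$n50 <- 1e6; g$strain_heterogeneity <- 0
  expect_equal(score_genome(g), 103)
  # monotone in completeness
  g2 <- rbind(gq_row(95, 1), gq_row(90, 1))
  s <- score_genome(g2)
  expect_gt(s[1], s[2])
  expect_error(score_genome(transform(g, n50 = 0)), "N50")
})

test_that("representative selection is argmax with lexicographic ties", {
  expect_equal(select_representative("a", c(a = 5)), "a")
  expect_equal(select_representative(c("a", "b"), c(a = 90, b = 95)), "b")
  expect_equal(select_representative(c("b", "a"), c(a = 90, b = 90)), "a")
  expect_error(select_representative(character(0), c(a = 1)), "empty")
  # random clusters agree with a brute-force argmax
  set.seed(9)
  for (i in 1:20) {
    ids <- sample(sprintf("g%02d", 1:50), sample(2:10, 1))
    sc <- stats::setNames(round(stats::runif(length(ids)), 2), ids)
    best <- min(ids[sc == max(sc)])
    expect_equal(select_representative(ids, sc), best)
  }
})

test_that("two-stage dereplication collapses duplicates then species", {
  g3 <- do.call(rbind, lapply(1:3, function(i) {
    r <- gq_row(95 - i, 1); r$genome_id <- paste0("g", i); r
  }))
  e <- data.frame(genome_a = c("g1", "g1", "g2"), genome_b = c("g2", "g3", "g3"),
                  ani = 100, aligned_fraction = 0.9)
  d <- dereplicate_catalog(g3, e)
  expect_equal(length(d$nonredundant), 1)
  expect_equal(length(unique(d$species$cluster_id)), 1)
  expect_equal(d$nonredundant, "g1")  # highest completeness wins

  # coverage gate: ANI 97 but aligned fraction 0.25 -> two species
  g2 <- g3[1:2, ]
  e2 <- data.frame(genome_a = "g1", genome_b = "g2", ani = 97,
                   aligned_fraction = 0.25)
  d2 <- dereplicate_catalog(g2, e2)
  expect_equal(length(unique(d2$species$cluster_id)), 2)
})

test_that("the 99.9 partition refines the 95 partition and order is irrelevant", {
  sim <- simulate_scenario(small_config(seed = 21))
  d <- dereplicate_catalog(sim$genomes, sim$ani)
  gt <- d$genome_table
  # refinement: all members of one stage-1 cluster share a species cluster
  stage1 <- cluster_genomes(build_ani_graph(sim$ani, sim$genomes$genome_id,
                                            99.9, 0))
  sp_of <- stats::setNames(gt$species_cluster_id, gt$genome_id)
  for (cl in split(stage1$genome_id, stage1$cluster_id)) {
    expect_equal(length(unique(sp_of[cl])), 1)
  }
  # invariance to edge and genome order
  perm_e <- sim$ani[sample(nrow(sim$ani)), ]
  perm_g <- sim$genomes[sample(nrow(sim$genomes)), ]
  d2 <- dereplicate_catalog(perm_g, perm_e)
  m <- match(gt$genome_id, d2$genome_table$genome_id)
  expect_equal(gt$species_cluster_id, d2$genome_table$species_cluster_id[m])
  expect_equal(sort(d$nonredundant), sort(d2$nonredundant))
})

test_that("dereplication recovers the ground-truth species partition", {
  cfg <- small_config(seed = 5, n_families = 15, n_species = 15,
                      depth_meanlog = log(5e4))
  sim <- simulate_scenario(cfg)
  expect_gt(nrow(sim$genomes), 150)
  d <- dereplicate_catalog(sim$genomes, sim$ani)
  truth <- sim$truth$genomes
  called <- d$genome_table$species_cluster_id[
    match(truth$genome_id, d$genome_table$genome_id)]
  expect_gte(rand_index(called, truth$species_id), 0.95)
  expect_equal(length(unique(d$species$cluster_id)),
               length(unique(truth$species_id)))
})

test_that("novelty labels match a brute-force mixed-component check", {
  # no cross edges at threshold: all queries novel
  empty <- data.frame(genome_a = character(), genome_b = character(),
                      ani = numeric(), aligned_fraction = numeric())
  nv <- assess_novelty(c("q1", "q2"), c("r1"), empty)
  expect_equal(unname(nv$counts["novel"]), 2L)

  e <- data.frame(genome_a = "q1", genome_b = "r1", ani = 96,
                  aligned_fraction = 0.8)
  nv <- assess_novelty(c("q1", "q2"), "r1", e)
  expect_equal(nv$labels$label[nv$labels$genome_id == "q1"], "known")
  expect_equal(nv$labels$label[nv$labels$genome_id == "q2"], "novel")

  set.seed(3)
  for (i in 1:10) {
    q <- sprintf("q%02d", 1:8); r <- sprintf("r%02d", 1:5)
    all_ids <- c(q, r)
    m <- sample(5:20, 1)
    e <- data.frame(genome_a = sample(all_ids, m, replace = TRUE),
                    genome_b = sample(all_ids, m, replace = TRUE),
                    ani = sample(c(90, 97), m, replace = TRUE),
                    aligned_fraction = 0.9)
    e <- e[e$genome_a != e$genome_b, , drop = FALSE]
    nv <- assess_novelty(q, r, e)
    pass <- e[e$ani >= 95, , drop = FALSE]
    comp <- flood_fill_components(all_ids, pass$genome_a, pass$genome_b)
    for (qq in q) {
      expected <- if (any(comp[r] == comp[qq])) "known" else "novel"
      expect_equal(nv$labels$label[nv$labels$genome_id == qq], expected)
    }
  }
})
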