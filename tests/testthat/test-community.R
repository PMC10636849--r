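test_that("depth filter and rarefying produce exact equal-depth columns", {
  set.seed(5)
  tab <- matrix(rpois(60, 40), nrow = 6,
                dimnames = list(sprintf("s%d", 1:6), sprintf("x%d", 1:10)))
  tab[, 1] <- 0:5  # 15 reads, below threshold
  out <- filter_low_depth_and_rarefy(tab, min_reads = 100, depth = 100, seed = 2)
  expect_false("x1" %in% colnames(out))
  expect_true(all(colSums(out) == 100))
  expect_true(all(out <= tab[, colnames(out)]))

  # equal depths rarefied to that depth: unchanged
  eq <- matrix(c(3, 7, 2, 8), nrow = 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(filter_low_depth_and_rarefy(eq, min_reads = 1, depth = 10),
               eq, ignore_attr = TRUE)
  # auto depth = minimum retained total
  auto <- filter_low_depth_and_rarefy(tab, min_reads = 100, seed = 2)
  expect_true(all(colSums(auto) == min(colSums(tab[, -1]))))
})

test_that("richness uses the 5-read rule and Shannon matches the textbook form", {
  tab <- matrix(c(10, 4, 0), ncol = 1, dimnames = list(c("a", "b", "c"), "x"))
  a <- alpha_diversity(tab)
  expect_equal(a$richness, 1L)

  unif <- matrix(rep(10, 7), ncol = 1, dimnames = list(sprintf("s%d", 1:7), "x"))
  expect_equal(alpha_diversity(unif)$shannon, log(7))

  zero <- matrix(0, nrow = 3, ncol = 1, dimnames = list(letters[1:3], "x"))
  expect_equal(alpha_diversity(zero)$richness, 0L)
  expect_equal(alpha_diversity(zero)$shannon, 0)

  set.seed(8)
  tabs <- matrix(rpois(50, 6), nrow = 5,
                 dimnames = list(sprintf("s%d", 1:5), sprintf("x%d", 1:10)))
  got <- alpha_diversity(tabs)$shannon
  oracle <- apply(tabs, 2, function(col) {
    p <- col[col > 0] / sum(col)
    -sum(p * log(p))
  })
  expect_equal(got, unname(oracle), tolerance = 1e-12)
})

test_that("Bray-Curtis on log counts matches a hand computation", {
  tab <- matrix(c(10, 10, 0,
                  0, 0, 5,
                  3, 3, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("sp1", "sp2", "sp3"), c("u", "v", "w")))
  d <- as.matrix(transform_and_distance(tab, prevalence_cut = 0, pseudocount = 1))
  expect_equal(d["u", "v"], 0)
  lu <- log(tab[, "u"] + 1); lw <- log(tab[, "w"] + 1)
  expect_equal(d["u", "w"], sum(abs(lu - lw)) / sum(lu + lw), tolerance = 1e-12)

  # disjoint supports give dissimilarity 1
  dis <- matrix(c(4, 0, 0, 6), nrow = 2,
                dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.matrix(transform_and_distance(dis, 0))["x", "y"], 1)

  # prevalence filter: species in <= 20 percent of samples are dropped
  wide <- matrix(c(rep(5, 10), c(9, rep(0, 9))), nrow = 2, byrow = TRUE,
                 dimnames = list(c("common", "rare"), sprintf("x%d", 1:10)))
  expect_error(transform_and_distance(wide[2, , drop = FALSE], 0.2), "removed")
  d2 <- transform_and_distance(wide, 0.2)
  expect_equal(max(d2), 0)  # only the constant common species survives
})

test_that("PCoA embeds a 3-4-5 triangle and duplicates coincide", {
  d <- matrix(0, 3, 3, dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  d["p", "q"] <- d["q", "p"] <- 3
  d["p", "r"] <- d["r", "p"] <- 4
  d["q", "r"] <- d["r", "q"] <- 5
  fit <- pcoa(d, k = 2)
  got <- as.matrix(dist(fit$coordinates))
  expect_equal(got, d, tolerance = 1e-9)
  expect_lte(sum(fit$explained), 1)

  d4 <- matrix(c(0, 0, 1, 1,
                 0, 0, 1, 1,
                 1, 1, 0, 0.5,
                 1, 1, 0.5, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  fit4 <- pcoa(d4, k = 2)
  expect_equal(fit4$coordinates["a", ], fit4$coordinates["b", ])
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("dyad test separates clear signal and ignores sample order", {
  meta <- data.frame(
    sample_id = c(sprintf("i%d", 1:4), sprintf("m%d", 1:4)),
    subject_id = c(sprintf("I%d", 1:4), sprintf("M%d", 1:4)),
    family_id = rep(sprintf("F%d", 1:4), 2),
    role = rep(c("infant", "mother"), each = 4),
    site = "antecubital",
    age_group = rep(c("12m", "mother"), each = 4)
  )
  d <- matrix(1, 8, 8, dimnames = list(meta$sample_id, meta$sample_id))
  diag(d) <- 0
  for (f in 1:4) d[paste0("i", f), paste0("m", f)] <-
    d[paste0("m", f), paste0("i", f)] <- 0
  res <- dyad_dissimilarity_test(d, meta)
  expect_equal(res$median_related, 0)
  expect_equal(res$median_unrelated, 1)
  expect_lt(res$p_value, 0.05)

  perm <- sample(nrow(meta))
  res2 <- dyad_dissimilarity_test(d[perm, perm], meta[perm, ])
  expect_equal(res2$p_value, res$p_value)

  # relabeling family ids consistently does not change the result
  meta3 <- meta
  meta3$family_id <- paste0("X", meta3$family_id)
  expect_equal(dyad_dissimilarity_test(d, meta3)$p_value, res$p_value)
})

test_that("longitudinal contrast prefers within-individual pairs", {
  meta <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    subject_id = rep(sprintf("I%d", 1:3), each = 2),
    family_id = rep(sprintf("F%d", 1:3), each = 2),
    role = "infant", site = "antecubital",
    age_group = rep(c("2-3m", "12m"), 3)
  )
  d <- matrix(1, 6, 6, dimnames = list(meta$sample_id, meta$sample_id))
  diag(d) <- 0
  for (i in c(1, 3, 5)) d[i, i + 1] <- d[i + 1, i] <- 0.1
  res <- longitudinal_dissimilarity_test(d, meta)
  expect_lt(res$median_within, res$median_between)
})

test_that("kingdom composition normalizes by genome size correctly", {
  tab <- matrix(c(90, 10), ncol = 1, dimnames = list(c("b", "f"), "x"))
  meta <- data.frame(species_id = c("b", "f"), kingdom = c("bacteria", "fungi"),
                     genome_size = c(9, 1))
  raw <- kingdom_composition(tab, meta)
  expect_equal(raw$proportion[raw$kingdom == "bacteria"], 0.9)
  norm <- kingdom_composition(tab, meta, normalize = TRUE)
  expect_equal(sort(norm$proportion), c(0.5, 0.5))
  expect_equal(sum(norm$proportion), 1, tolerance = 1e-12)

  meta_eq <- transform(meta, genome_size = 5)
  expect_equal(kingdom_composition(tab, meta_eq, normalize = TRUE)$proportion,
               raw$proportion)
  expect_error(kingdom_composition(tab, transform(meta, genome_size = NA),
                                   normalize = TRUE), "genome size")
})
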