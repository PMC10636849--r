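#' Run every generator stage for one scenario
#'
#' Convenience wrapper chaining [generate_species_pool()],
#' [generate_samples_and_abundances()], [generate_genome_recoveries()],
#' [generate_strain_transmission()], [generate_gene_matrix()], and
#' [generate_classification_fractions()] under the per-stage seed
#' substreams of `config$seed`.
#'
#' @param config a [scenario_config()].
#' @param gene_min_genomes passed to [generate_gene_matrix()].
#' @return list with elements `config`, `pool`, `samples`, `abundance`,
#'   `genomes`, `ani`, `viral`, `snv`, `pairwise`, `st_isolates`,
#'   `st_profiles`, `scheme`, `typed_species`, `genes`, `gene_meta`,
#'   `classified`, `truth`.
#' @export
simulate_scenario <- function(config, gene_min_genomes = 2) {
  pool <- generate_species_pool(config)
  abund <- generate_samples_and_abundances(config, pool)
  recov <- generate_genome_recoveries(config, abund, pool)
  strains <- generate_strain_transmission(config, recov$truth)
  gm <- generate_gene_matrix(config, recov$truth, recov$genomes,
                             min_genomes = gene_min_genomes)
  classified <- generate_classification_fractions(config, abund$samples$sample_id)
  list(
    config = config, pool = pool,
    samples = abund$samples, abundance = abund$abundance,
    genomes = recov$genomes, ani = recov$ani, viral = recov$viral,
    snv = strains$snv, pairwise = strains$pairwise,
    st_isolates = strains$st_isolates, st_profiles = strains$st_profiles,
    scheme = strains$scheme, typed_species = strains$typed_species,
    genes = gm$genes, gene_meta = gm$gene_meta,
    classified = classified, truth = recov$truth
  )
}

scenario_tables <- c("pool", "samples", "genomes", "ani", "viral", "snv",
                     "pairwise", "st_isolates", "st_profiles", "scheme",
                     "genes", "gene_meta", "classified")

#' Write a simulated scenario to a directory of TSV files
#'
#' Writes each table as plain TSV plus the abundance matrix
#' (`abundance.tsv`, species in rows) and ground-truth labels
#' (`truth.json`). Reading the directory back with [read_scenario()] is
#' lossless for every table.
#'
#' @param sim output of [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in scenario_tables) {
    if (!is.null(sim[[nm]])) {
      write_tsv_file(sim[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  ab <- data.frame(species_id = rownames(sim$abundance), sim$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(ab, file.path(dir, "abundance.tsv"))
  truth <- sim$truth
  truth$typed_species <- sim$typed_species
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scenario directory written by [write_scenario()]
#'
#' @param dir directory path.
#' @return list of tables mirroring [simulate_scenario()] output (without
#'   `config`).
#' @export
read_scenario <- function(dir) {
  out <- list()
  for (nm in scenario_tables) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(path)) out[[nm]] <- read_tsv_file(path)
  }
  ab <- read_tsv_file(file.path(dir, "abundance.tsv"), check.names = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ab$species_id
  out$abundance <- m
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    out$typed_species <- tr$typed_species
    tr$typed_species <- NULL
    for (nm in c("genomes", "transmitted", "pool")) {
      if (!is.null(tr[[nm]]) && !is.data.frame(tr[[nm]])) {
        tr[[nm]] <- as.data.frame(tr[[nm]], stringsAsFactors = FALSE)
      }
    }
    out$truth <- tr
  }
  out
}
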