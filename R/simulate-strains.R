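#' Generate strain-level SNVs, pairwise distances, and MLST profiles
#'
#' Makes the vertical-transmission mechanism explicit. Each strain lineage
#' descends from its species ancestor (the reference coordinate system of
#' length `L`) through a lineage branch of length
#' `divergence_time_unrelated - divergence_time_related`, and every genome
#' adds a private terminal branch of length `divergence_time_related`.
#' Substitutions accumulate as Poisson(`mu` x branch x `L`) events placed
#' uniformly on the shared coordinate system (infinite-sites
#' approximation, saturating at `L` sites with a warning). A transmitted
#' infant genome sits on the maternal lineage, so a related mother-infant
#' pair differs at about `2 mu t_related L` sites while unrelated pairs
#' differ at about `2 mu t_unrelated L` sites. Lineage-branch substitutions
#' are shared by all genomes of a lineage and therefore survive the
#' downstream two-genome occurrence filter; terminal substitutions are
#' private.
#'
#' Sequence typing emulates cultured isolates of the most prevalent
#' bacterial species: every distinct lineage owns a 7-locus allele
#' profile, individuals carry one or two lineages, and each individual
#' contributes `n_isolates_range` isolates typed against the scheme built
#' from all observed profiles.
#'
#' @param config a [scenario_config()].
#' @param truth ground truth from [generate_genome_recoveries()].
#' @return list with `snv` (species_id, genome_id, position, ref, alt),
#'   `pairwise` (genome_a, genome_b, species_id, n_snvs, relationship),
#'   `st_isolates`, `st_profiles`, `scheme`, and `typed_species`.
#' @export
generate_strain_transmission <- function(config, truth) {
  stopifnot(inherits(config, "scenario_config"))
  check_fraction(config$sharing_prob, "sharing_prob")
  gt <- truth$genomes
  with_seed(stage_seed(config$seed, "strains"), {
    L <- as.integer(config$genome_length)
    mu <- config$mutation_rate
    t_r <- config$divergence_time_related
    t_u <- config$divergence_time_unrelated
    bases <- c("A", "C", "G", "T")

    draw_mutations <- function(expected) {
      n <- stats::rpois(1, expected)
      if (n > L) {
        warning("expected substitutions exceed genome length; saturating at L",
                call. = FALSE)
        n <- L
      }
      pos <- sample.int(L, n)
      ref <- sample(4L, n, replace = TRUE)
      alt <- 1L + (ref - 1L + sample(3L, n, replace = TRUE)) %% 4L
      list(pos = pos, ref = ref, alt = alt)
    }

    acc_sp <- list(); acc_g <- list(); acc_pos <- list()
    acc_ref <- list(); acc_alt <- list()
    keysets <- new.env(parent = emptyenv())

    for (sp in unique(gt$species_id)) {
      gsp <- gt[gt$species_id == sp, , drop = FALSE]
      lineages <- unique(gsp$lineage_id)
      lin_mut <- lapply(stats::setNames(lineages, lineages), function(l) {
        draw_mutations(mu * max(t_u - t_r, 0) * L)
      })
      for (i in seq_len(nrow(gsp))) {
        lm <- lin_mut[[gsp$lineage_id[i]]]
        tm <- draw_mutations(mu * t_r * L)
        keep <- !(tm$pos %in% lm$pos)
        pos <- c(lm$pos, tm$pos[keep])
        g <- gsp$genome_id[i]
        k <- length(acc_pos) + 1L
        acc_sp[[k]] <- rep(sp, length(pos))
        acc_g[[k]] <- rep(g, length(pos))
        acc_pos[[k]] <- pos
        acc_ref[[k]] <- c(lm$ref, tm$ref[keep])
        acc_alt[[k]] <- c(lm$alt, tm$alt[keep])
        assign(g, pos * 4 + (acc_alt[[k]] - 1L), envir = keysets)
      }
    }
    snv <- data.frame(
      species_id = unlist(acc_sp), genome_id = unlist(acc_g),
      position = unlist(acc_pos), ref = bases[unlist(acc_ref)],
      alt = bases[unlist(acc_alt)], stringsAsFactors = FALSE
    )

    pairwise <- build_pairwise_snv(gt, keysets)
    st <- simulate_sequence_typing(config, truth)

    c(list(snv = snv, pairwise = pairwise), st)
  })
}

build_pairwise_snv <- function(gt, keysets) {
  count_diff <- function(a, b) {
    ka <- get(a, envir = keysets); kb <- get(b, envir = keysets)
    length(ka) + length(kb) - 2L * sum(ka %in% kb)
  }
  blocks <- list()
  for (sp in unique(gt$species_id)) {
    gsp <- gt[gt$species_id == sp, , drop = FALSE]
    inf <- gsp[gsp$role == "infant", , drop = FALSE]
    mom <- gsp[gsp$role == "mother", , drop = FALSE]
    if (nrow(inf) && nrow(mom)) {
      idx <- expand.grid(i = seq_len(nrow(inf)), j = seq_len(nrow(mom)))
      blocks[[length(blocks) + 1L]] <- data.frame(
        genome_a = inf$genome_id[idx$i],
        genome_b = mom$genome_id[idx$j],
        species_id = sp,
        n_snvs = mapply(count_diff, inf$genome_id[idx$i], mom$genome_id[idx$j],
                        USE.NAMES = FALSE),
        relationship = ifelse(inf$family_id[idx$i] == mom$family_id[idx$j],
                              "related_pair", "unrelated_pair"),
        stringsAsFactors = FALSE
      )
    }
    for (subj in unique(gsp$subject_id)) {
      gs <- gsp$genome_id[gsp$subject_id == subj]
      if (length(gs) < 2) next
      pr <- utils::combn(gs, 2)
      blocks[[length(blocks) + 1L]] <- data.frame(
        genome_a = pr[1, ], genome_b = pr[2, ], species_id = sp,
        n_snvs = mapply(count_diff, pr[1, ], pr[2, ], USE.NAMES = FALSE),
        relationship = "same_individual", stringsAsFactors = FALSE
      )
    }
  }
  if (!length(blocks)) {
    return(data.frame(genome_a = character(), genome_b = character(),
                      species_id = character(), n_snvs = integer(),
                      relationship = character()))
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

simulate_sequence_typing <- function(config, truth) {
  pool <- truth$pool
  bact <- pool[pool$kingdom == "bacteria", , drop = FALSE]
  if (!nrow(bact)) {
    return(list(st_isolates = NULL, st_profiles = NULL, scheme = NULL,
                typed_species = NA_character_))
  }
  typed <- bact$species_id[order(-bact$prevalence, bact$species_id)][1]
  tr <- truth$transmitted
  tr <- tr[tr$species_id == typed, , drop = FALSE]
  families <- sort(unique(tr$family_id))

  ## lineages carried per individual
  carried <- list()
  for (f in families) {
    transmitted <- tr$transmitted[tr$family_id == f]
    lm <- paste0("lin_", f, "_", typed, "_m")
    lm2 <- paste0("lin_", f, "_", typed, "_m2")
    li <- paste0("lin_", f, "_", typed, "_i")
    mother_lin <- c(lm, if (stats::runif(1) < config$p_second_lineage) lm2)
    infant_lin <- if (transmitted) {
      c(lm, if (stats::runif(1) < config$p_second_lineage) li)
    } else {
      li
    }
    carried[[paste0("M_", f)]] <- mother_lin
    carried[[paste0("I_", f)]] <- infant_lin
  }

  all_lineages <- sort(unique(unlist(carried)))
  profiles <- matrix(sample.int(config$st_alleles,
                                length(all_lineages) * config$st_loci,
                                replace = TRUE),
                     nrow = length(all_lineages),
                     dimnames = list(all_lineages, NULL))
  prof_key <- apply(profiles, 1, paste, collapse = "-")
  st_of_key <- stats::setNames(sprintf("ST%02d", seq_along(unique(prof_key))),
                               unique(prof_key))
  lineage_st <- st_of_key[prof_key]
  names(lineage_st) <- all_lineages

  scheme <- data.frame(st = unname(st_of_key),
                       do.call(rbind, strsplit(names(st_of_key), "-")),
                       stringsAsFactors = FALSE)
  names(scheme) <- c("st", paste0("locus_", seq_len(config$st_loci)))
  for (j in seq_len(config$st_loci)) {
    scheme[[j + 1]] <- as.integer(scheme[[j + 1]])
  }

  iso <- list()
  for (ind in names(carried)) {
    role <- if (startsWith(ind, "M_")) "mother" else "infant"
    fam <- sub("^[MI]_", "", ind)
    n_iso <- sample(seq(config$n_isolates_range[1], config$n_isolates_range[2]), 1)
    lins <- carried[[ind]]
    picked <- lins[sample.int(length(lins), n_iso, replace = TRUE)]
    iso[[length(iso) + 1L]] <- data.frame(
      individual_id = ind, family_id = fam, role = role,
      lineage_id = picked, st = unname(lineage_st[picked]),
      stringsAsFactors = FALSE
    )
  }
  st_isolates <- do.call(rbind, iso)
  st_isolates$isolate_id <- sprintf("iso%04d", seq_len(nrow(st_isolates)))
  st_isolates <- st_isolates[, c("isolate_id", "individual_id", "family_id",
                                 "role", "lineage_id", "st")]
  st_profiles <- unique(st_isolates[, c("individual_id", "family_id", "role", "st")])
  rownames(st_profiles) <- NULL
  list(st_isolates = st_isolates, st_profiles = st_profiles,
       scheme = scheme, typed_species = typed)
}
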