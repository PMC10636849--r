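#' Generate a synthetic species pool
#'
#' Draws a pool of skin-associated species with per-species prevalence,
#' mean relative abundance, kingdom, and genome size. Kingdom proportions
#' and abundance distributions are configurable; defaults emulate a
#' bacteria-dominated skin community with a minority of fungi and
#' eukaryotic viruses.
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns `species_id`, `kingdom`, `prevalence`,
#'   `mean_abundance`, `genome_size`.
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_species < 2) stop_input("n_species must be at least 2")
  with_seed(stage_seed(config$seed, "pool"), {
    n <- config$n_species
    kingdom <- sample(names(config$kingdom_props), n, replace = TRUE,
                      prob = config$kingdom_props)
    prevalence <- pmin(1, pmax(0.02, stats::rbeta(n, 1.3, 2.2)))
    mean_abundance <- stats::rlnorm(n, meanlog = log(0.01), sdlog = 1.5)
    size_meanlog <- c(bacteria = log(2.5e6), fungi = log(1.2e7), virus = log(4e4))
    size_sdlog <- c(bacteria = 0.30, fungi = 0.25, virus = 0.50)
    genome_size <- round(stats::rlnorm(n, size_meanlog[kingdom], size_sdlog[kingdom]))
    data.frame(
      species_id = sprintf("sp%03d", seq_len(n)),
      kingdom = kingdom,
      prevalence = prevalence,
      mean_abundance = mean_abundance,
      genome_size = genome_size,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate sample metadata and a species-by-sample count table
#'
#' Emulates the study design downstream analyses assume: each family has
#' one mother sample (antecubital fossa only) and an infant sampled at up
#' to two sites and up to two ages (a configurable fraction of infants is
#' longitudinal). Carriage and abundance derive from a latent Gaussian per
#' subject and species whose within-family correlation is
#' `relatedness_cor`, so related mother-infant dyads receive correlated
#' community draws; site and age effects enter as per-species log-fold
#' shifts.
#'
#' @param config a [scenario_config()].
#' @param pool species pool from [generate_species_pool()].
#' @return list with `abundance` (integer matrix, species x samples) and
#'   `samples` (data.frame: sample_id, subject_id, family_id, role, site,
#'   age_group).
#' @export
generate_samples_and_abundances <- function(config, pool) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(pool) == 0) stop_input("species pool is empty")
  with_seed(stage_seed(config$seed, "samples"), {
    nf <- config$n_families
    ns <- nrow(pool)
    infant_ages <- setdiff(config$ages, "mother")
    longitudinal <- stats::runif(nf) < config$prob_longitudinal

    rows <- list()
    for (f in seq_len(nf)) {
      fam <- sprintf("F%03d", f)
      ages_f <- if (longitudinal[f] || length(infant_ages) == 1) {
        infant_ages
      } else {
        infant_ages[length(infant_ages)]
      }
      for (age in ages_f) {
        for (site in config$sites) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sprintf("I%03d", f), family_id = fam,
            role = "infant", site = site, age_group = age,
            stringsAsFactors = FALSE
          )
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("M%03d", f), family_id = fam,
        role = "mother", site = "antecubital", age_group = "mother",
        stringsAsFactors = FALSE
      )
    }
    samples <- do.call(rbind, rows)
    samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
    samples <- samples[, c("sample_id", "subject_id", "family_id",
                           "role", "site", "age_group")]

    ## Latent per-subject species deviations, correlated within families.
    subjects <- unique(samples[, c("subject_id", "family_id")])
    rho <- config$relatedness_cor
    z_fam <- matrix(stats::rnorm(nf * ns), nrow = nf,
                    dimnames = list(sprintf("F%03d", seq_len(nf)), NULL))
    eps <- matrix(stats::rnorm(nrow(subjects) * ns), nrow = nrow(subjects))
    z_subj <- sqrt(rho) * z_fam[subjects$family_id, , drop = FALSE] +
      sqrt(1 - rho) * eps
    rownames(z_subj) <- subjects$subject_id

    tau <- stats::qnorm(1 - pool$prevalence)
    carried <- sweep(z_subj, 2, tau, `>`)

    site_eff <- matrix(0, nrow = ns, ncol = length(config$sites),
                       dimnames = list(NULL, config$sites))
    if (length(config$sites) > 1) {
      site_eff[, -1] <- stats::rnorm(ns * (length(config$sites) - 1),
                                     sd = config$site_effect_sd)
    }
    age_eff <- matrix(0, nrow = ns, ncol = length(config$ages),
                      dimnames = list(NULL, config$ages))
    if (length(config$ages) > 1) {
      age_eff[, -1] <- stats::rnorm(ns * (length(config$ages) - 1),
                                    sd = config$age_effect_sd)
    }

    depth <- round(stats::rlnorm(nrow(samples), config$depth_meanlog,
                                 config$depth_sdlog))
    abundance <- matrix(0L, nrow = ns, ncol = nrow(samples),
                        dimnames = list(pool$species_id, samples$sample_id))
    for (i in seq_len(nrow(samples))) {
      subj <- samples$subject_id[i]
      lw <- log(pool$mean_abundance) +
        config$abundance_sigma * z_subj[subj, ] +
        site_eff[, samples$site[i]] + age_eff[, samples$age_group[i]] +
        stats::rnorm(ns, sd = 0.3)
      w <- ifelse(carried[subj, ], exp(lw), 0)
      if (sum(w) == 0) w <- rep(1, ns)
      abundance[, i] <- stats::rmultinom(1, depth[i], w)[, 1]
    }
    storage.mode(abundance) <- "integer"
    list(abundance = abundance, samples = samples)
  })
}
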