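#' Assign a sequence type from a 7-locus allele profile
#'
#' Exact lookup of the profile in the scheme; profiles not in the scheme
#' are `"novel"` with the Hamming distance (number of differing loci) to
#' the nearest known profile reported as an aid.
#'
#' @param alleles integer vector of allele numbers, one per scheme locus.
#' @param scheme data.frame: `st` plus one `locus_*` column per locus.
#' @return list with `st` (`"novel"` when unmatched) and
#'   `nearest_distance` (0 for exact matches).
#' @export
assign_sequence_type <- function(alleles, scheme) {
  loci <- grep("^locus_", names(scheme), value = TRUE)
  if (length(alleles) != length(loci)) {
    stop_input("profile has ", length(alleles), " alleles; scheme has ",
               length(loci), " loci")
  }
  prof <- as.matrix(scheme[, loci, drop = FALSE])
  dist <- rowSums(prof != matrix(alleles, nrow(prof), length(alleles), byrow = TRUE))
  hit <- which(dist == 0)
  if (length(hit)) {
    list(st = scheme$st[hit[1]], nearest_distance = 0L)
  } else {
    list(st = "novel", nearest_distance = as.integer(min(dist)))
  }
}

## normalize a profile table (individual_id, family_id, role, st) into a
## per-family list of infant/mother ST sets
family_st_sets <- function(profiles) {
  check_columns(profiles, c("family_id", "role", "st"), "ST profiles")
  fams <- sort(unique(profiles$family_id))
  sets <- list()
  dropped <- character(0)
  for (f in fams) {
    inf <- unique(profiles$st[profiles$family_id == f & profiles$role == "infant"])
    mom <- unique(profiles$st[profiles$family_id == f & profiles$role == "mother"])
    if (!length(inf) || !length(mom)) {
      dropped <- c(dropped, f)
      next
    }
    sets[[f]] <- list(infant = inf, mother = mom)
  }
  if (length(dropped)) {
    message("excluded incomplete family(ies): ", paste(dropped, collapse = ", "))
  }
  sets
}

#' Count families whose infant and mother share a sequence type
#'
#' @param profiles data.frame: `individual_id`, `family_id`, `role`, `st`
#'   (one row per observed ST per individual). Families missing either
#'   member are excluded with a message.
#' @return integer count of families with a nonempty ST intersection.
#' @export
st_sharing_stat <- function(profiles) {
  sets <- family_st_sets(profiles)
  sum(vapply(sets, function(s) length(intersect(s$infant, s$mother)) > 0,
             logical(1)))
}

#' Permutation test for mother-infant sequence-type sharing
#'
#' The observed statistic is [st_sharing_stat()]; the null permutes the
#' mother-to-infant pairing (all pairings admissible, not only
#' derangements). Monte-Carlo mode draws `n_perm` pairings and reports
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`; exact mode enumerates
#' all `n!` pairings (allowed for up to 8 families) and reports the exact
#' tail probability `#\{null >= observed\} / n!`.
#'
#' @param profiles as in [st_sharing_stat()].
#' @param n_perm Monte-Carlo permutation count (default 1000).
#' @param seed integer seed for Monte-Carlo mode.
#' @param mode `"monte_carlo"` or `"exact"`.
#' @return list with `observed`, `p_value`, `null` (statistic per
#'   permutation), and `mode`.
#' @export
st_permutation_test <- function(profiles, n_perm = 1000, seed = 1,
                                mode = c("monte_carlo", "exact")) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop_input("n_perm must be at least 1")
  sets <- family_st_sets(profiles)
  n <- length(sets)
  if (n < 2) stop_input("need at least two complete families")
  inf <- lapply(sets, `[[`, "infant")
  mom <- lapply(sets, `[[`, "mother")
  stat <- function(perm) {
    sum(vapply(seq_len(n),
               function(i) length(intersect(inf[[i]], mom[[perm[i]]])) > 0,
               logical(1)))
  }
  observed <- stat(seq_len(n))
  if (mode == "exact") {
    if (n > 8) stop_input("exact enumeration limited to 8 families")
    perms <- permutations_of(n)
    null <- vapply(perms, stat, numeric(1))
    p <- sum(null >= observed) / length(null)
  } else {
    null <- with_seed(stage_seed(seed, "st_perm"), {
      replicate(n_perm, stat(sample.int(n)))
    })
    p <- (1 + sum(null >= observed)) / (1 + n_perm)
  }
  list(observed = observed, p_value = p, null = null, mode = mode)
}

## all permutations of 1..n as a list (n <= 8: at most 40320)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = i - 1L)
    }
  }
  out
}
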