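## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name, allow_na = FALSE) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (allow_na) {
    if (any(bad)) stop_input(name, " must lie in [0, 1]")
  } else if (any(is.na(x)) || any(bad)) {
    stop_input(name, " must lie in [0, 1] with no missing values")
  }
  invisible(x)
}

check_percent <- function(x, name, allow_na = FALSE) {
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad) || (!allow_na && any(is.na(x)))) {
    stop_input(name, " must be a percentage in [0, 100]")
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input(name, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

## Deterministic per-stage seed derivation so that adding or re-running one
## generator stage never perturbs the draws of another.
stage_seed <- function(seed, stage) {
  offsets <- c(
    pool = 11L, samples = 23L, genomes = 37L, strains = 41L,
    genes = 53L, classified = 67L, rarefy = 71L, rarefaction = 83L,
    st_perm = 97L, dyad = 101L
  )
  if (!stage %in% names(offsets)) stop_input("unknown RNG substream: ", stage)
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
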