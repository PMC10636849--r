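# Shared settings for the numbered analysis drivers. Every script sources
# this file, so one seed and one scenario definition govern the whole run.

library(skincat)

ANALYSIS_SEED <- 20240917
RESULTS_DIR <- "results"
SCENARIO_DIR <- file.path(RESULTS_DIR, "scenario")

analysis_config <- function() scenario_config(seed = ANALYSIS_SEED)

ensure_dir <- function(path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  path
}

save_table <- function(df, name) {
  ensure_dir(RESULTS_DIR)
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
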