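# Shared setup for the analysis drivers: seed handling and output locations.
suppressPackageStartupMessages(library(affnet))

arg_seed <- function(default = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i)) as.integer(args[i + 1L]) else default
}

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
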