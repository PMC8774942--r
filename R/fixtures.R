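#' Packaged fixture bundle: published-table transcriptions and synthetic
#' stand-ins
#'
#' Loads the plain-text fixtures shipped under \code{inst/extdata}:
#' \itemize{
#'   \item \code{table2_genes} — the 132 genes of the published recurrence
#'     table (a gene with a prioritized rare variant in >= 2 AFF cases).
#'   \item \code{table2_counts} — per-gene variant/carrier/homozygote counts
#'     with recurrence category.
#'   \item \code{table3_genes} — the 12 published bone/AFF candidate genes.
#'   \item \code{bone_candidates} — fixture bone/AFF literature list
#'     (candidate genes plus canonical bone-biology genes not in the
#'     recurrence table).
#'   \item \code{s31_variants} — the DAAM2/LRP5 worked-example variant
#'     enumerations as a variant-call table (synthetic coordinates).
#'   \item \code{prior_sisters} — synthetic 34-gene stand-in for the prior
#'     3-sisters study list.
#'   \item \code{all_mutated} — synthetic 455-gene stand-in for the cohort's
#'     full mutated-gene list.
#'   \item \code{damaging} — synthetic stand-in for the damaging-variant
#'     gene set.
#' }
#'
#' @param outdir optional directory; when given, the fixture files are also
#'   copied there.
#' @return named list of gene sets / data frames as described.
#' @export
paper_fixtures <- function(outdir = NULL) {
  p <- function(f) system.file("extdata", f, package = "affnet",
                               mustWork = TRUE)
  files <- c("table2_genes.txt", "table2_counts.tsv", "table3_genes.txt",
             "bone_candidates_fixture.txt", "s31_variants.tsv",
             "prior_sisters34_synthetic.txt", "all_mutated_synthetic.txt",
             "damaging_genes_synthetic.txt")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    file.copy(vapply(files, p, character(1)), outdir, overwrite = TRUE)
  }
  counts <- utils::read.delim(p("table2_counts.tsv"), comment.char = "#",
                              stringsAsFactors = FALSE)
  list(
    table2_genes = read_gene_list(p("table2_genes.txt"), "table2"),
    table2_counts = counts,
    table3_genes = read_gene_list(p("table3_genes.txt"), "table3"),
    bone_candidates = read_gene_list(p("bone_candidates_fixture.txt"),
                                     "bone_candidates"),
    s31_variants = read_variant_table(p("s31_variants.tsv"), "tsv"),
    prior_sisters = read_gene_list(p("prior_sisters34_synthetic.txt"),
                                   "prior_sisters"),
    all_mutated = read_gene_list(p("all_mutated_synthetic.txt"),
                                 "all_mutated"),
    damaging = read_gene_list(p("damaging_genes_synthetic.txt"), "damaging")
  )
}
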