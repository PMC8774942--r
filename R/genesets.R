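#' Named gene sets
#'
#' A gene set is a named, deterministically ordered collection of gene
#' symbols. Membership is case-insensitive; the first-seen spelling of each
#' symbol is kept and symbols are stored in lexicographic (C-locale) order.
#'
#' @param name non-empty label.
#' @param symbols character vector of gene symbols.
#' @param provenance free-text source note.
#' @return object of class \code{"gene_set"}.
#' @export
gene_set <- function(name, symbols, provenance = "") {
  if (!nzchar(name)) stop_affnet("gene set name must be non-empty")
  structure(list(name = name, symbols = unique_symbols(as.character(symbols)),
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$symbols), " symbols\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Read a gene list file (one symbol per line, `#` comments)
#'
#' @param path file path.
#' @param name set label; defaults to the file name.
#' @return \code{\link{gene_set}}.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  gene_set(name, lines[nzchar(lines)], provenance = path)
}

#' Write a gene list file
#'
#' @param gs \code{\link{gene_set}}.
#' @param path output path.
#' @export
write_gene_list <- function(gs, path) {
  writeLines(c(paste0("# ", gs$name), gs$symbols), path)
  invisible(path)
}

#' Read a GMT-style term collection
#'
#' Each tab-separated line is \code{term, description, symbol, symbol, ...}.
#'
#' @param path file path.
#' @return named list of \code{\link{gene_set}} objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_affnet("GMT line needs term, description, >=1 symbol: ", ln)
    gene_set(f[1], f[-(1:2)], provenance = f[2])
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Gene-set intersection (case-insensitive)
#'
#' @param a,b \code{\link{gene_set}} objects.
#' @return \code{gene_set} named \code{"a∩b"} holding symbols present in both.
#' @export
gs_intersect <- function(a, b) {
  keep <- fold_symbol(a$symbols) %in% fold_symbol(b$symbols)
  gene_set(paste0(a$name, "∩", b$name), a$symbols[keep],
           provenance = "intersection")
}

#' Gene-set difference (case-insensitive)
#'
#' @param a,b \code{\link{gene_set}} objects.
#' @return \code{gene_set} of symbols in \code{a} but not \code{b}.
#' @export
gs_setdiff <- function(a, b) {
  keep <- !fold_symbol(a$symbols) %in% fold_symbol(b$symbols)
  gene_set(paste0(a$name, "\\", b$name), a$symbols[keep],
           provenance = "difference")
}

#' Gene-set union (case-insensitive)
#'
#' @param a,b \code{\link{gene_set}} objects.
#' @return \code{gene_set} of symbols in either input.
#' @export
gs_union <- function(a, b) {
  gene_set(paste0(a$name, "∪", b$name), c(a$symbols, b$symbols),
           provenance = "union")
}

#' Overlap of cohort-mutated genes with a prior study's gene list
#'
#' Reports which genes mutated in the present cohort were also mutated in a
#' prior study, and which of those additionally carry damaging
#' (post-prioritization) variants here.
#'
#' @param all_mutated genes with any rare variant in the cohort.
#' @param prior the prior study's gene list.
#' @param damaging genes surviving damaging-variant prioritization.
#' @return list with \code{overlap} and \code{damaging_overlap}
#'   \code{\link{gene_set}}s.
#' @export
overlap_with_prior <- function(all_mutated, prior, damaging) {
  if (!length(prior$symbols)) warn_affnet("prior gene list is empty")
  overlap <- gs_intersect(all_mutated, prior)
  overlap$name <- "prior_overlap"
  damaging_overlap <- gs_intersect(overlap, damaging)
  damaging_overlap$name <- "prior_overlap_damaging"
  list(overlap = overlap, damaging_overlap = damaging_overlap)
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, tests over-representation of the query in the term with the
#' hypergeometric upper tail P(X >= k), where k = |query ∩ term|, K = |term|,
#' n = |query|, N = |universe|, followed by Benjamini-Hochberg adjustment
#' across terms.
#'
#' @param query \code{\link{gene_set}} of genes of interest; must be a subset
#'   of the universe.
#' @param terms list of \code{\link{gene_set}} terms; symbols outside the
#'   universe are dropped per term.
#' @param universe \code{\link{gene_set}} defining the background.
#' @param adjust multiple-testing method passed to \code{stats::p.adjust}
#'   (default \code{"BH"}).
#' @return data frame sorted by p-value: term, k, K, n, N, p_value, q_value.
#' @export
hypergeom_enrichment <- function(query, terms, universe, adjust = "BH") {
  uni <- fold_symbol(universe$symbols)
  q <- fold_symbol(query$symbols)
  offenders <- setdiff(q, uni)
  if (length(offenders)) {
    stop_affnet("query symbols outside universe: ", paste(offenders, collapse = ", "))
  }
  n <- length(q); N <- length(uni)
  rows <- lapply(terms, function(term) {
    tt <- intersect(fold_symbol(term$symbols), uni)
    k <- length(intersect(q, tt)); K <- length(tt)
    # upper tail P(X >= k) for X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term$name, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = adjust)
  out <- out[order(out$p_value, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
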