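#' Aggregate surviving case variants by gene
#'
#' Collapses a filtered variant-call table to one record per gene: the set of
#' distinct variants, the set of distinct carrier samples (a sample counts
#' once however many qualifying variants it carries in the gene), the number
#' of carriers with a homozygous call, and whether any single variant is
#' shared by two or more distinct cases. Gene symbols are matched
#' case-insensitively; the first-seen spelling is reported.
#'
#' @param calls variant-call table restricted to case samples.
#' @param case_ids character vector of case sample ids; every call must come
#'   from one of them.
#' @return data frame with one row per gene: \code{gene}, \code{n_variants},
#'   \code{n_carriers}, \code{n_hom}, \code{shared_variant}, \code{category}
#'   (see \code{\link{classify_recurrence}}), plus list-columns
#'   \code{variant_ids} and \code{carrier_ids}.
#' @export
aggregate_by_gene <- function(calls, case_ids) {
  calls <- as_variant_calls(calls)
  stray <- setdiff(unique(calls$sample_id), case_ids)
  if (length(stray)) {
    stop_affnet("call(s) from non-case sample(s): ", paste(stray, collapse = ", "))
  }
  if (!nrow(calls)) {
    return(data.frame(gene = character(), n_variants = integer(),
                      n_carriers = integer(), n_hom = integer(),
                      shared_variant = logical(), category = character(),
                      stringsAsFactors = FALSE))
  }
  key <- fold_symbol(calls$gene)
  display <- calls$gene[!duplicated(key)]
  names(display) <- key[!duplicated(key)]
  vids <- variant_id(calls)

  recs <- lapply(split(seq_len(nrow(calls)), key), function(i) {
    sub <- calls[i, , drop = FALSE]
    vi <- vids[i]
    carriers <- unique(sub$sample_id)
    hom_carriers <- unique(sub$sample_id[sub$zygosity == "homozygous"])
    shared <- any(vapply(split(sub$sample_id, vi),
                         function(s) length(unique(s)) >= 2L, logical(1)))
    data.frame(
      gene = display[[fold_symbol(sub$gene[1])]],
      n_variants = length(unique(vi)),
      n_carriers = length(carriers),
      n_hom = length(hom_carriers),
      shared_variant = shared,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  out <- out[order(fold_symbol(out$gene), method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out$category <- classify_recurrence(out)
  out$variant_ids <- lapply(split(vids, key), function(v) sort(unique(v)))[
    fold_symbol(out$gene)]
  out$carrier_ids <- lapply(split(calls$sample_id, key),
                            function(s) sort(unique(s)))[fold_symbol(out$gene)]
  out
}

#' Classify gene recurrence
#'
#' Category semantics mirror how recurrent genes are tabulated across AFF
#' cases: carriers in more than two cases; exactly two cases sharing one
#' identical variant; exactly two cases with two different variants; and
#' singletons (fewer than two carriers). A gene with two carriers where one
#' carries several variants including the shared one is classified by the
#' shared variant.
#'
#' @param records data frame with columns \code{n_carriers} and
#'   \code{shared_variant} (as from \code{\link{aggregate_by_gene}}).
#' @return character vector of categories: \code{"more_than_two_cases"},
#'   \code{"two_cases_one_variant"}, \code{"two_cases_two_variants"},
#'   \code{"singleton"}.
#' @export
classify_recurrence <- function(records) {
  ifelse(records$n_carriers > 2L, "more_than_two_cases",
  ifelse(records$n_carriers == 2L & records$shared_variant, "two_cases_one_variant",
  ifelse(records$n_carriers == 2L, "two_cases_two_variants", "singleton")))
}

#' Genes recurrent across cases
#'
#' @param records output of \code{\link{aggregate_by_gene}}.
#' @param min_carriers minimum number of distinct carrier cases (default 2).
#' @return \code{\link{gene_set}} of recurrent genes, lexicographic order.
#' @export
recurrent_genes <- function(records, min_carriers = 2L) {
  stopifnot(min_carriers >= 1L)
  gene_set("recurrent",
           records$gene[records$n_carriers >= min_carriers],
           provenance = sprintf("genes with >= %d carriers", min_carriers))
}

#' Recurrence summary report
#'
#' Emits category totals and a listing in the field's compact
#' \code{"gene  n_variants (n_carriers[, n homoz])"} form.
#'
#' @param records output of \code{\link{aggregate_by_gene}}.
#' @return list with \code{totals} (data frame: n_genes, n_variants and
#'   per-category gene counts) and \code{listing} (data frame: gene, line).
#' @export
recurrence_report <- function(records) {
  cats <- c("two_cases_two_variants", "two_cases_one_variant",
            "more_than_two_cases", "singleton")
  cat_counts <- vapply(cats, function(cc) sum(records$category == cc), integer(1))
  totals <- data.frame(
    n_genes = nrow(records),
    n_variants = if (nrow(records)) sum(records$n_variants) else 0L,
    t(cat_counts), stringsAsFactors = FALSE, check.names = FALSE
  )
  note <- ifelse(records$n_hom > 0L,
                 paste0(", ", ifelse(records$n_hom == 1L, "one homoz",
                                     paste0(records$n_hom, " homoz"))),
                 "")
  listing <- data.frame(
    gene = records$gene,
    line = sprintf("%s %d (%d%s)", records$gene, records$n_variants,
                   records$n_carriers, note),
    stringsAsFactors = FALSE
  )
  list(totals = totals, listing = listing)
}

#' Parse a recurrence listing back into counts
#'
#' Inverse of the \code{listing} produced by \code{\link{recurrence_report}};
#' used for round-trip checks and for reading transcribed published tables.
#'
#' @param lines character vector like \code{"LRP5 4 (3)"} or
#'   \code{"DAAM2 3 (3, one homoz)"}.
#' @return data frame: gene, n_variants, n_carriers, n_hom.
#' @export
parse_recurrence_listing <- function(lines) {
  m <- regmatches(lines,
                  regexec("^(\\S+)\\s+(\\d+)\\s+\\((\\d+)(?:,\\s*(one|\\d+)\\s+homoz)?\\)\\s*$",
                          lines))
  bad <- lengths(m) == 0L | vapply(m, length, integer(1)) < 4L
  if (any(bad)) stop_affnet("unparseable listing line(s): ",
                            paste(lines[bad], collapse = "; "))
  data.frame(
    gene = vapply(m, `[`, character(1), 2L),
    n_variants = as.integer(vapply(m, `[`, character(1), 3L)),
    n_carriers = as.integer(vapply(m, `[`, character(1), 4L)),
    n_hom = vapply(m, function(g) {
      h <- g[5L]
      if (is.na(h) || h == "") 0L else if (h == "one") 1L else as.integer(h)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}
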