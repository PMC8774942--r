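#' Filter configuration for the variant cascade
#'
#' Thresholds follow the standard rare-disease exome workflow for this cohort:
#' site quality (DP >= 10, GQ >= 30), removal of synonymous changes, rarity
#' against the ExAC and CSVS panels (MAF <= 0.005), and damaging-variant
#' prioritization (CADD phred >= 20; SIFT not "tolerated"; PolyPhen HumDiv not
#' "benign").
#'
#' @param dp_min minimum read depth (default 10).
#' @param gq_min minimum genotype quality (default 30).
#' @param maf_max maximum population minor-allele frequency, applied to both
#'   panels; the boundary is inclusive (default 0.005).
#' @param cadd_min minimum CADD phred score at prioritization (default 20).
#' @param excluded_consequences consequence classes removed outright
#'   (default \code{"synonymous"}).
#' @param missing_prediction_policy what prioritization does with calls whose
#'   SIFT/PolyPhen/CADD annotations are absent: \code{"pass"} (default —
#'   an unscored variant cannot be called tolerated or benign; truncating
#'   variants are often unscored) or \code{"fail"}.
#' @return list of class \code{"affnet_filter_config"}.
#' @export
filter_config <- function(dp_min = 10L, gq_min = 30L, maf_max = 0.005,
                          cadd_min = 20, excluded_consequences = "synonymous",
                          missing_prediction_policy = c("pass", "fail")) {
  missing_prediction_policy <- match.arg(missing_prediction_policy)
  stopifnot(dp_min >= 0, gq_min >= 0, maf_max >= 0, maf_max <= 1, cadd_min >= 0)
  bad <- setdiff(excluded_consequences, CONSEQUENCE_LEVELS)
  if (length(bad)) stop_affnet("unknown consequence class(es): ",
                               paste(bad, collapse = ", "))
  structure(list(dp_min = as.integer(dp_min), gq_min = as.integer(gq_min),
                 maf_max = maf_max, cadd_min = cadd_min,
                 excluded_consequences = excluded_consequences,
                 missing_prediction_policy = missing_prediction_policy),
            class = "affnet_filter_config")
}

#' Quality filter: retain calls with DP >= dp_min and GQ >= gq_min
#'
#' Boundary values are retained (thresholds are inclusive). Missing DP or GQ
#' fails the filter: quality must be demonstrated, not assumed.
#'
#' @param calls variant-call table.
#' @param cfg \code{\link{filter_config}}.
#' @return filtered variant-call table, input order preserved.
#' @export
qc_filter <- function(calls, cfg = filter_config()) {
  calls <- as_variant_calls(calls)
  keep <- !is.na(calls$dp) & !is.na(calls$gq) &
    calls$dp >= cfg$dp_min & calls$gq >= cfg$gq_min
  reset_rows(calls[keep, , drop = FALSE])
}

#' Consequence filter: drop excluded consequence classes
#'
#' @inheritParams qc_filter
#' @return filtered variant-call table.
#' @export
consequence_filter <- function(calls, cfg = filter_config()) {
  calls <- as_variant_calls(calls)
  reset_rows(calls[!calls$consequence %in% cfg$excluded_consequences, ,
                   drop = FALSE])
}

#' Rarity filter: retain calls rare in both reference panels
#'
#' A call passes when each panel frequency is either absent (the allele was
#' never observed in the panel, hence rare) or at most \code{maf_max}.
#'
#' @inheritParams qc_filter
#' @return filtered variant-call table.
#' @export
rarity_filter <- function(calls, cfg = filter_config()) {
  calls <- as_variant_calls(calls)
  ok_exac <- is.na(calls$maf_exac) | calls$maf_exac <= cfg$maf_max
  ok_csvs <- is.na(calls$maf_csvs) | calls$maf_csvs <= cfg$maf_max
  reset_rows(calls[ok_exac & ok_csvs, , drop = FALSE])
}

#' Control subtraction: drop case variants seen in any control
#'
#' A case call is removed when its variant identity (chrom, pos, ref, alt)
#' was called in any control sample at any zygosity. Returns case calls only.
#'
#' @param chrt an \code{\link{cohort}} object.
#' @return variant-call table restricted to case samples, control-seen
#'   variants removed.
#' @export
control_subtract <- function(chrt) {
  stopifnot(inherits(chrt, "affnet_cohort"))
  calls <- chrt$calls
  in_case <- calls$sample_id %in% chrt$cases
  control_ids <- unique(variant_id(calls[!in_case, , drop = FALSE]))
  case_calls <- calls[in_case, , drop = FALSE]
  reset_rows(case_calls[!variant_id(case_calls) %in% control_ids, ,
                        drop = FALSE])
}

#' Damaging-variant prioritization
#'
#' Exclusion is a disjunction of failure criteria: a call is removed when its
#' CADD phred score is present and below \code{cadd_min}, OR SIFT calls it
#' tolerated, OR PolyPhen calls it benign. Equivalently, retention requires
#' CADD >= \code{cadd_min} (if scored) AND SIFT != tolerated AND PolyPhen !=
#' benign. PolyPhen "possibly_damaging" is retained. Under the default
#' \code{missing_prediction_policy = "pass"} an absent prediction never
#' excludes; under \code{"fail"} a call with any absent prediction is removed.
#'
#' The disjunctive rule is what drops a variant with damaging PolyPhen and
#' CADD but a tolerated SIFT call — one predictor calling the change benign
#' suffices for exclusion.
#'
#' @inheritParams qc_filter
#' @return filtered variant-call table.
#' @export
prioritize_damaging <- function(calls, cfg = filter_config()) {
  calls <- as_variant_calls(calls)
  fail_cadd <- !is.na(calls$cadd) & calls$cadd < cfg$cadd_min
  fail_sift <- !is.na(calls$sift) & calls$sift == "tolerated"
  fail_pp <- !is.na(calls$polyphen) & calls$polyphen == "benign"
  fail <- fail_cadd | fail_sift | fail_pp
  if (cfg$missing_prediction_policy == "fail") {
    fail <- fail | is.na(calls$cadd) | is.na(calls$sift) | is.na(calls$polyphen)
  }
  reset_rows(calls[!fail, , drop = FALSE])
}

#' Run the full filter cascade over a cohort
#'
#' Stage order: control subtraction, then quality, consequence and rarity
#' filters, then (optionally) damaging-variant prioritization. The per-variant
#' stages are pure predicates and commute; the order is fixed for the
#' stage-count report only.
#'
#' @param chrt an \code{\link{cohort}}.
#' @param cfg \code{\link{filter_config}}.
#' @param prioritize apply \code{\link{prioritize_damaging}} as the final
#'   stage (default \code{TRUE}).
#' @return list of class \code{"affnet_cascade"} with \code{survivors} (the
#'   surviving variant-call table) and \code{report} (data frame: stage,
#'   n_calls surviving after the stage).
#' @export
run_cascade <- function(chrt, cfg = filter_config(), prioritize = TRUE) {
  stopifnot(inherits(chrt, "affnet_cohort"))
  stages <- list()
  case_calls <- chrt$calls[chrt$calls$sample_id %in% chrt$cases, , drop = FALSE]
  stages[["input_case_calls"]] <- nrow(case_calls)
  cur <- control_subtract(chrt)
  stages[["control_subtract"]] <- nrow(cur)
  cur <- qc_filter(cur, cfg)
  stages[["qc_filter"]] <- nrow(cur)
  cur <- consequence_filter(cur, cfg)
  stages[["consequence_filter"]] <- nrow(cur)
  cur <- rarity_filter(cur, cfg)
  stages[["rarity_filter"]] <- nrow(cur)
  if (prioritize) {
    cur <- prioritize_damaging(cur, cfg)
    stages[["prioritize_damaging"]] <- nrow(cur)
  }
  report <- data.frame(stage = names(stages),
                       n_calls = unlist(stages, use.names = FALSE),
                       stringsAsFactors = FALSE)
  structure(list(survivors = cur, report = report), class = "affnet_cascade")
}

#' @export
print.affnet_cascade <- function(x, ...) {
  cat("Variant filter cascade:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
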