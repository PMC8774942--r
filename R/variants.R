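#' @title Annotated variant-call tables
#' @description
#' The package represents a cohort's annotated variant calls as an ordinary
#' data frame with one row per sample-variant observation, the shape a
#' per-sample VEP/ANNOVAR-style export takes after flattening. Column
#' contract (the canonical flat-TSV dialect):
#'
#' \itemize{
#'   \item \code{sample_id} opaque sample label
#'   \item \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt}
#'   \item \code{gene} HGNC-style symbol; \code{hgvs_p} optional protein change
#'   \item \code{zygosity} \code{"heterozygous"} or \code{"homozygous"}
#'   \item \code{dp}, \code{gq} read depth and genotype quality
#'   \item \code{consequence} one of \code{synonymous}, \code{missense},
#'     \code{stop_gained}, \code{frameshift}, \code{splice},
#'     \code{inframe_indel}, \code{other}
#'   \item \code{maf_exac}, \code{maf_csvs} population allele frequencies in
#'     \[0,1\], \code{NA} when the allele is unobserved in the panel
#'   \item \code{sift} \code{deleterious}/\code{tolerated} or \code{NA};
#'     \code{polyphen} \code{probably_damaging}/\code{possibly_damaging}/
#'     \code{benign} or \code{NA} (HumDiv model); \code{cadd} phred-scaled
#'     deleteriousness or \code{NA}
#' }
#'
#' Absent annotations are always \code{NA}, never 0: an allele missing from a
#' frequency panel is unobserved, not common.
#' @name variant-tables
NULL

VARIANT_COLUMNS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "gene", "hgvs_p", "zygosity",
  "dp", "gq", "consequence", "maf_exac", "maf_csvs", "sift", "polyphen", "cadd"
)

CONSEQUENCE_LEVELS <- c(
  "synonymous", "missense", "stop_gained", "frameshift", "splice",
  "inframe_indel", "other"
)
ZYGOSITY_LEVELS <- c("heterozygous", "homozygous")
SIFT_LEVELS <- c("deleterious", "tolerated")
POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign")

#' Construct and validate a variant-call table
#'
#' Coerces a data frame to the canonical variant-call column set, checks the
#' domain invariants (positions >= 1, ref != alt, non-negative DP/GQ,
#' frequencies in \[0,1\], known enum levels) and normalises column order.
#' Unknown consequence strings are mapped to \code{"other"} with a warning.
#'
#' @param df data frame carrying at least the canonical columns
#'   (\code{hgvs_p} may be omitted and is filled with \code{NA}).
#' @return validated data frame with columns in canonical order.
#' @export
as_variant_calls <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"hgvs_p" %in% names(df)) df$hgvs_p <- NA_character_
  missing <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing)) {
    stop_affnet("variant table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[VARIANT_COLUMNS]
  for (col in c("sample_id", "chrom", "ref", "alt", "gene", "hgvs_p",
                "zygosity", "consequence", "sift", "polyphen")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  df$pos <- as.integer(df$pos)
  df$dp <- as.integer(df$dp)
  df$gq <- as.integer(df$gq)
  for (col in c("maf_exac", "maf_csvs", "cadd")) df[[col]] <- as.numeric(df[[col]])

  if (nrow(df)) {
    if (anyNA(df$sample_id) || anyNA(df$chrom) || anyNA(df$pos) ||
        anyNA(df$ref) || anyNA(df$alt) || anyNA(df$gene)) {
      stop_affnet("sample_id, chrom, pos, ref, alt and gene must be present for every call")
    }
    if (any(df$pos < 1L)) stop_affnet("pos must be >= 1")
    if (any(df$ref == df$alt)) stop_affnet("ref and alt alleles must differ")
    if (any(df$dp < 0L, na.rm = TRUE) || any(df$gq < 0L, na.rm = TRUE)) {
      stop_affnet("dp and gq must be non-negative")
    }
    for (col in c("maf_exac", "maf_csvs")) {
      bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1)
      if (any(bad)) stop_affnet(col, " outside [0,1] on row(s) ",
                                paste(which(bad), collapse = ", "))
    }
    if (any(df$cadd < 0, na.rm = TRUE)) stop_affnet("cadd must be non-negative")
    bad_zyg <- !df$zygosity %in% ZYGOSITY_LEVELS
    if (any(bad_zyg)) stop_affnet("unknown zygosity: ",
                                  paste(unique(df$zygosity[bad_zyg]), collapse = ", "))
    unknown <- !is.na(df$consequence) & !df$consequence %in% CONSEQUENCE_LEVELS
    if (any(unknown)) {
      warn_affnet("unknown consequence string(s) mapped to 'other': ",
                  paste(unique(df$consequence[unknown]), collapse = ", "))
      df$consequence[unknown] <- "other"
    }
    df$consequence[is.na(df$consequence)] <- "other"
    bad_sift <- !is.na(df$sift) & !df$sift %in% SIFT_LEVELS
    if (any(bad_sift)) stop_affnet("unknown SIFT call: ",
                                   paste(unique(df$sift[bad_sift]), collapse = ", "))
    bad_pp <- !is.na(df$polyphen) & !df$polyphen %in% POLYPHEN_LEVELS
    if (any(bad_pp)) stop_affnet("unknown PolyPhen call: ",
                                 paste(unique(df$polyphen[bad_pp]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Variant identity keys
#'
#' \code{(chrom, pos, ref, alt)} identifies a variant independently of the
#' carrying sample or zygosity; control subtraction and recurrence counting
#' both key on it. Inputs are expected pre-normalised (decomposed
#' multi-allelics, left-aligned indels) — no re-normalisation is attempted.
#'
#' @param calls variant-call table.
#' @return character vector of \code{chrom:pos:ref:alt} keys.
#' @export
variant_id <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Read a variant table
#'
#' @param path file path.
#' @param dialect \code{"tsv"} for the canonical flat dialect (empty string =
#'   absent annotation) or \code{"vcf"} for VCF 4.x with per-sample FORMAT
#'   DP/GQ and a VEP-CSQ-like pipe-delimited INFO annotation.
#' @param vcf_config for \code{dialect = "vcf"}: list with \code{info_key}
#'   (INFO key holding the annotation, default \code{"CSQ"}) and
#'   \code{fields}, a named character vector mapping canonical names
#'   (\code{gene}, \code{hgvs_p}, \code{consequence}, \code{sift},
#'   \code{polyphen}, \code{cadd}, \code{maf_exac}, \code{maf_csvs}) to
#'   subfield names of the annotation's pipe-delimited format (declared in the
#'   VCF header \code{##INFO} Description as \code{"... Format: A|B|C"}).
#' @return validated variant-call table.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               vcf_config = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_affnet("no such file: ", path)
  if (dialect == "tsv") read_variant_tsv(path) else read_variant_vcf(path, vcf_config)
}

read_variant_tsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", comment.char = "#",
                      na.strings = NULL, check.names = FALSE),
    error = function(e) stop_affnet("cannot parse ", path, ": ", conditionMessage(e))
  )
  n_bad <- which(is.na(suppressWarnings(as.integer(df$pos))))
  if (length(n_bad)) {
    stop_affnet("unparseable pos at data line ", n_bad[1], " of ", path)
  }
  as_variant_calls(df)
}

#' Write a variant table in the canonical flat-TSV dialect
#'
#' Absent annotations are written as empty strings, so write/read round-trips
#' are lossless.
#'
#' @param calls variant-call table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  calls <- as_variant_calls(calls)
  out <- calls
  for (col in names(out)) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- ""
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Map a VEP-style consequence term onto the package's consequence enum.
normalize_consequence <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[grepl("synonymous", x)] <- "synonymous"
  out[grepl("missense", x)] <- "missense"
  out[grepl("stop_gained|stop gained|nonsense", x)] <- "stop_gained"
  out[grepl("frameshift", x)] <- "frameshift"
  out[grepl("splice", x)] <- "splice"
  out[grepl("inframe", x)] <- "inframe_indel"
  out[is.na(x) | x == ""] <- "other"
  out
}

read_variant_vcf <- function(path, vcf_config) {
  info_key <- vcf_config$info_key %||% "CSQ"
  fields <- vcf_config$fields %||% c(
    gene = "SYMBOL", hgvs_p = "HGVSp", consequence = "Consequence",
    sift = "SIFT", polyphen = "PolyPhen", cadd = "CADD_PHRED",
    maf_exac = "ExAC_AF", maf_csvs = "CSVS_AF"
  )
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcf@fix  # always a matrix, even for a single record
  fix <- as.data.frame(fixm[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variant_calls())
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop_affnet("multi-allelic record(s) found; decompose to one ALT per record first")
  }
  # header declaration of the annotation subfield order
  meta <- vcf@meta
  decl <- grep(paste0("^##INFO=<ID=", info_key, ","), meta, value = TRUE)
  if (!length(decl)) stop_affnet("INFO key ", info_key, " not declared in header")
  fmt <- sub('.*Format: ?([^">]+).*', "\\1", decl[1])
  subfields <- trimws(strsplit(fmt, "|", fixed = TRUE)[[1]])
  idx <- match(fields, subfields)
  if (anyNA(idx)) {
    stop_affnet("annotation subfield(s) not in ", info_key, " Format: ",
                paste(fields[is.na(idx)], collapse = ", "))
  }
  ann_raw <- vcfR::extract.info(vcf, element = info_key)
  ann <- t(vapply(ann_raw, function(s) {
    if (is.na(s)) return(rep(NA_character_, length(fields)))
    # first annotation block only (one transcript per record expected)
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]][1], "|", fixed = TRUE)[[1]]
    length(parts) <- length(subfields)
    parts[idx]
  }, character(length(fields)), USE.NAMES = FALSE))
  colnames(ann) <- names(fields)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  samples <- colnames(gt)

  rows <- list()
  for (j in seq_along(samples)) {
    g <- gsub("|", "/", gt[, j], fixed = TRUE)
    has_alt <- !is.na(g) & g %in% c("0/1", "1/0", "1/1")
    if (!any(has_alt)) next
    i <- which(has_alt)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = samples[j],
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = fix$ALT[i],
      gene = ann[i, "gene"], hgvs_p = ann[i, "hgvs_p"],
      zygosity = ifelse(g[i] == "1/1", "homozygous", "heterozygous"),
      dp = as.integer(dp[i, j]), gq = as.integer(gq[i, j]),
      consequence = normalize_consequence(ann[i, "consequence"]),
      maf_exac = suppressWarnings(as.numeric(ann[i, "maf_exac"])),
      maf_csvs = suppressWarnings(as.numeric(ann[i, "maf_csvs"])),
      sift = tolower(ann[i, "sift"]),
      polyphen = sub(" ", "_", tolower(ann[i, "polyphen"])),
      cadd = suppressWarnings(as.numeric(ann[i, "cadd"])),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(as_variant_calls(empty_variant_calls()))
  df <- do.call(rbind, rows)
  # SIFT/PolyPhen may arrive as "tolerated(0.45)"-style strings
  df$sift <- sub("\\(.*", "", df$sift)
  df$polyphen <- sub("\\(.*", "", df$polyphen)
  df$sift[!df$sift %in% SIFT_LEVELS] <- NA_character_
  df$polyphen[!df$polyphen %in% POLYPHEN_LEVELS] <- NA_character_
  as_variant_calls(df)
}

empty_variant_calls <- function() {
  df <- data.frame(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    hgvs_p = character(), zygosity = character(), dp = integer(),
    gq = integer(), consequence = character(), maf_exac = numeric(),
    maf_csvs = numeric(), sift = character(), polyphen = character(),
    cadd = numeric(), stringsAsFactors = FALSE
  )
  df
}

#' Assemble a cohort from case/control sample lists and calls
#'
#' @param calls variant-call table.
#' @param cases,controls character vectors of sample ids; must be disjoint and
#'   jointly cover every \code{sample_id} in \code{calls}.
#' @return list with elements \code{cases}, \code{controls}, \code{calls},
#'   class \code{"affnet_cohort"}.
#' @export
cohort <- function(calls, cases, controls = character()) {
  calls <- as_variant_calls(calls)
  cases <- as.character(cases); controls <- as.character(controls)
  if (length(intersect(cases, controls))) {
    stop_affnet("cases and controls overlap: ",
                paste(intersect(cases, controls), collapse = ", "))
  }
  stray <- setdiff(unique(calls$sample_id), c(cases, controls))
  if (length(stray)) {
    stop_affnet("calls from sample(s) outside the cohort: ",
                paste(stray, collapse = ", "))
  }
  structure(list(cases = cases, controls = controls, calls = calls),
            class = "affnet_cohort")
}

#' @export
print.affnet_cohort <- function(x, ...) {
  cat("AFF cohort:", length(x$cases), "cases,", length(x$controls),
      "controls,", nrow(x$calls), "calls\n")
  invisible(x)
}
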