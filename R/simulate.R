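#' Synthetic cohort configuration
#'
#' Defaults mirror the study design this package targets: 12 AFF cases and 4
#' BP-treated controls sequenced at high coverage, with recurrent genes of
#' every tabulated category planted alongside variants engineered to fail
#' each filter stage exactly once.
#'
#' @param n_cases,n_controls cohort arm sizes (defaults 12 and 4).
#' @param n_two_two genes planted with 2 carriers / 2 different variants.
#' @param n_two_one genes planted with 2 carriers sharing one variant.
#' @param n_more genes planted with 3 carriers / 3 variants.
#' @param n_singleton genes planted with a single carrier.
#' @param n_fail_per_mode variants planted per failure mode (low DP, low GQ,
#'   synonymous, common in ExAC, common in CSVS, seen in a control, CADD
#'   below threshold, SIFT tolerated, PolyPhen benign).
#' @param homozygote_rate probability a planted passing call is homozygous,
#'   beyond the one guaranteed homozygote.
#' @param mean_depth mean sequencing depth for passing calls (default 140).
#' @param seed RNG seed.
#' @return list of class \code{"cohort_sim_config"}.
#' @export
cohort_sim_config <- function(n_cases = 12L, n_controls = 4L,
                              n_two_two = 4L, n_two_one = 3L, n_more = 2L,
                              n_singleton = 5L, n_fail_per_mode = 2L,
                              homozygote_rate = 0.05, mean_depth = 140,
                              seed = 1L) {
  stopifnot(n_cases >= 3L, n_controls >= 0L, homozygote_rate >= 0,
            homozygote_rate <= 1, mean_depth > 0)
  structure(as.list(environment()), class = "cohort_sim_config")
}

# One passing annotated call; the generator's notion of "passes every filter".
passing_call <- function(sample_id, gene, vkey, cfg, zygosity = NULL,
                         hgvs_p = NA_character_) {
  data.frame(
    sample_id = sample_id,
    chrom = as.character(sample.int(22L, 1L)),
    pos = vkey,
    ref = sample(c("A", "C", "G", "T"), 1L),
    alt = NA_character_,  # filled by caller wrapper
    gene = gene, hgvs_p = hgvs_p,
    zygosity = zygosity %||%
      sample(c("heterozygous", "homozygous"), 1L,
             prob = c(1 - cfg$homozygote_rate, cfg$homozygote_rate)),
    dp = max(10L, stats::rpois(1L, cfg$mean_depth)),
    gq = sample(30:99, 1L),
    consequence = sample(c("missense", "stop_gained", "frameshift", "splice"),
                         1L, prob = c(0.7, 0.1, 0.1, 0.1)),
    maf_exac = if (stats::runif(1) < 0.4) NA_real_ else stats::runif(1, 0, 0.005),
    maf_csvs = if (stats::runif(1) < 0.6) NA_real_ else stats::runif(1, 0, 0.005),
    sift = sample(c("deleterious", NA_character_), 1L, prob = c(0.8, 0.2)),
    polyphen = sample(c("probably_damaging", "possibly_damaging", NA_character_),
                      1L, prob = c(0.6, 0.3, 0.1)),
    cadd = stats::runif(1, 20, 45),
    stringsAsFactors = FALSE
  )
}

#' Simulate an annotated exome cohort with recorded ground truth
#'
#' Plants (i) recurrent genes of each category — including one gene shaped
#' like the LRP5 worked example (4 variants, 3 carriers, one carrier with two
#' variants) and one like DAAM2 (3 variants, 3 carriers, one homozygous, plus
#' a fourth carrier whose variant is SIFT-tolerated and must fall at
#' prioritization) — (ii) singleton genes, and (iii) variants failing each
#' filter stage exactly once, including case variants duplicated into
#' controls. Every planted fate is recorded in the returned ground truth.
#'
#' @param cfg \code{\link{cohort_sim_config}}.
#' @return list with \code{cohort} (an \code{\link{cohort}} object) and
#'   \code{truth}: \code{surviving_variant_keys} (sample_id + variant id of
#'   every call that must survive the full cascade),
#'   \code{recurrent_genes_by_category} (post-cascade), \code{lrp5_like},
#'   \code{daam2_like} (the two worked-example gene names),
#'   \code{bone_list} (a planted bone-candidate gene set whose intersection
#'   with the recurrent genes is \code{candidate_genes}), and
#'   \code{candidate_genes}.
#' @export
simulate_cohort <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  cases <- sprintf("AFF%02d", seq_len(cfg$n_cases))
  controls <- if (cfg$n_controls) sprintf("CTRL%02d", seq_len(cfg$n_controls))
    else character()

  pos_counter <- 0L
  next_pos <- function() {
    pos_counter <<- pos_counter + 1L
    1000000L + pos_counter * 100L
  }
  alts <- c(A = "G", C = "T", G = "A", T = "C")

  rows <- list()
  surviving <- character()
  add <- function(row, survives) {
    row$alt <- unname(alts[row$ref])
    rows[[length(rows) + 1L]] <<- row
    if (survives) {
      surviving <<- c(surviving, paste(row$sample_id, row$chrom, row$pos,
                                       row$ref, row$alt, sep = ":"))
    }
    row
  }
  gene_i <- 0L
  next_gene <- function(prefix = "SGENE") {
    gene_i <<- gene_i + 1L
    sprintf("%s%03d", prefix, gene_i)
  }

  truth_cat <- list(two_cases_two_variants = character(),
                    two_cases_one_variant = character(),
                    more_than_two_cases = character(),
                    singleton = character())

  # LRP5-like: 4 variants, 3 carriers, one carrier with two variants
  lrp5_like <- next_gene()
  carriers <- sample(cases, 3L)
  add(passing_call(carriers[1], lrp5_like, next_pos(), cfg, "heterozygous"), TRUE)
  add(passing_call(carriers[2], lrp5_like, next_pos(), cfg, "heterozygous"), TRUE)
  add(passing_call(carriers[3], lrp5_like, next_pos(), cfg, "heterozygous"), TRUE)
  add(passing_call(carriers[3], lrp5_like, next_pos(), cfg, "heterozygous"), TRUE)
  truth_cat$more_than_two_cases <- c(truth_cat$more_than_two_cases, lrp5_like)

  # DAAM2-like: 3 distinct variants / 3 carriers, one homozygous; a fourth
  # carrier's variant is SIFT-tolerated and must fall at prioritization
  daam2_like <- next_gene()
  carriers <- sample(cases, 4L)
  add(passing_call(carriers[1], daam2_like, next_pos(), cfg, "homozygous"), TRUE)
  add(passing_call(carriers[2], daam2_like, next_pos(), cfg, "heterozygous"), TRUE)
  add(passing_call(carriers[3], daam2_like, next_pos(), cfg, "heterozygous"), TRUE)
  tol <- passing_call(carriers[4], daam2_like, next_pos(), cfg, "heterozygous")
  tol$sift <- "tolerated"; tol$polyphen <- "probably_damaging"; tol$cadd <- 28
  add(tol, FALSE)
  truth_cat$more_than_two_cases <- c(truth_cat$more_than_two_cases, daam2_like)

  for (i in seq_len(cfg$n_two_two)) {
    gn <- next_gene()
    carriers <- sample(cases, 2L)
    add(passing_call(carriers[1], gn, next_pos(), cfg), TRUE)
    add(passing_call(carriers[2], gn, next_pos(), cfg), TRUE)
    truth_cat$two_cases_two_variants <- c(truth_cat$two_cases_two_variants, gn)
  }
  for (i in seq_len(cfg$n_two_one)) {
    gn <- next_gene()
    carriers <- sample(cases, 2L)
    shared_pos <- next_pos()
    v1 <- add(passing_call(carriers[1], gn, shared_pos, cfg, "heterozygous"), TRUE)
    v2 <- passing_call(carriers[2], gn, shared_pos, cfg, "heterozygous")
    v2$chrom <- v1$chrom; v2$ref <- v1$ref
    v2$consequence <- v1$consequence
    v2$maf_exac <- v1$maf_exac; v2$maf_csvs <- v1$maf_csvs
    v2$sift <- v1$sift; v2$polyphen <- v1$polyphen; v2$cadd <- v1$cadd
    add(v2, TRUE)
    truth_cat$two_cases_one_variant <- c(truth_cat$two_cases_one_variant, gn)
  }
  for (i in seq_len(cfg$n_more)) {
    gn <- next_gene()
    carriers <- sample(cases, 3L)
    for (s in carriers) add(passing_call(s, gn, next_pos(), cfg), TRUE)
    truth_cat$more_than_two_cases <- c(truth_cat$more_than_two_cases, gn)
  }
  for (i in seq_len(cfg$n_singleton)) {
    gn <- next_gene()
    add(passing_call(sample(cases, 1L), gn, next_pos(), cfg), TRUE)
    truth_cat$singleton <- c(truth_cat$singleton, gn)
  }

  # failure-mode plants, each in a fresh gene so they cannot rescue a
  # recurrent gene's counts
  fail_modes <- c("low_dp", "low_gq", "synonymous", "common_exac",
                  "common_csvs", "in_control", "low_cadd", "sift_tolerated",
                  "polyphen_benign")
  for (mode in fail_modes) {
    for (i in seq_len(cfg$n_fail_per_mode)) {
      gn <- next_gene("FGENE")
      row <- passing_call(sample(cases, 1L), gn, next_pos(), cfg)
      if (mode == "low_dp") row$dp <- sample(0:9, 1L)
      if (mode == "low_gq") row$gq <- sample(0:29, 1L)
      if (mode == "synonymous") row$consequence <- "synonymous"
      if (mode == "common_exac") row$maf_exac <- stats::runif(1, 0.006, 0.5)
      if (mode == "common_csvs") row$maf_csvs <- stats::runif(1, 0.006, 0.5)
      if (mode == "low_cadd") row$cadd <- stats::runif(1, 0, 19.99)
      if (mode == "sift_tolerated") row$sift <- "tolerated"
      if (mode == "polyphen_benign") row$polyphen <- "benign"
      row <- add(row, FALSE)
      if (mode == "in_control" && length(controls)) {
        dup <- row
        dup$sample_id <- sample(controls, 1L)
        dup$zygosity <- "heterozygous"
        add(dup, FALSE)
      }
    }
  }
  # control-only background variants
  for (s in controls) {
    gn <- next_gene("CGENE")
    add(passing_call(s, gn, next_pos(), cfg), FALSE)
  }

  calls <- as_variant_calls(do.call(rbind, rows))
  chrt <- cohort(calls, cases, controls)

  recurrent <- unique(c(truth_cat$two_cases_two_variants,
                        truth_cat$two_cases_one_variant,
                        truth_cat$more_than_two_cases))
  bone_extra <- sprintf("BONE%02d", 1:10)
  bone_hits <- sort(sample(recurrent, min(3L, length(recurrent))))
  truth <- list(
    surviving_variant_keys = sort(surviving),
    recurrent_genes_by_category = lapply(truth_cat, sort),
    lrp5_like = lrp5_like, daam2_like = daam2_like,
    bone_list = gene_set("bone_candidates_planted",
                         c(bone_hits, bone_extra),
                         provenance = "synthetic planted bone list"),
    candidate_genes = bone_hits
  )
  list(cohort = chrt, truth = truth)
}

#' Sample-level call keys
#'
#' \code{sample_id:chrom:pos:ref:alt} keys, sorted — the identity under which
#' generated ground truth records which calls must survive the cascade.
#'
#' @param calls variant-call table.
#' @return sorted character vector.
#' @export
call_keys <- function(calls) {
  sort(paste(calls$sample_id, variant_id(calls), sep = ":"))
}

#' Synthetic interactome configuration
#'
#' @param n_seeds number of seed genes (default 5).
#' @param path_length geodesic length planted between every seed pair
#'   (default 3, i.e. two intermediates); scalar.
#' @param n_background_nodes filler nodes besides seeds and intermediates.
#' @param background_density edge probability among filler nodes.
#' @param model \code{"planted_paths"} (default), \code{"erdos_renyi"} or
#'   \code{"barabasi_albert"}.
#' @param seed RNG seed.
#' @return list of class \code{"network_sim_config"}.
#' @export
network_sim_config <- function(n_seeds = 5L, path_length = 3L,
                               n_background_nodes = 30L,
                               background_density = 0.1,
                               model = c("planted_paths", "erdos_renyi",
                                         "barabasi_albert"),
                               seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_seeds >= 1L, path_length >= 1L, background_density >= 0,
            background_density <= 1)
  structure(as.list(environment()), class = "network_sim_config")
}

#' Simulate an interactome with planted geodesics
#'
#' Under \code{model = "planted_paths"} each unordered seed pair is connected
#' by a unique geodesic of the configured length through fresh intermediate
#' nodes; background edges are added only among filler nodes, which touch
#' neither seeds nor intermediates, so no background edge can shortcut or tie
#' a planted geodesic. The construction is verified at generation time by
#' re-running shortest paths and asserting distance and uniqueness per pair.
#'
#' @param cfg \code{\link{network_sim_config}}.
#' @param seed_names optional character vector of seed gene names (length
#'   \code{n_seeds}); defaults to \code{SEED1..k}.
#' @return list with \code{edges} (data frame source, target, origin,
#'   confidence), \code{nodes} (all node labels, covering isolated seeds),
#'   \code{seeds}, and \code{truth} with
#'   \code{planted_intermediates} (per "A|B" seed pair) and
#'   \code{path_length}.
#' @export
simulate_interactome <- function(cfg = network_sim_config(),
                                 seed_names = NULL) {
  stopifnot(inherits(cfg, "network_sim_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  seeds <- seed_names %||% sprintf("SEED%d", seq_len(cfg$n_seeds))
  stopifnot(length(seeds) == cfg$n_seeds)

  if (cfg$model != "planted_paths") {
    n <- cfg$n_seeds + cfg$n_background_nodes
    ig <- if (cfg$model == "erdos_renyi") {
      igraph::sample_gnp(n, cfg$background_density)
    } else {
      igraph::sample_pa(n, m = max(1L, round(cfg$background_density * 10)),
                        directed = FALSE)
    }
    el <- igraph::as_edgelist(ig, names = FALSE)
    labels <- c(seeds, sprintf("BG%03d", seq_len(cfg$n_background_nodes)))
    edges <- data.frame(source = labels[el[, 1]], target = labels[el[, 2]],
                        origin = rep("custom", nrow(el)),
                        confidence = rep(NA_real_, nrow(el)),
                        stringsAsFactors = FALSE)
    return(list(edges = edges, nodes = labels, seeds = seeds,
                truth = list(planted_intermediates = NULL,
                             path_length = NA_integer_)))
  }

  inter_i <- 0L
  edges <- list()
  planted <- list()
  if (cfg$n_seeds >= 2L) {
    for (a in seq_len(cfg$n_seeds - 1L)) {
      for (b in seq((a + 1L), cfg$n_seeds)) {
        k <- cfg$path_length - 1L
        mids <- if (k > 0L) {
          inter_i <- inter_i + k
          sprintf("INT%03d", (inter_i - k + 1L):inter_i)
        } else character()
        chain <- c(seeds[a], mids, seeds[b])
        edges[[length(edges) + 1L]] <- data.frame(
          source = chain[-length(chain)], target = chain[-1L],
          origin = "custom", confidence = NA_real_, stringsAsFactors = FALSE)
        planted[[paste(sort(c(seeds[a], seeds[b])), collapse = "|")]] <-
          sort(mids)
      }
    }
  }
  # background among filler nodes only
  if (cfg$n_background_nodes >= 2L) {
    bg <- sprintf("BG%03d", seq_len(cfg$n_background_nodes))
    cmb <- utils::combn(bg, 2L)
    pick <- stats::runif(ncol(cmb)) < cfg$background_density
    if (any(pick)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = cmb[1, pick], target = cmb[2, pick],
        origin = "custom", confidence = NA_real_, stringsAsFactors = FALSE)
    }
    # anchor the filler component to one intermediate (never a seed) so the
    # graph need not be connected but stays realistic; cannot shortcut:
    # a single bridge adds no alternative seed-seed route shorter than 2x
    if (inter_i >= 1L) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = bg[1], target = "INT001", origin = "custom",
        confidence = NA_real_, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               origin = character(), confidence = numeric(),
               stringsAsFactors = FALSE)

  # generation-time self-check: every pair's distance equals the planted
  # length and the geodesic is unique
  g <- build_graph(edges, weight_mode = "unit", nodes = seeds)
  if (cfg$n_seeds >= 2L) {
    sk <- shortest_path_skeleton(g, seeds, ties = "all")
    for (r in seq_len(nrow(sk$pairs))) {
      key <- paste(sort(c(sk$pairs$seed_a[r], sk$pairs$seed_b[r])),
                   collapse = "|")
      if (sk$pairs$distance[r] != cfg$path_length ||
          sk$pairs$n_paths[r] != 1 ||
          !identical(sort(strsplit(sk$pairs$intermediates[r], ",")[[1]]),
                     planted[[key]])) {
        stop_affnet("planted-geodesic self-check failed for pair ", key,
                    "; lower background_density")
      }
    }
  }
  list(edges = edges, nodes = sort(unique(c(seeds, edges$source, edges$target))),
       seeds = seeds,
       truth = list(planted_intermediates = planted,
                    path_length = cfg$path_length))
}

#' Simulate a two-group expression matrix
#'
#' Gene-wise variances are drawn from a scaled-inverse-chi-square prior
#' (d0, s0^2) — the generative model the moderated-t machinery assumes —
#' unless a fixed \code{sd} is supplied; group means differ by the planted
#' log2 fold change.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (>= 2).
#' @param planted_logfc named numeric vector, gene -> planted log2 fold
#'   change (treated - untreated); genes beyond these get logfc 0. Names not
#'   of the form \code{GENE<k>} are appended as extra genes.
#' @param d0,s0_sq variance-prior hyperparameters (defaults 4 and 0.25).
#' @param sd optional fixed per-gene standard deviation overriding the prior
#'   draw.
#' @param baseline_range log2 baseline expression range (default c(4, 12)).
#' @param seed RNG seed.
#' @return list with \code{matrix} (a logged \code{\link{expression_matrix}})
#'   and \code{truth} (planted_logfc per gene, gene sds, d0, s0_sq).
#' @export
simulate_expression <- function(n_genes = 1000L, n_per_group = 5L,
                                planted_logfc = numeric(), d0 = 4,
                                s0_sq = 0.25, sd = NULL,
                                baseline_range = c(4, 12), seed = 1L) {
  stopifnot(n_per_group >= 2L, d0 > 0, s0_sq > 0, is.null(sd) || sd > 0)
  set.seed(derive_seed(seed, 3L))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  extra <- setdiff(names(planted_logfc), genes)
  genes <- c(genes, extra)
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  lfc[names(planted_logfc)] <- planted_logfc

  sds <- if (is.null(sd)) sqrt(d0 * s0_sq / stats::rchisq(length(genes), df = d0))
    else rep(sd, length(genes))
  base <- stats::runif(length(genes), baseline_range[1], baseline_range[2])

  samples <- c(sprintf("TRT%d", seq_len(n_per_group)),
               sprintf("UNT%d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("treated", "untreated"), each = n_per_group),
                            samples)
  mu <- cbind(matrix(base + lfc, length(genes), n_per_group),
              matrix(base, length(genes), n_per_group))
  values <- mu + matrix(stats::rnorm(length(genes) * length(samples)),
                        length(genes)) * sds
  dimnames(values) <- list(genes, samples)
  m <- expression_matrix(values, groups, logged = TRUE)
  list(matrix = m,
       truth = list(planted_logfc = lfc, gene_sd = stats::setNames(sds, genes),
                    d0 = d0, s0_sq = s0_sq))
}
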