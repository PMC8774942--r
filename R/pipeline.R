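#' Run the full synthetic end-to-end pipeline
#'
#' Chains every stage on generated data with recorded ground truth: simulate
#' a cohort, run the filter cascade, aggregate gene recurrence, intersect the
#' recurrent genes with the planted bone-candidate list, plant an interactome
#' whose seeds are the candidate genes, extract the shortest-path skeleton,
#' annotate it (o/e LoF sizes, border classes, expression-overlay fills from
#' a simulated two-group contrast) and export it. Returns every intermediate
#' plus a \code{checks} list comparing each stage's output to the planted
#' truth.
#'
#' @param outdir directory for exported tables and graphs; \code{NULL} skips
#'   writing.
#' @param seed integer seed driving every generator.
#' @param cohort_cfg,network_cfg optional configs overriding the defaults
#'   (seeds inside them are replaced by \code{seed}).
#' @return list with \code{cohort}, \code{cascade}, \code{records},
#'   \code{recurrent}, \code{candidates}, \code{skeleton}, \code{de},
#'   \code{checks} (all logical), and \code{paths} of written files.
#' @export
run_pipeline <- function(outdir = NULL, seed = 1L,
                         cohort_cfg = NULL, network_cfg = NULL) {
  cohort_cfg <- cohort_cfg %||% cohort_sim_config(seed = seed)
  cohort_cfg$seed <- seed

  sim <- simulate_cohort(cohort_cfg)
  casc <- run_cascade(sim$cohort, filter_config(), prioritize = TRUE)
  records <- aggregate_by_gene(casc$survivors, sim$cohort$cases)
  recurrent <- recurrent_genes(records, min_carriers = 2L)
  candidates <- gs_intersect(recurrent, sim$truth$bone_list)
  candidates$name <- "candidates"

  network_cfg <- network_cfg %||%
    network_sim_config(n_seeds = length(candidates$symbols), seed = seed)
  network_cfg$seed <- seed
  network_cfg$n_seeds <- length(candidates$symbols)
  net <- simulate_interactome(network_cfg, seed_names = candidates$symbols)
  g <- build_graph(net$edges, weight_mode = "unit", nodes = net$nodes)
  skel <- shortest_path_skeleton(g, candidates, ties = "all")

  # expression overlay for the skeleton nodes
  expr_sim <- simulate_expression(
    n_genes = 200L, n_per_group = 5L,
    planted_logfc = stats::setNames(
      rep(c(-2, 2), length.out = length(skel$nodes)), skel$nodes),
    seed = seed)
  de <- de_two_group(expr_sim$matrix, moderation = TRUE)

  ann <- data.frame(
    gene = skel$nodes,
    oe_lof = round(stats::runif(length(skel$nodes), 0, 1.5), 3),
    constraint_outlier = seq_along(skel$nodes) %% 4L == 0L,
    border_class = ifelse(fold_symbol(skel$nodes) %in%
                            fold_symbol(candidates$symbols), "both", "other"),
    fill_logfc = de$logfc[match(skel$nodes, de$gene)],
    carriers = records$n_carriers[match(fold_symbol(skel$nodes),
                                        fold_symbol(records$gene))],
    stringsAsFactors = FALSE
  )
  skel <- annotate_nodes(skel, ann)

  truth <- sim$truth
  post_cats <- truth$recurrent_genes_by_category
  recurrent_truth <- sort(unlist(post_cats[c("two_cases_two_variants",
                                             "two_cases_one_variant",
                                             "more_than_two_cases")],
                                 use.names = FALSE))
  cats_obs <- split(records$gene, records$category)
  checks <- list(
    cascade_exact = identical(call_keys(casc$survivors),
                              truth$surviving_variant_keys),
    recurrence_categories = all(vapply(names(post_cats), function(cc) {
      identical(sort(cats_obs[[cc]] %||% character()), post_cats[[cc]])
    }, logical(1))),
    recurrent_set = identical(recurrent$symbols, recurrent_truth),
    candidates = identical(candidates$symbols, sort(truth$candidate_genes)),
    skeleton_intermediates = all(vapply(seq_len(nrow(skel$pairs)), function(r) {
      key <- paste(sort(c(skel$pairs$seed_a[r], skel$pairs$seed_b[r])),
                   collapse = "|")
      identical(sort(strsplit(skel$pairs$intermediates[r], ",")[[1]]),
                net$truth$planted_intermediates[[key]])
    }, logical(1)))
  )

  paths <- character()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(outdir, x)
    write_variant_table(casc$survivors, f("survivors.tsv"))
    utils::write.table(casc$report, f("cascade_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rep <- recurrence_report(records)
    utils::write.table(
      records[c("gene", "n_variants", "n_carriers", "n_hom",
                "shared_variant", "category")],
      f("recurrence.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(rep$listing$line, f("recurrence_listing.txt"))
    write_gene_list(candidates, f("candidate_genes.txt"))
    export_graph(skel, f("skeleton.graphml"), "graphml")
    export_graph(skel, f("skeleton.sif"), "sif")
    export_graph(skel, f("skeleton.json"), "cytoscape_json")
    utils::write.table(overlay_table(de), f("overlay.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- vapply(c("survivors.tsv", "cascade_report.tsv", "recurrence.tsv",
                      "recurrence_listing.txt", "candidate_genes.txt",
                      "skeleton.graphml", "skeleton.sif", "skeleton.json",
                      "overlay.tsv"), f, character(1))
  }

  list(cohort = sim$cohort, truth = truth, cascade = casc, records = records,
       recurrent = recurrent, candidates = candidates, network = net,
       graph = g, skeleton = skel, de = de, checks = checks, paths = paths)
}
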