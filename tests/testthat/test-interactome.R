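test_that("undirected edges become arc pairs; duplicates merge provenance", {
  edges <- data.frame(
    source = c("A", "B", "C", "A"),
    target = c("B", "C", "D", "B"),
    origin = c("biogrid_like", "biogrid_like", "biogrid_like", "string_like"),
    confidence = c(NA, NA, NA, 900), stringsAsFactors = FALSE)
  g <- build_graph(edges)
  expect_length(g$nodes, 4L)
  expect_equal(nrow(g$arcs), 6L)
  ab <- g$arcs[g$arcs$from == "A" & g$arcs$to == "B", ]
  expect_identical(ab$origin, "biogrid_like,string_like")
  expect_equal(ab$weight, 1)
  expect_error(build_graph(transform(edges, confidence = c(NA, NA, NA, 2000))),
               "confidence")
  expect_message(build_graph(data.frame(source = c("A", "A"),
                                        target = c("A", "B"),
                                        origin = "custom")), "self-loop")
})

test_that("string-confidence weighting maps scores to clamped distances", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      origin = "string_like", confidence = c(1000, 200),
                      stringsAsFactors = FALSE)
  g <- build_graph(edges, weight_mode = "string_confidence")
  expect_equal(sort(unique(g$arcs$weight)), c(0.001, 0.8))
})

test_that("node and arc counts equal a brute-force recount on random inputs", {
  for (seed in c(1, 2, 3)) {
    edges <- random_edges(15, 0.3, seed = seed)
    g <- build_graph(edges)
    expect_length(g$nodes, length(unique(c(edges$source, edges$target))))
    und <- unique(paste(pmin(edges$source, edges$target),
                        pmax(edges$source, edges$target)))
    expect_equal(nrow(g$arcs), 2L * length(und))
  }
})

test_that("a forced intermediate appears and adjacent seeds connect directly", {
  g <- build_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
                              origin = "custom"))
  sk <- shortest_path_skeleton(g, c("A", "C"))
  expect_setequal(sk$nodes, c("A", "B", "C"))
  expect_equal(sk$pairs$distance, 2)
  expect_identical(sk$pairs$intermediates, "B")
  sk2 <- shortest_path_skeleton(g, c("A", "B"))
  expect_setequal(sk2$nodes, c("A", "B"))
  expect_equal(nrow(sk2$edges), 1L)
})

test_that("tied geodesics are all collected on the diamond; ties=one picks one", {
  g <- build_graph(data.frame(source = c("A", "B", "A", "C"),
                              target = c("B", "D", "C", "D"),
                              origin = "custom"))
  all_sk <- shortest_path_skeleton(g, c("A", "D"), ties = "all")
  expect_setequal(all_sk$nodes, c("A", "B", "C", "D"))
  expect_equal(all_sk$pairs$n_paths, 2)
  one_sk <- shortest_path_skeleton(g, c("A", "D"), ties = "one")
  expect_setequal(one_sk$nodes, c("A", "B", "D"))  # lexicographic tie-break
  expect_true(all(one_sk$nodes %in% all_sk$nodes))
  expect_true(all(paste(one_sk$edges$from, one_sk$edges$to) %in%
                    paste(all_sk$edges$from, all_sk$edges$to)))
})

test_that("skeleton distances equal igraph and Floyd-Warshall oracles", {
  set.seed(81)
  for (rep in 1:12) {
    n <- sample(c(30, 80, 200), 1)
    edges <- random_edges(n, 2.5 / n)
    if (!nrow(edges)) next
    g <- build_graph(edges)
    seeds <- sample(g$nodes, min(4, length(g$nodes)))
    sk <- shortest_path_skeleton(g, seeds, ties = "all")
    ig <- igraph::graph_from_data_frame(edges[1:2], directed = FALSE,
                                        vertices = g$nodes)
    D <- igraph::distances(ig)
    for (r in seq_len(nrow(sk$pairs))) {
      expect_equal(sk$pairs$distance[r],
                   D[sk$pairs$seed_a[r], sk$pairs$seed_b[r]])
    }
    for (r in seq_len(nrow(sk$unreachable_pairs))) {
      expect_true(is.infinite(D[sk$unreachable_pairs$seed_a[r],
                                sk$unreachable_pairs$seed_b[r]]))
    }
    if (n == 30) {
      FW <- oracle_floyd_warshall(g$nodes, edges$source, edges$target)
      expect_equal(D[g$nodes, g$nodes], FW, ignore_attr = TRUE)
    }
  }
})

test_that("weighted Dijkstra distances match igraph on random weighted graphs", {
  set.seed(82)
  for (rep in 1:5) {
    edges <- random_edges(40, 0.12)
    if (nrow(edges) < 5) next
    edges$confidence <- sample(100:1000, nrow(edges), replace = TRUE)
    edges$origin <- "string_like"
    g <- build_graph(edges, weight_mode = "string_confidence")
    seeds <- sample(g$nodes, 3)
    sk <- shortest_path_skeleton(g, seeds)
    ig <- igraph::graph_from_data_frame(edges[1:2], directed = FALSE,
                                        vertices = g$nodes)
    w <- pmin(pmax(1 - edges$confidence / 1000, 0.001), 1)
    D <- igraph::distances(ig, weights = w)
    for (r in seq_len(nrow(sk$pairs))) {
      expect_equal(sk$pairs$distance[r],
                   D[sk$pairs$seed_a[r], sk$pairs$seed_b[r]],
                   tolerance = 1e-9)
    }
  }
})

test_that("tied-path unions equal exhaustive enumeration on small graphs", {
  set.seed(83)
  for (rep in 1:20) {
    edges <- random_edges(sample(6:12, 1), 0.35)
    if (!nrow(edges)) next
    g <- build_graph(edges)
    seeds <- sample(g$nodes, 2)
    sk <- shortest_path_skeleton(g, seeds, ties = "all")
    paths <- oracle_all_shortest_paths(g$nodes, edges$source, edges$target,
                                       seeds[1], seeds[2])
    if (!length(paths)) {
      expect_equal(nrow(sk$unreachable_pairs), 1L)
      next
    }
    expect_setequal(sk$nodes, unique(unlist(paths)))
    expect_equal(sk$pairs$n_paths, length(paths))
    inter <- setdiff(unique(unlist(paths)), seeds)
    got <- if (nzchar(sk$pairs$intermediates))
      strsplit(sk$pairs$intermediates, ",")[[1]] else character()
    expect_setequal(got, inter)
  }
})

test_that("skeleton is minimal: dropping any non-seed node breaks some pair", {
  set.seed(84)
  tested <- 0
  for (rep in 1:30) {
    edges <- random_edges(sample(7:12, 1), 0.3)
    if (!nrow(edges)) next
    g <- build_graph(edges)
    seeds <- sample(g$nodes, 2)
    sk <- shortest_path_skeleton(g, seeds, ties = "all")
    if (!nrow(sk$pairs)) next
    non_seed <- setdiff(sk$nodes, seeds)
    for (v in non_seed) {
      keep <- edges$source != v & edges$target != v
      paths <- oracle_all_shortest_paths(setdiff(g$nodes, v),
                                         edges$source[keep], edges$target[keep],
                                         seeds[1], seeds[2])
      # removing v must lengthen the pair distance or remove a tied path
      worse <- !length(paths) ||
        (length(paths[[1]]) - 1 > sk$pairs$distance) ||
        (length(paths) < sk$pairs$n_paths)
      expect_true(worse)
      tested <- tested + 1
    }
  }
  expect_gt(tested, 10)
})

test_that("pair distances measured inside the skeleton equal full-graph distances", {
  set.seed(85)
  for (rep in 1:8) {
    edges <- random_edges(30, 0.12)
    if (!nrow(edges)) next
    g <- build_graph(edges)
    seeds <- sample(g$nodes, 3)
    sk <- shortest_path_skeleton(g, seeds, ties = "all")
    if (!nrow(sk$pairs) || !nrow(sk$edges)) next
    sub_edges <- data.frame(source = sk$edges$from, target = sk$edges$to,
                            origin = "custom", stringsAsFactors = FALSE)
    g2 <- build_graph(sub_edges)
    sk2 <- shortest_path_skeleton(g2, intersect(seeds, g2$nodes), ties = "all")
    m <- merge(sk$pairs[1:3], sk2$pairs[1:3], by = c("seed_a", "seed_b"))
    expect_equal(m$distance.x, m$distance.y)
  }
})

test_that("direct subnetwork equals the brute-force induced subgraph", {
  set.seed(86)
  for (rep in 1:10) {
    edges <- random_edges(20, 0.2)
    if (!nrow(edges)) next
    g <- build_graph(edges)
    seeds <- sample(g$nodes, 5)
    ds <- direct_subnet(g, seeds)
    expect_setequal(ds$nodes, seeds)
    both <- edges[edges$source %in% seeds & edges$target %in% seeds, ]
    expect_equal(nrow(ds$edges), nrow(unique(
      data.frame(a = pmin(both$source, both$target),
                 b = pmax(both$source, both$target)))))
    # every direct edge also joins adjacent seeds in the skeleton view
    sk <- shortest_path_skeleton(g, seeds, ties = "all")
    expect_true(all(ds$edges$from %in% sk$nodes) &&
                  all(ds$edges$to %in% sk$nodes))
  }
  # seeds with no mutual edges and the triangle case
  g <- build_graph(data.frame(source = c("A", "B", "C", "A"),
                              target = c("B", "C", "A", "X"),
                              origin = "custom"))
  tri <- direct_subnet(g, c("A", "B", "C"))
  expect_equal(nrow(tri$edges), 3L)
  none <- direct_subnet(g, c("B", "X"))
  expect_equal(nrow(none$edges), 0L)
  expect_setequal(none$isolated_seeds, c("B", "X"))
})

test_that("planted geodesics are recovered exactly from simulated interactomes", {
  for (seed in 1:6) {
    cfg <- network_sim_config(n_seeds = 4, path_length = 3,
                              background_density = 0.15, seed = seed)
    net <- simulate_interactome(cfg)
    g <- build_graph(net$edges, nodes = net$nodes)
    sk <- shortest_path_skeleton(g, net$seeds, ties = "all")
    for (r in seq_len(nrow(sk$pairs))) {
      key <- paste(sort(c(sk$pairs$seed_a[r], sk$pairs$seed_b[r])),
                   collapse = "|")
      expect_identical(sort(strsplit(sk$pairs$intermediates[r], ",")[[1]]),
                       net$truth$planted_intermediates[[key]])
      expect_equal(sk$pairs$n_paths[r], 1)
    }
  }
})

test_that("annotation drives size, border, fill and defaults; duplicates error", {
  g <- build_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
                              origin = "custom"))
  sk <- shortest_path_skeleton(g, c("A", "C"))
  ann <- data.frame(gene = c("A", "B"),
                    oe_lof = c(0, 2.5),
                    constraint_outlier = c(TRUE, FALSE),
                    border_class = c("aff_mutated", "bone_related"),
                    fill_logfc = c(1, -1))
  out <- annotate_nodes(sk, ann, size_range = c(10, 50), cap = 1)
  nt <- out$node_table
  expect_equal(nt$size[nt$node == "A"], 10)       # clamp at o/e = 0
  expect_equal(nt$size[nt$node == "B"], 50)       # clamp above 2
  expect_equal(nt$size[nt$node == "C"], 30)       # absent -> midpoint
  expect_identical(nt$border_class[nt$node == "C"], "other")
  expect_identical(nt$fill[nt$node == "A"], "#FF0000")
  expect_identical(nt$fill[nt$node == "C"], "#BEBEBE")
  expect_error(annotate_nodes(sk, rbind(ann, ann[1, ])), "duplicate")
})

test_that("an isolated seed is annotated but edge-free", {
  g <- build_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
                              origin = "custom"))
  suppressWarnings(sk <- direct_subnet(g, c("A", "C", "LURAP1L-like")))
  expect_true(all(c("A", "C") %in% sk$isolated_seeds))
  ann <- annotate_nodes(sk, data.frame(gene = "A", oe_lof = 1))
  expect_true("A" %in% ann$node_table$node)
  expect_equal(nrow(sk$edges), 0L)
})

test_that("connectivity report lists intermediates and tie counts per pair", {
  g <- build_graph(data.frame(source = c("A", "B", "A"),
                              target = c("B", "C", "D"),
                              origin = "custom"))
  sk <- shortest_path_skeleton(g, c("A", "C", "D"))
  rep <- connectivity_report(sk)
  ac <- rep[rep$seed_a == "A" & rep$seed_b == "C", ]
  expect_equal(ac$n_intermediates, 1L)
  expect_identical(ac$intermediates, "B")
  ad <- rep[rep$seed_a == "A" & rep$seed_b == "D", ]
  expect_equal(ad$n_intermediates, 0L)
})

test_that("exports: SIF lines, graphml round-trip, cytoscape JSON schema", {
  g <- build_graph(data.frame(source = c("A", "B"), target = c("B", "C"),
                              origin = "custom"))
  sk <- shortest_path_skeleton(g, c("A", "C"))
  sk <- annotate_nodes(sk, data.frame(gene = c("A", "B", "C"),
                                      oe_lof = c(0.2, 1.1, NA),
                                      fill_logfc = c(0.5, NA, -2)))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(sk, sif, "sif")
  expect_setequal(readLines(sif), c("A pp B", "B pp C"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(sk, gml, "graphml")
  ig <- import_graphml(gml)
  expect_setequal(igraph::V(ig)$name, sk$nodes)
  expect_equal(igraph::ecount(ig), nrow(sk$edges))
  expect_equal(sort(igraph::V(ig)$size),
               sort(sk$node_table$size))

  js <- withr::local_tempfile(fileext = ".json")
  export_graph(sk, js, "cytoscape_json")
  doc <- jsonlite::read_json(js)
  ids <- vapply(doc$elements$nodes, function(n) n$data$id, character(1))
  expect_setequal(ids, sk$nodes)
  expect_true(all(c("size", "border_class", "fill") %in%
                    names(doc$elements$nodes[[1]]$data)))
  expect_length(doc$elements$edges, nrow(sk$edges))
})

test_that("edge-list dialect readers parse BioGRID-like and STRING-like files", {
  bg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SymbolA\tSymbolB", "TP53\tMDM2", "LRP5\tDAAM2"), bg)
  e1 <- read_biogrid_edges(bg)
  expect_equal(nrow(e1), 2L)
  expect_identical(e1$origin[1], "biogrid_like")
  st <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 combined_score", "TP53 MDM2 900",
               "LRP5 LRP6 410"), st)
  e2 <- read_string_edges(st)
  expect_equal(e2$confidence, c(900, 410))
  g <- build_graph(rbind(e1, e2))
  expect_identical(
    g$arcs$origin[g$arcs$from == "MDM2" & g$arcs$to == "TP53"],
    "biogrid_like,string_like")
})
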