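#' Read a BioGRID-tab-like interaction edge list
#'
#' A tab-separated table with header; two columns hold the interactor gene
#' symbols (configurable indices, defaults suit BioGRID "Official Symbol"
#' layouts reduced to two columns).
#'
#' @param path file path.
#' @param col_a,col_b column indices of the two interactor symbols.
#' @return data frame: source, target, origin (\code{"biogrid_like"}),
#'   confidence (\code{NA}).
#' @export
read_biogrid_edges <- function(path, col_a = 1L, col_b = 2L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  data.frame(source = as.character(df[[col_a]]),
             target = as.character(df[[col_b]]),
             origin = "biogrid_like", confidence = NA_real_,
             stringsAsFactors = FALSE)
}

#' Read a STRING-link-like edge list
#'
#' Whitespace-separated table with header columns \code{protein1},
#' \code{protein2}, \code{combined_score} (0-1000).
#'
#' @param path file path.
#' @return data frame: source, target, origin (\code{"string_like"}),
#'   confidence.
#' @export
read_string_edges <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  data.frame(source = as.character(df$protein1),
             target = as.character(df$protein2),
             origin = "string_like",
             confidence = as.numeric(df$combined_score),
             stringsAsFactors = FALSE)
}

#' Build the integrated interactome graph
#'
#' Undirected input edges are stored as a directed graph with both arcs, the
#' representation that makes pairwise shortest-path extraction uniform.
#' Duplicate edges across origins are merged with their provenance unioned;
#' self-loops are dropped (count reported via message).
#'
#' @param edges data frame with columns \code{source}, \code{target},
#'   \code{origin} (one of \code{biogrid_like}, \code{string_like},
#'   \code{custom}) and optional \code{confidence} in \[0,1000\].
#' @param weight_mode \code{"unit"} (every arc weight 1; default) or
#'   \code{"string_confidence"} (weight \code{1 - confidence/1000} clamped to
#'   \[0.001, 1\], so high-confidence interactions are shorter).
#' @param nodes optional extra node symbols to include even when they touch
#'   no edge (isolated genes).
#' @return object of class \code{"affnet_graph"}: \code{nodes} (display
#'   symbols), \code{arcs} (data frame from, to, weight, origin), plus an
#'   internal adjacency index.
#' @export
build_graph <- function(edges, weight_mode = c("unit", "string_confidence"),
                        nodes = NULL) {
  weight_mode <- match.arg(weight_mode)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "origin") %in% names(edges))) {
    stop_affnet("edges need columns source, target, origin")
  }
  if (!"confidence" %in% names(edges)) edges$confidence <- NA_real_
  bad_conf <- !is.na(edges$confidence) &
    (edges$confidence < 0 | edges$confidence > 1000)
  if (any(bad_conf)) {
    stop_affnet("confidence outside [0,1000] on edge row(s) ",
                paste(which(bad_conf), collapse = ", "))
  }
  src <- fold_symbol(edges$source); tgt <- fold_symbol(edges$target)
  loops <- src == tgt
  if (any(loops)) message("dropped ", sum(loops), " self-loop edge(s)")
  edges <- edges[!loops, , drop = FALSE]
  src <- src[!loops]; tgt <- tgt[!loops]

  display <- c(edges$source, edges$target, as.character(nodes))
  key <- c(src, tgt, fold_symbol(as.character(nodes)))
  nodes <- display[!duplicated(key)]
  names(nodes) <- key[!duplicated(key)]
  nodes <- nodes[order(names(nodes), method = "radix")]

  w <- if (weight_mode == "unit") rep(1, nrow(edges)) else {
    conf <- ifelse(is.na(edges$confidence), 0, edges$confidence)
    pmin(pmax(1 - conf / 1000, 0.001), 1)
  }
  # expand to both arc directions, then merge duplicates (min weight,
  # provenance union)
  arc_from <- c(src, tgt); arc_to <- c(tgt, src)
  arc_w <- c(w, w); arc_o <- c(edges$origin, edges$origin)
  akey <- paste(arc_from, arc_to, sep = "\r")
  origin <- vapply(split(arc_o, akey),
                   function(o) paste(sort(unique(o)), collapse = ","),
                   character(1))
  weight <- vapply(split(arc_w, akey), min, numeric(1))
  first <- !duplicated(akey)
  ord <- order(akey[first], method = "radix")
  arcs <- data.frame(from = arc_from[first][ord], to = arc_to[first][ord],
                     stringsAsFactors = FALSE)
  arcs$weight <- unname(weight[akey[first][ord]])
  arcs$origin <- unname(origin[akey[first][ord]])

  g <- structure(list(nodes = unname(nodes), node_key = names(nodes),
                      arcs = arcs),
                 class = "affnet_graph")
  g$adj <- build_adjacency(g)
  g
}

build_adjacency <- function(g) {
  from_i <- match(g$arcs$from, g$node_key)
  to_i <- match(g$arcs$to, g$node_key)
  adj <- vector("list", length(g$nodes))
  sp <- split(seq_along(from_i), from_i)
  for (k in names(sp)) {
    i <- as.integer(k)
    adj[[i]] <- list(to = to_i[sp[[k]]], w = g$arcs$weight[sp[[k]]])
  }
  adj
}

#' @export
print.affnet_graph <- function(x, ...) {
  cat("Interactome graph:", length(x$nodes), "nodes,", nrow(x$arcs),
      "arcs (", nrow(x$arcs) / 2, "undirected edges )\n")
  invisible(x)
}

# Dijkstra single-source shortest paths with full predecessor sets.
# Returns list(dist = numeric, pred = list of integer predecessor vectors,
# npaths = numeric count of tied geodesics from the source).
# Tie detection uses a small absolute tolerance for weighted graphs.
dijkstra_sssp <- function(g, source_idx, tol = 1e-9) {
  n <- length(g$nodes)
  dist <- rep(Inf, n)
  pred <- vector("list", n)
  done <- rep(FALSE, n)
  dist[source_idx] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || is.infinite(dist[u])) break
    done[u] <- TRUE
    nb <- g$adj[[u]]
    if (!is.null(nb)) {
      for (k in seq_along(nb$to)) {
        v <- nb$to[k]
        if (done[v]) next
        alt <- dist[u] + nb$w[k]
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          pred[[v]] <- u
        } else if (alt <= dist[v] + tol) {
          pred[[v]] <- union(pred[[v]], u)
        }
      }
    }
    if (all(done | is.infinite(dist))) break
  }
  # tied-geodesic counts by DP in order of increasing distance
  npaths <- rep(0, n)
  npaths[source_idx] <- 1
  ord <- order(dist)
  for (v in ord) {
    if (v == source_idx || is.infinite(dist[v])) next
    npaths[v] <- sum(npaths[pred[[v]]])
  }
  list(dist = dist, pred = pred, npaths = npaths)
}

# Backtrack the predecessor DAG from target, returning node indices and arcs
# (matrix from,to) on ALL tied geodesics source -> target.
backtrack_all <- function(sp, target_idx) {
  nodes <- integer(0); arcs_from <- integer(0); arcs_to <- integer(0)
  seen <- logical(length(sp$dist))
  stack <- target_idx
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    nodes <- c(nodes, v)
    for (u in sp$pred[[v]]) {
      arcs_from <- c(arcs_from, u); arcs_to <- c(arcs_to, v)
      if (!seen[u]) stack <- c(stack, u)
    }
  }
  list(nodes = nodes, arcs = cbind(from = arcs_from, to = arcs_to))
}

# One deterministic geodesic source -> target: at each step pick the
# lexicographically smallest predecessor symbol.
backtrack_one <- function(g, sp, target_idx) {
  path <- target_idx
  v <- target_idx
  while (length(sp$pred[[v]])) {
    preds <- sp$pred[[v]]
    v <- preds[order(g$node_key[preds], method = "radix")][1]
    path <- c(v, path)
  }
  path
}

#' Extract the seed-gene shortest-path skeleton
#'
#' For every unordered pair of seed genes, computes the shortest-path
#' distance by Dijkstra's algorithm on the directed interactome and overlays
#' the connecting geodesics: with \code{ties = "all"} (default) the skeleton
#' is the union, over all seed pairs, of every tied minimum-weight path
#' (collected from the shortest-path predecessor DAG); with
#' \code{ties = "one"} one deterministic path per pair (lexicographic
#' tie-break). Seed pairs farther apart than \code{max_len}, and disconnected
#' pairs, are recorded as unreachable.
#'
#' @param g \code{\link{build_graph}} result.
#' @param seeds \code{\link{gene_set}} or character vector of seed genes;
#'   seeds absent from the graph are reported and skipped.
#' @param max_len optional distance bound (hops under unit weights).
#' @param ties \code{"all"} or \code{"one"}.
#' @return object of class \code{"affnet_subnet"}: \code{seed_genes},
#'   \code{nodes}, \code{edges} (undirected, canonical order),
#'   \code{pairs} (per seed pair: distance, n_paths, intermediates),
#'   \code{unreachable_pairs}, \code{missing_seeds}, \code{isolated_seeds}.
#' @export
shortest_path_skeleton <- function(g, seeds, max_len = Inf,
                                   ties = c("all", "one")) {
  ties <- match.arg(ties)
  if (inherits(seeds, "gene_set")) seeds <- seeds$symbols
  seeds <- unique_symbols(as.character(seeds))
  if (!length(seeds)) stop_affnet("seed set is empty")
  seed_key <- fold_symbol(seeds)
  present <- seed_key %in% g$node_key
  missing_seeds <- seeds[!present]
  if (length(missing_seeds)) {
    warn_affnet("seed(s) absent from graph, skipped: ",
                paste(missing_seeds, collapse = ", "))
  }
  seeds <- seeds[present]; seed_key <- seed_key[present]
  if (!length(seeds)) stop_affnet("no seed is present in the graph")
  seed_idx <- match(seed_key, g$node_key)

  node_set <- seed_idx
  arc_rows <- list()
  pair_rows <- list()
  unreach <- list()

  if (length(seed_idx) >= 2L) {
    for (a in seq_len(length(seed_idx) - 1L)) {
      sp <- dijkstra_sssp(g, seed_idx[a])
      for (b in seq((a + 1L), length(seed_idx))) {
        t_idx <- seed_idx[b]
        d <- sp$dist[t_idx]
        if (is.infinite(d)) {
          unreach[[length(unreach) + 1L]] <- data.frame(
            seed_a = seeds[a], seed_b = seeds[b], distance = NA_real_,
            reason = "disconnected", stringsAsFactors = FALSE)
          next
        }
        if (d > max_len) {
          unreach[[length(unreach) + 1L]] <- data.frame(
            seed_a = seeds[a], seed_b = seeds[b], distance = d,
            reason = "beyond_max_len", stringsAsFactors = FALSE)
          next
        }
        if (ties == "all") {
          bt <- backtrack_all(sp, t_idx)
          path_nodes <- bt$nodes
          arcs <- bt$arcs
        } else {
          path <- backtrack_one(g, sp, t_idx)
          path_nodes <- path
          arcs <- if (length(path) > 1L)
            cbind(from = path[-length(path)], to = path[-1L]) else
            cbind(from = integer(0), to = integer(0))
        }
        node_set <- union(node_set, path_nodes)
        if (nrow(arcs)) arc_rows[[length(arc_rows) + 1L]] <- arcs
        inter <- setdiff(path_nodes, c(seed_idx[a], t_idx))
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          seed_a = seeds[a], seed_b = seeds[b], distance = d,
          n_paths = sp$npaths[t_idx],
          intermediates = paste(sort(g$nodes[inter]), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }

  edges <- canonical_edges(g, arc_rows)
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(seed_a = character(), seed_b = character(),
               distance = numeric(), n_paths = numeric(),
               intermediates = character(), stringsAsFactors = FALSE)
  unreachable <- if (length(unreach)) do.call(rbind, unreach) else
    data.frame(seed_a = character(), seed_b = character(),
               distance = numeric(), reason = character(),
               stringsAsFactors = FALSE)
  connected <- unique(c(pairs$seed_a, pairs$seed_b))
  structure(list(
    seed_genes = seeds,
    nodes = sort(g$nodes[node_set]),
    edges = edges,
    pairs = pairs,
    unreachable_pairs = unreachable,
    missing_seeds = missing_seeds,
    isolated_seeds = setdiff(seeds, connected)
  ), class = "affnet_subnet")
}

# Collapse arc index matrices to a canonical undirected edge table.
canonical_edges <- function(g, arc_rows) {
  if (!length(arc_rows)) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  arcs <- do.call(rbind, arc_rows)
  a <- pmin(arcs[, "from"], arcs[, "to"])
  b <- pmax(arcs[, "from"], arcs[, "to"])
  key <- paste(a, b)
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  w <- g$arcs$weight[match(paste(g$node_key[a], g$node_key[b], sep = "\r"),
                           paste(g$arcs$from, g$arcs$to, sep = "\r"))]
  out <- data.frame(from = g$nodes[a], to = g$nodes[b], weight = w,
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direct-interaction subnetwork among seed genes
#'
#' The simplified published view: only seed genes and the interactions
#' directly connecting them (the induced subgraph on the seeds).
#'
#' @inheritParams shortest_path_skeleton
#' @return \code{"affnet_subnet"} whose nodes are the seeds present in the
#'   graph and whose edges have both endpoints among them.
#' @export
direct_subnet <- function(g, seeds) {
  if (inherits(seeds, "gene_set")) seeds <- seeds$symbols
  seeds <- unique_symbols(as.character(seeds))
  if (!length(seeds)) stop_affnet("seed set is empty")
  seed_key <- fold_symbol(seeds)
  present <- seed_key %in% g$node_key
  missing_seeds <- seeds[!present]
  seeds <- seeds[present]; seed_key <- seed_key[present]
  in_seed <- g$arcs$from %in% seed_key & g$arcs$to %in% seed_key
  arcs <- g$arcs[in_seed, , drop = FALSE]
  a <- pmin(arcs$from, arcs$to); b <- pmax(arcs$from, arcs$to)
  keep <- !duplicated(paste(a, b))
  edges <- data.frame(from = g$nodes[match(a[keep], g$node_key)],
                      to = g$nodes[match(b[keep], g$node_key)],
                      weight = arcs$weight[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  connected <- unique(c(fold_symbol(edges$from), fold_symbol(edges$to)))
  structure(list(
    seed_genes = seeds,
    nodes = sort(g$nodes[match(seed_key, g$node_key)]),
    edges = edges,
    pairs = data.frame(seed_a = character(), seed_b = character(),
                       distance = numeric(), n_paths = numeric(),
                       intermediates = character(), stringsAsFactors = FALSE),
    unreachable_pairs = data.frame(seed_a = character(), seed_b = character(),
                                   distance = numeric(), reason = character(),
                                   stringsAsFactors = FALSE),
    missing_seeds = missing_seeds,
    isolated_seeds = seeds[!seed_key %in% connected]
  ), class = "affnet_subnet")
}

#' @export
print.affnet_subnet <- function(x, ...) {
  cat("Seed subnetwork:", length(x$seed_genes), "seeds,", length(x$nodes),
      "nodes,", nrow(x$edges), "edges\n")
  if (length(x$isolated_seeds))
    cat("  isolated seeds:", paste(x$isolated_seeds, collapse = ", "), "\n")
  invisible(x)
}

#' Annotate subnetwork nodes for display
#'
#' Attaches the display semantics used for AFF candidate networks: border
#' class (cohort-mutated, bone-related, both, other), node size from the
#' gnomAD-style observed/expected loss-of-function ratio (clamped to \[0,2\]
#' and mapped linearly to \code{size_range}; constrained genes draw small),
#' a constraint-outlier flag, and a fill colour from the expression overlay
#' via \code{\link{map_color}}.
#'
#' @param subnet \code{"affnet_subnet"} object.
#' @param annotations data frame with columns \code{gene} and any of
#'   \code{oe_lof}, \code{constraint_outlier}, \code{border_class},
#'   \code{fill_logfc}, \code{carriers}; at most one row per gene.
#' @param size_range numeric length-2 node-size range (default c(10, 50)).
#' @param cap log2-fold-change saturation for the fill colour (default 1).
#' @return the subnetwork with a \code{node_table} data frame attached.
#' @export
annotate_nodes <- function(subnet, annotations, size_range = c(10, 50),
                           cap = 1) {
  stopifnot(inherits(subnet, "affnet_subnet"))
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!"gene" %in% names(annotations)) stop_affnet("annotations need a gene column")
  key <- fold_symbol(annotations$gene)
  if (anyDuplicated(key)) {
    stop_affnet("duplicate annotation for gene(s): ",
                paste(unique(annotations$gene[duplicated(key)]), collapse = ", "))
  }
  for (col in c("oe_lof", "fill_logfc")) {
    if (!col %in% names(annotations)) annotations[[col]] <- NA_real_
  }
  if (!"constraint_outlier" %in% names(annotations))
    annotations$constraint_outlier <- FALSE
  if (!"border_class" %in% names(annotations))
    annotations$border_class <- "other"
  if (!"carriers" %in% names(annotations)) annotations$carriers <- NA_integer_

  i <- match(fold_symbol(subnet$nodes), key)
  oe <- annotations$oe_lof[i]
  oe_clamped <- pmin(pmax(oe, 0), 2)
  size <- ifelse(is.na(oe_clamped), mean(size_range),
                 size_range[1] + oe_clamped / 2 * diff(size_range))
  fill_logfc <- annotations$fill_logfc[i]
  subnet$node_table <- data.frame(
    node = subnet$nodes,
    border_class = ifelse(is.na(i), "other", annotations$border_class[i]),
    oe_lof = oe,
    size = size,
    constraint_outlier = ifelse(is.na(i), FALSE,
                                as.logical(annotations$constraint_outlier[i])),
    fill_logfc = fill_logfc,
    fill = map_color(fill_logfc, cap = cap),
    carriers = ifelse(is.na(i), NA_integer_,
                      as.integer(annotations$carriers[i])),
    is_seed = fold_symbol(subnet$nodes) %in% fold_symbol(subnet$seed_genes),
    stringsAsFactors = FALSE
  )
  subnet
}

#' Seed-pair connectivity report
#'
#' One row per reachable seed pair: distance, number of tied shortest paths
#' and the intermediate genes lying on them, plus the isolated-seed list as
#' an attribute.
#'
#' @param subnet result of \code{\link{shortest_path_skeleton}}.
#' @return data frame \code{pairs} with attribute \code{isolated_seeds}.
#' @export
connectivity_report <- function(subnet) {
  stopifnot(inherits(subnet, "affnet_subnet"))
  out <- subnet$pairs
  out$n_intermediates <- ifelse(nzchar(out$intermediates),
                                lengths(strsplit(out$intermediates, ",")), 0L)
  attr(out, "isolated_seeds") <- subnet$isolated_seeds
  out
}

subnet_node_table <- function(subnet) {
  if (!is.null(subnet$node_table)) return(subnet$node_table)
  data.frame(node = subnet$nodes,
             is_seed = fold_symbol(subnet$nodes) %in%
               fold_symbol(subnet$seed_genes),
             stringsAsFactors = FALSE)
}

subnet_to_igraph <- function(subnet) {
  nt <- subnet_node_table(subnet)
  edges <- subnet$edges
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges else
      data.frame(from = character(), to = character(), weight = numeric()),
    directed = FALSE, vertices = nt)
  ig
}

#' Export a subnetwork to file
#'
#' @param subnet (optionally annotated) \code{"affnet_subnet"}.
#' @param path output file path.
#' @param format \code{"graphml"} (lossless attribute round-trip via igraph),
#'   \code{"sif"} (one \code{A pp B} line per undirected edge, isolated nodes
#'   as bare lines), or \code{"cytoscape_json"} (elements document for the
#'   Cytoscape JavaScript library, node size/border/fill included).
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(subnet, path,
                         format = c("graphml", "sif", "cytoscape_json")) {
  format <- match.arg(format)
  stopifnot(inherits(subnet, "affnet_subnet"))
  if (format == "graphml") {
    ig <- subnet_to_igraph(subnet)
    igraph::write_graph(ig, path, format = "graphml")
  } else if (format == "sif") {
    edges <- subnet$edges
    lines <- if (nrow(edges)) paste(edges$from, "pp", edges$to) else character()
    isolated <- setdiff(subnet$nodes, unique(c(edges$from, edges$to)))
    writeLines(c(lines, isolated), path)
  } else {
    nt <- subnet_node_table(subnet)
    node_elems <- lapply(seq_len(nrow(nt)), function(i) {
      d <- as.list(nt[i, , drop = FALSE])
      d$id <- d$node
      d$node <- NULL
      list(data = d)
    })
    edge_elems <- lapply(seq_len(nrow(subnet$edges)), function(i) {
      list(data = list(id = paste0("e", i),
                       source = subnet$edges$from[i],
                       target = subnet$edges$to[i],
                       weight = subnet$edges$weight[i]))
    })
    doc <- list(elements = list(nodes = node_elems, edges = edge_elems))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Re-import a GraphML export
#'
#' @param path GraphML file written by \code{\link{export_graph}}.
#' @return igraph object (undirected, attributes preserved).
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
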