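# Independent oracles used across the suite. These re-derive expected values
# by brute force and must stay free of the package's own code paths.

# Per-call predicate re-evaluation of the quality/consequence/rarity/
# prioritization rules, row by row.
oracle_filter_scan <- function(calls, cfg = affnet::filter_config(),
                               stages = c("qc", "consequence", "rarity")) {
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    if ("qc" %in% stages &&
        (is.na(r$dp) || is.na(r$gq) || r$dp < cfg$dp_min || r$gq < cfg$gq_min))
      keep[i] <- FALSE
    if ("consequence" %in% stages && r$consequence %in% cfg$excluded_consequences)
      keep[i] <- FALSE
    if ("rarity" %in% stages &&
        ((!is.na(r$maf_exac) && r$maf_exac > cfg$maf_max) ||
         (!is.na(r$maf_csvs) && r$maf_csvs > cfg$maf_max)))
      keep[i] <- FALSE
    if ("prioritize" %in% stages &&
        ((!is.na(r$cadd) && r$cadd < cfg$cadd_min) ||
         (!is.na(r$sift) && r$sift == "tolerated") ||
         (!is.na(r$polyphen) && r$polyphen == "benign")))
      keep[i] <- FALSE
  }
  calls[keep, , drop = FALSE]
}

# Random variant-call table exercising every annotation pattern.
random_calls <- function(n, samples = sprintf("S%02d", 1:6), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maybe <- function(x, p_na = 0.3) ifelse(runif(n) < p_na, NA, x)
  df <- data.frame(
    sample_id = sample(samples, n, replace = TRUE),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample(1:5000, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = rep(NA_character_, n),
    gene = sprintf("G%03d", sample(1:40, n, replace = TRUE)),
    hgvs_p = rep(NA_character_, n),
    zygosity = sample(c("heterozygous", "homozygous"), n, TRUE, c(0.9, 0.1)),
    dp = sample(0:60, n, replace = TRUE),
    gq = sample(0:99, n, replace = TRUE),
    consequence = sample(c("missense", "synonymous", "stop_gained",
                           "frameshift", "splice", "other"), n, TRUE),
    maf_exac = maybe(runif(n, 0, 0.02)),
    maf_csvs = maybe(runif(n, 0, 0.02)),
    sift = maybe(sample(c("deleterious", "tolerated"), n, TRUE)),
    polyphen = maybe(sample(c("probably_damaging", "possibly_damaging",
                              "benign"), n, TRUE)),
    cadd = maybe(runif(n, 0, 40)),
    stringsAsFactors = FALSE
  )
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  df$alt <- unname(flip[df$ref])
  affnet::as_variant_calls(df)
}

# Vectorised Floyd-Warshall all-pairs distances on an edge list.
oracle_floyd_warshall <- function(nodes, edges_from, edges_to, w = NULL) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  w <- w %||% rep(1, length(edges_from))
  for (k in seq_along(edges_from)) {
    i <- match(edges_from[k], nodes); j <- match(edges_to[k], nodes)
    D[i, j] <- min(D[i, j], w[k]); D[j, i] <- min(D[j, i], w[k])
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive simple-path enumeration between two nodes on a small undirected
# unit-weight graph; returns all minimum-length paths (lists of node names).
oracle_all_shortest_paths <- function(nodes, edges_from, edges_to, s, t) {
  adj <- lapply(nodes, function(v) {
    c(edges_to[edges_from == v], edges_from[edges_to == v])
  })
  names(adj) <- nodes
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
    for (u in adj[[v]]) if (!u %in% path) walk(c(path, u))
  }
  walk(s)
  if (!length(paths)) return(list())
  lens <- vapply(paths, length, integer(1))
  paths[lens == min(lens)]
}

# Exact hypergeometric upper tail by pmf enumeration with exact binomial
# coefficients (chooseZ-free: choose() is exact well beyond N = 20).
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}

# Random small graph as an edge data frame.
random_edges <- function(n_nodes, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  cmb <- combn(nodes, 2)
  pick <- runif(ncol(cmb)) < p
  data.frame(source = cmb[1, pick], target = cmb[2, pick],
             origin = rep("custom", sum(pick)),
             confidence = rep(NA_real_, sum(pick)),
             stringsAsFactors = FALSE)
}
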