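test_that("log2 normalisation maps 0 to 0, 1 to 1, and is idempotent", {
  v <- matrix(c(0, 1, 3, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  groups <- c(s1 = "treated", s2 = "untreated")
  m <- expression_matrix(rbind(v, v), stats::setNames(groups, c("s1", "s2")))
  expect_error(de_two_group(m), "normalize")
  v4 <- matrix(c(0, 1, 3, 7), 1, 4,
               dimnames = list("g1", paste0("s", 1:4)))
  m <- expression_matrix(v4, stats::setNames(rep(c("treated", "untreated"),
                                                 each = 2), paste0("s", 1:4)))
  logged <- normalize_log2(m)
  expect_equal(unname(logged$values[1, 1:2]), c(0, 1))
  expect_identical(normalize_log2(logged), logged)
  neg <- m; neg$values[1] <- -1
  expect_error(normalize_log2(neg), "negative")
})

make_matrix <- function(n_genes = 50, n = 4, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * 2 * n, mean = 8), n_genes, 2 * n)
  dimnames(v) <- list(sprintf("g%03d", 1:n_genes), sprintf("s%d", 1:(2 * n)))
  expression_matrix(v, stats::setNames(rep(c("treated", "untreated"), each = n),
                                       colnames(v)), logged = TRUE)
}

test_that("identical group means give logfc 0; groups need >= 2 samples", {
  m <- make_matrix(n_genes = 5, n = 3, seed = 2)
  m$values[1, ] <- 5
  de <- de_two_group(m, moderation = FALSE)
  expect_equal(de$logfc[1], 0)
  small <- m
  small$values <- small$values[, c(1, 4, 5, 6)]
  small$groups <- small$groups[c(1, 4, 5, 6)]
  expect_error(de_two_group(small), ">= 2")
})

test_that("unmoderated results equal genewise equal-variance t-tests", {
  m <- make_matrix(seed = 3)
  de <- de_two_group(m, moderation = FALSE)
  for (i in c(1, 17, 50)) {
    tt <- t.test(m$values[i, m$groups == "treated"],
                 m$values[i, m$groups == "untreated"], var.equal = TRUE)
    expect_equal(de$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$logfc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("swapping group labels negates logfc and preserves |t|", {
  m <- make_matrix(seed = 4)
  de1 <- de_two_group(m, moderation = TRUE)
  flipped <- m
  flipped$groups <- ifelse(m$groups == "treated", "untreated", "treated")
  de2 <- de_two_group(flipped, moderation = TRUE)
  expect_equal(de2$logfc, -de1$logfc)
  expect_equal(abs(de2$t_stat), abs(de1$t_stat))
})

test_that("posterior variances shrink between the gene and prior variances", {
  # heteroskedastic genes: variances drawn from a finite-d0 prior
  sim <- simulate_expression(n_genes = 200, n_per_group = 4, d0 = 4,
                             s0_sq = 0.3, seed = 5)
  m <- sim$matrix
  de <- de_two_group(m, moderation = TRUE)
  d0 <- attr(de, "d0"); s0 <- attr(de, "s0_sq")
  expect_true(is.finite(d0))
  scale2 <- 1 / 4 + 1 / 4
  s2_post <- de$se^2 / scale2
  # recompute raw s2 from the unmoderated run
  raw <- de_two_group(m, moderation = FALSE)
  s2 <- raw$se^2 / scale2
  lo <- pmin(s2, s0); hi <- pmax(s2, s0)
  expect_true(all(s2_post >= lo - 1e-12 & s2_post <= hi + 1e-12))
})

test_that("equal gene variances drive d0 to infinity and t to the common-variance t", {
  set.seed(6)
  n <- 4
  base <- rnorm(2 * n, mean = 8)
  v <- t(vapply(1:100, function(i) base + rnorm(1, sd = 3), numeric(2 * n)))
  # every gene is a mean-shifted copy: residual variances are identical
  dimnames(v) <- list(sprintf("g%03d", 1:100), sprintf("s%d", 1:(2 * n)))
  m <- expression_matrix(v, stats::setNames(rep(c("treated", "untreated"),
                                                each = n), colnames(v)),
                         logged = TRUE)
  de <- de_two_group(m, moderation = TRUE)
  expect_true(is.infinite(attr(de, "d0")))
  s_common <- sqrt(attr(de, "s0_sq") * (1 / n + 1 / n))
  expect_equal(de$t_stat, de$logfc / s_common, tolerance = 1e-8)
})

test_that("moderated statistics agree with the limma reference implementation", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(n_genes = 500, n_per_group = 4, d0 = 5,
                             s0_sq = 0.3, seed = 77)
  de <- de_two_group(sim$matrix, moderation = TRUE)
  design <- stats::model.matrix(~ factor(sim$matrix$groups,
                                         c("untreated", "treated")))
  fit <- limma::eBayes(limma::lmFit(sim$matrix$values, design))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$logfc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("method of moments recovers the planted variance prior", {
  sim <- simulate_expression(n_genes = 2000, n_per_group = 5, d0 = 4,
                             s0_sq = 0.25, seed = 19)
  de <- de_two_group(sim$matrix, moderation = TRUE)
  expect_lt(abs(attr(de, "d0") - 4) / 4, 0.25)
  expect_lt(abs(attr(de, "s0_sq") - 0.25) / 0.25, 0.10)
})

test_that("planted fold changes are recovered in mean and sign", {
  planted <- stats::setNames(rep(2, 1000), sprintf("GENE%04d", 1:1000))
  suppressWarnings(
    sim <- simulate_expression(n_genes = 1000, n_per_group = 5,
                               planted_logfc = planted, sd = 0.5, seed = 42))
  de <- de_two_group(sim$matrix, moderation = TRUE)
  expect_lt(abs(mean(de$logfc) - 2), 0.15)
  expect_gte(mean(de$logfc > 0), 0.99)
})

test_that("colour map hits the anchors, is symmetric, monotone and clamps", {
  expect_identical(map_color(0), "#FFFF00")
  expect_identical(map_color(1, cap = 1), "#FF0000")
  expect_identical(map_color(5, cap = 1), "#FF0000")
  expect_identical(map_color(-1, cap = 1), "#00008B")
  expect_identical(map_color(NA), "#BEBEBE")
  # mirror symmetry: green channel falls identically on both sides
  chan <- function(hex, i) strtoi(substr(hex, 2 * i, 2 * i + 1), 16L)
  x <- seq(0.1, 0.9, by = 0.2)
  expect_equal(chan(map_color(x), 2), chan(map_color(-x), 2))
  # monotone: red side keeps red fixed while green falls with logfc
  g <- chan(map_color(seq(0, 1, by = 0.1)), 2)
  expect_true(all(diff(g) <= 0))
  ov <- overlay_table(data.frame(gene = "g", logfc = 0.5))
  expect_named(ov, c("gene", "logfc", "fill"))
})
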