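#' Expression matrix with a two-group sample sheet
#'
#' @param values gene x sample numeric matrix (rownames = gene symbols,
#'   colnames = sample ids); non-negative intensities unless already logged.
#' @param groups named character vector or data frame (sample, group) mapping
#'   every sample to \code{"treated"} or \code{"untreated"}.
#' @param logged whether \code{values} are already on the log2 scale.
#' @return list of class \code{"affnet_expr"}.
#' @export
expression_matrix <- function(values, groups, logged = FALSE) {
  values <- as.matrix(values)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  }
  if (is.null(colnames(values)) || is.null(rownames(values))) {
    stop_affnet("values must carry gene rownames and sample colnames")
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) stop_affnet("sample(s) without group: ",
                                   paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- !groups %in% c("treated", "untreated")
  if (any(bad)) stop_affnet("groups must be treated/untreated; got: ",
                            paste(unique(groups[bad]), collapse = ", "))
  if (anyNA(values)) stop_affnet("missing expression values are not supported")
  m <- structure(list(values = values, groups = groups, logged = logged),
                 class = "affnet_expr")
  med <- tapply(apply(values, 2, stats::median), groups, stats::median)
  if (length(med) == 2L && abs(diff(med)) > 1 && logged) {
    warn_affnet("group median intensities differ by > 1 log2 unit; ",
                "matrices may not be comparable")
  }
  m
}

#' Read an expression TSV (first column gene, remaining columns samples) and
#' its sample sheet (columns sample, group)
#'
#' @param expr_path,groups_path file paths.
#' @param logged whether intensities are already log2.
#' @return \code{\link{expression_matrix}}.
#' @export
read_expression <- function(expr_path, groups_path, logged = FALSE) {
  df <- utils::read.delim(expr_path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  sheet <- utils::read.delim(groups_path, header = TRUE,
                             stringsAsFactors = FALSE)
  expression_matrix(values, sheet, logged = logged)
}

#' Log2 normalisation
#'
#' Applies \code{log2(x + 1)} unless the matrix is flagged as already logged,
#' in which case this is a no-op (idempotent by contract).
#'
#' @param m \code{\link{expression_matrix}}.
#' @return logged \code{expression_matrix}.
#' @export
normalize_log2 <- function(m) {
  stopifnot(inherits(m, "affnet_expr"))
  if (m$logged) return(m)
  if (any(m$values < 0)) stop_affnet("negative raw intensities")
  m$values <- log2(m$values + 1)
  m$logged <- TRUE
  m
}

# Newton inversion of the trigamma function, for the method-of-moments fit
# of the prior degrees of freedom. Solves trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate empirical-Bayes variance prior by method of moments
#'
#' Models gene-wise residual variances s2 (each on d degrees of freedom) as
#' draws whose distribution is s0^2 * F(d, d0). On the log scale,
#' z = log(s2) then satisfies E\[z\] = log(s0^2) + digamma(d/2) - log(d/2) -
#' (digamma(d0/2) - log(d0/2)) and Var\[z\] = trigamma(d/2) + trigamma(d0/2),
#' so matching the sample mean and variance of z yields (d0, s0^2); the
#' trigamma equation is inverted by Newton's method. When the observed
#' variance of z does not exceed trigamma(d/2), the variances are consistent
#' with a single common value and d0 = Inf is returned.
#'
#' @param s2 gene-wise residual variances.
#' @param d residual degrees of freedom per gene (scalar).
#' @return list with \code{d0} (prior df, possibly Inf) and \code{s0_sq}.
#' @export
estimate_variance_prior <- function(s2, d) {
  z <- log(s2)
  e_z <- mean(z)
  v_z <- stats::var(z)
  excess <- v_z - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(e_z - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_z - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Two-group differential expression with optional variance moderation
#'
#' Per gene: log2 fold change = mean(treated) - mean(untreated) and a pooled
#' residual variance s2 on d = n1 + n2 - 2 degrees of freedom. Without
#' moderation, the ordinary two-sample t-statistic is returned. With
#' moderation, gene-wise variances are shrunk toward a prior estimated across
#' genes by \code{\link{estimate_variance_prior}}:
#' s2_post = (d0 * s0^2 + d * s2) / (d0 + d), and the moderated t uses
#' s2_post with d0 + d degrees of freedom — small per-gene variances are
#' pulled up and unstable ones stabilised, exactly the empirical-Bayes
#' moderation practice for small two-group microarray contrasts.
#'
#' @param m logged \code{\link{expression_matrix}} with >= 2 samples per
#'   group.
#' @param moderation apply empirical-Bayes variance shrinkage (default TRUE).
#' @return data frame: gene, logfc, se, t_stat, p_value, moderated; with
#'   attributes \code{d0} and \code{s0_sq} when moderated.
#' @export
de_two_group <- function(m, moderation = TRUE) {
  stopifnot(inherits(m, "affnet_expr"))
  if (!m$logged) stop_affnet("normalize_log2() the matrix first")
  g1 <- m$groups == "treated"; g2 <- m$groups == "untreated"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop_affnet("each group needs >= 2 samples")
  x1 <- m$values[, g1, drop = FALSE]; x2 <- m$values[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  logfc <- m1 - m2
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  d <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / d
  scale2 <- 1 / n1 + 1 / n2

  if (moderation) {
    prior <- estimate_variance_prior(s2, d)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
    s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
      (d0 * s0_sq + d * s2) / (d0 + d)
    se <- sqrt(s2_post * scale2)
    t_stat <- logfc / se
    df_total <- d0 + d
    p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  } else {
    se <- sqrt(s2 * scale2)
    t_stat <- logfc / se
    p <- 2 * stats::pt(-abs(t_stat), df = d)
  }
  out <- data.frame(gene = rownames(m$values), logfc = logfc, se = se,
                    t_stat = t_stat, p_value = p, moderated = moderation,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (moderation) {
    attr(out, "d0") <- d0
    attr(out, "s0_sq") <- s0_sq
  }
  out
}

#' Map log2 fold change to the red-yellow-blue overlay colour
#'
#' 0 maps to yellow (no change), +cap and beyond to pure red (overexpressed),
#' -cap and beyond to dark blue (underexpressed), with linear interpolation
#' in RGB between yellow and each extreme. Absent values map to neutral grey.
#'
#' @param logfc numeric vector (NA allowed).
#' @param cap positive saturation point in log2 units (default 1).
#' @return character vector of hex colours.
#' @export
map_color <- function(logfc, cap = 1) {
  stopifnot(cap > 0)
  yellow <- c(255, 255, 0); red <- c(255, 0, 0); darkblue <- c(0, 0, 139)
  vapply(logfc, function(x) {
    if (is.na(x)) return("#BEBEBE")
    f <- min(abs(x) / cap, 1)
    target <- if (x >= 0) red else darkblue
    rgb <- round(yellow + f * (target - yellow))
    sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])
  }, character(1))
}

#' Expression overlay table for network fills
#'
#' @param de result of \code{\link{de_two_group}}.
#' @param cap colour saturation (log2 units).
#' @return data frame: gene, logfc, fill (hex colour).
#' @export
overlay_table <- function(de, cap = 1) {
  data.frame(gene = de$gene, logfc = de$logfc,
             fill = map_color(de$logfc, cap = cap), stringsAsFactors = FALSE)
}
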